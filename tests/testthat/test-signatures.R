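test_that("profile correlation handles identity, negation and orthogonality", {
  x <- c(1.5, -2, 0.5, 3)
  expect_equal(profile_cor(x, x), 1)
  expect_equal(profile_cor(x, -x), -1)
  expect_equal(profile_cor(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
})

test_that("profile correlation enforces shared support and variance", {
  expect_error(profile_cor(c(1, 2, NA, NA), c(1, NA, 2, 3)), "fewer than 3")
  expect_error(profile_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(profile_cor(1:3, 1:4), "length")
  # pairwise-complete: correlation computed over the shared positions only
  expect_equal(profile_cor(c(1, 2, 3, NA), c(2, 4, 6, 100)), 1)
})

test_that("identical and anti-correlated profiles merge at the expected heights", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  hc <- cluster_profiles(m)
  expect_equal(sort(hc$height), c(0, 2), tolerance = 1e-12)
  first_pair <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first_pair, c("a", "b"))
})

test_that("average-linkage heights match the brute-force oracle", {
  set.seed(77)
  for (n in c(6L, 8L, 10L)) {
    m <- matrix(rnorm(n * 7), nrow = n,
                dimnames = list(paste0("r", seq_len(n)), NULL))
    hc <- cluster_profiles(m)
    d <- 1 - cor(t(m))
    expect_equal(sort(hc$height), sort(upgma_heights_bruteforce(d)),
                 tolerance = 1e-10)
  }
})

test_that("rows that cannot be correlated are excluded with a warning", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3), c = c(5, 5, 5, 5),
             d = c(0, 2, 1, 5))
  expect_warning(hc <- cluster_profiles(m), "excluding profile 'c'")
  expect_equal(sort(hc$labels), c("a", "b", "d"))
})

test_that("dendrogram cuts range from all singletons to one cluster", {
  m <- make_two_block_matrix(n_per_block = 4, n_noise = 3, seed = 5)
  hc <- cluster_profiles(m)
  low <- extract_clusters(hc, min(hc$height) / 2)
  expect_equal(length(unique(low)), nrow(m))
  high <- extract_clusters(hc, max(hc$height) + 0.1)
  expect_equal(length(unique(high)), 1L)
})

test_that("planted two-block structure is recovered at the default cut", {
  m <- make_two_block_matrix(n_per_block = 5, n_noise = 6, seed = 42)
  mem <- extract_clusters(cluster_profiles(m), 0.5)
  a <- mem[paste0("a", 1:5)]
  b <- mem[paste0("b", 1:5)]
  expect_equal(length(unique(a)), 1L)
  expect_equal(length(unique(b)), 1L)
  expect_false(unique(a) == unique(b))
})

test_that("consensus signatures average members and ignore missing values", {
  m <- rbind(a = c(1, 3), b = c(3, 1), c = c(NA, 5))
  expect_equal(consensus_signature("a", m), m["a", ])
  expect_equal(unname(consensus_signature(c("a", "b"), m)), c(2, 2))
  expect_equal(unname(consensus_signature(c("a", "b", "c"), m)), c(2, 3))
  # invariant to member order; adding a member equal to the consensus
  # leaves it unchanged
  expect_equal(consensus_signature(c("b", "a"), m),
               consensus_signature(c("a", "b"), m))
  m2 <- rbind(m, d = c(2, 2))
  expect_equal(unname(consensus_signature(c("a", "b", "d"), m2)), c(2, 2))
  expect_error(consensus_signature(character(0), m), "empty")
  expect_error(consensus_signature("zz", m), "absent")
})

# Toy audit: two genes concordant in the signature cluster, one discordant
# annotated gene (false negative), one discordant unannotated-mismatch gene
# (false positive attribution).
make_toy_audit <- function() {
  set.seed(12)
  sig <- c(-4, -3, -5, -0.2, -4.5, -0.1, -3.5, -4)
  mk <- function(active) {
    if (active) sig + rnorm(8, 0, 0.3) else rnorm(8, 0, 1)
  }
  m <- rbind(
    g1_r1 = mk(TRUE), g1_r2 = mk(TRUE),
    g2_r1 = mk(TRUE), g2_r2 = mk(TRUE),
    g3_r1 = mk(TRUE), g3_r2 = mk(FALSE),   # discordant, annotated -> FN
    g4_r1 = mk(TRUE), g4_r2 = mk(FALSE),   # discordant, other set -> FP
    g5_r1 = mk(FALSE), g5_r2 = mk(FALSE)   # concordant out
  )
  map <- data.frame(reagent_id = rownames(m),
                    gene_id = rep(paste0("g", 1:5), each = 2))
  annotation <- data.frame(gene_id = paste0("g", 1:5),
                           set_label = c("ribo", "ribo", "ribo", "other",
                                         "ribo"))
  list(m = m, map = map, annotation = annotation)
}

test_that("multi-reagent genes are classified and attributed correctly", {
  toy <- make_toy_audit()
  mem <- extract_clusters(cluster_profiles(toy$m), 0.5)
  sig_cl <- unname(mem["g1_r1"])
  res <- classify_multireagent_genes(mem, toy$m, toy$map, toy$annotation,
                                     cluster = sig_cl)
  expect_equal(res$label, "ribo")
  calls <- res$calls[order(res$calls$gene_id), ]
  expect_equal(calls$classification,
               c("concordant_in", "concordant_in", "discordant",
                 "discordant", "concordant_out"))
  expect_equal(calls$attribution[3:4], c("false_negative", "false_positive"))
  # classification is symmetric in reagent order
  m_flip <- toy$m[c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9), ]
  mem2 <- extract_clusters(cluster_profiles(m_flip), 0.5)
  res2 <- classify_multireagent_genes(mem2, m_flip, toy$map, toy$annotation,
                                      cluster = unname(mem2["g1_r1"]))
  expect_equal(res2$calls[order(res2$calls$gene_id), "classification"],
               calls$classification)
})

test_that("the cluster FN rate reproduces the discordance arithmetic", {
  # 42 concordant two-reagent genes, 8 discordant attributed FN, 1
  # discordant attributed FP, one gene carrying a third reagent: 103
  # reagents in total
  calls <- data.frame(
    n_reagents = c(rep(2, 42), rep(2, 8), 2),
    n_in = c(rep(2, 42), rep(1, 8), 1),
    classification = c(rep("concordant_in", 42), rep("discordant", 9)),
    attribution = c(rep(NA, 42), rep("false_negative", 8),
                    "false_positive"))
  calls$n_reagents[1] <- 3  # the triple-covered gene
  est <- estimate_cluster_fn_rate(calls, total_reagents = 103)
  expect_equal(est$n_false_negative, 8)
  expect_equal(est$rate, 8 / 103, tolerance = 1e-12)
  expect_equal(round(100 * est$rate), 8)

  none <- estimate_cluster_fn_rate(calls[1:42, ], 103)
  expect_equal(none$rate, 0)
  expect_error(estimate_cluster_fn_rate(calls, 0), "positive count")
})

test_that("pooled non-signature rates combine set counts", {
  expect_equal(pooled_nonsignature_rate(
    data.frame(n_nonsignature = c(22, 29), set_size = c(94, 58)))$rate,
    51 / 152, tolerance = 1e-12)
  expect_equal(pooled_nonsignature_rate(
    data.frame(n_nonsignature = 22, set_size = 94))$rate,
    22 / 94, tolerance = 1e-12)
  expect_equal(pooled_nonsignature_rate(
    data.frame(n_nonsignature = 0, set_size = 50))$rate, 0)
  expect_error(pooled_nonsignature_rate(
    data.frame(n_nonsignature = 10, set_size = 5)), "exceeds")
  expect_error(pooled_nonsignature_rate(
    data.frame(n_nonsignature = numeric(0), set_size = numeric(0))),
    "no gene sets")
})

test_that("the full audit recovers a planted inefficacy rate", {
  toy <- make_toy_audit()
  audit <- audit_fn_rate(toy$m, toy$map, toy$annotation, labels = "ribo")
  # audited genes: g1, g2 (concordant in), g3 (FN discordant) and g4
  # (discordant, annotated to the other set — counted in the denominator
  # like a false-positive intruder, but not in the FN numerator) = 8
  # reagents; g5 never enters the cluster
  expect_equal(audit$n_reagents, 8)
  expect_equal(audit$n_false_negative, 1)
  expect_equal(audit$rate, 1 / 8)
})
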