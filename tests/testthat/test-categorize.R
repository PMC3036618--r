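test_that("reagent hit calls enforce threshold, sign and evaluability", {
  z <- rbind(a = c(-4.5, -4.3),  # strong reproduced hit
             b = c(1.9, 2.5),    # below threshold once
             c = c(2.5, -2.5),   # sign flip: noise, not a hit
             d = c(2.1, 2.0),    # reproduced positive hit
             e = c(2.5, NA))     # non-evaluable
  h <- call_reagent_hits(z, threshold = 2)
  expect_equal(h$hit, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(h$evaluable, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # without the sign requirement the flip counts
  expect_true(call_reagent_hits(z, same_sign = FALSE)$hit[3])
  expect_error(call_reagent_hits(z, threshold = 0), "positive")
})

test_that("raising the threshold never gains hits (monotonicity)", {
  set.seed(19)
  z <- matrix(rnorm(200, sd = 2), ncol = 2,
              dimnames = list(sprintf("r%03d", 1:100), NULL))
  for (thr in c(1, 2, 3)) {
    lo <- call_reagent_hits(z, thr)$hit
    hi <- call_reagent_hits(z, thr + 0.5)$hit
    expect_true(all(lo | !hi))
  }
})

test_that("gene categories follow the all / some / single scoring scheme", {
  expect_equal(categorize_counts(c(4, 3, 2, 3, 1), c(4, 2, 1, 0, 1)),
               c("1", "2", "3", "none", "1"))
  expect_error(categorize_counts(2, 3), "exceeds")

  map <- data.frame(reagent_id = sprintf("r%d", 1:7),
                    gene_id = c("A", "A", "B", "B", "B", "C", "C"))
  hits <- data.frame(reagent_id = map$reagent_id,
                     hit = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                     evaluable = c(rep(TRUE, 6), FALSE))
  cat <- assign_gene_categories(hits, map)
  expect_equal(cat$category[cat$gene_id == "A"], "1")
  expect_equal(cat$category[cat$gene_id == "B"], "3")
  # C: one non-evaluable reagent dropped, remaining zero scoring
  expect_equal(cat$n_reagents[cat$gene_id == "C"], 1L)
  expect_equal(cat$category[cat$gene_id == "C"], "none")
  expect_error(assign_gene_categories(
    data.frame(reagent_id = "zz", hit = TRUE, evaluable = TRUE), map),
    "unmapped")
})

test_that("categories partition the genes with a scoring reagent", {
  set.seed(23)
  map <- data.frame(reagent_id = sprintf("r%03d", 1:120),
                    gene_id = rep(sprintf("g%02d", 1:40), each = 3))
  z <- matrix(rnorm(240, sd = 2), ncol = 2,
              dimnames = list(map$reagent_id, NULL))
  cat <- assign_gene_categories(call_reagent_hits(z), map)
  n_any <- sum(cat$n_scoring > 0)
  expect_equal(sum(cat$category %in% c("1", "2", "3")), n_any)
  expect_equal(nrow(cat), 40L)
})

test_that("expression flags honor thresholds, comparators and missing genes", {
  fpkm <- data.frame(gene_id = c("A", "B", "C"),
                     S2 = c(0.5, 5.0, 12), Kc = c(2, 0.1, 1))
  cats <- data.frame(gene_id = c("A", "B", "C", "D"))
  out <- apply_expression_filter(cats, fpkm, "S2")
  expect_equal(out$expressed, c(FALSE, TRUE, TRUE, NA))
  expect_equal(out$elevated, c(FALSE, TRUE, TRUE, NA))
  strict <- apply_expression_filter(cats, fpkm, "S2", comparator = ">")
  expect_false(strict$elevated[2])  # 5.0 fails the strict > 5 cut
  expect_error(apply_expression_filter(cats, fpkm, "BG3"), "unknown cell line")
})

test_that("expressed-intersection counts behave like independent filters", {
  fpkm <- data.frame(gene_id = c("A", "B"), S2 = c(2, 0.2), Kc = c(5, 8))
  expect_equal(count_expressed_intersection(fpkm, "S2"), 1L)
  expect_equal(count_expressed_intersection(fpkm, c("S2", "Kc")), 1L)
  expect_equal(count_expressed_intersection(fpkm, c("S2", "Kc"),
                                            threshold = 0), 2L)
  expect_error(count_expressed_intersection(fpkm, "nope"), "unknown")

  tab <- generate_expression_table(sprintf("g%04d", 1:8000),
                                   cell_lines = c("L1", "L2"),
                                   expressed_fraction = 0.5,
                                   meanlog = 4, sdlog = 0.5,
                                   unexpressed_fpkm_max = 0.9, seed = 6)
  n_both <- count_expressed_intersection(tab, c("L1", "L2"), threshold = 1)
  se <- sqrt(0.25 * 0.75 * 8000)
  expect_lt(abs(n_both - 0.25 * 8000), 3 * se)
})

test_that("screen-level rates follow their count definitions", {
  cats <- data.frame(gene_id = sprintf("g%d", 1:6),
                     n_reagents = c(3, 3, 2, 3, 2, 3),
                     n_scoring = c(3, 2, 1, 1, 0, 3))
  cats$category <- categorize_counts(cats$n_reagents, cats$n_scoring)
  r <- estimate_screen_rates(cats, library_size = 100)
  expect_equal(r$n_category_1, 2L)
  expect_equal(r$n_category_2, 1L)
  expect_equal(r$n_category_3, 2L)
  expect_equal(r$fp_reagent_rate, 2 / 100)
  expect_equal(r$fp_hit_fraction, 2 / 5)
  expect_equal(r$fn_reagent_rate, 1 / 9)  # cat-1/2 genes: 9 reagents, 1 miss
  # all-category-1 edge: no false signals at all
  allhit <- data.frame(gene_id = "g", n_reagents = 2, n_scoring = 2,
                       category = "1")
  r2 <- estimate_screen_rates(allhit, 10)
  expect_equal(r2$fp_hit_fraction, 0)
  expect_equal(r2$fn_reagent_rate, 0)
  expect_error(estimate_screen_rates(cats, 1), "smaller")
})

test_that("fp_reagent_rate cannot exceed fp_hit_fraction for real libraries", {
  set.seed(29)
  map <- data.frame(reagent_id = sprintf("r%03d", 1:90),
                    gene_id = rep(sprintf("g%02d", 1:30), each = 3))
  z <- matrix(rnorm(180, sd = 2), ncol = 2,
              dimnames = list(map$reagent_id, NULL))
  cat <- assign_gene_categories(call_reagent_hits(z), map)
  if (any(cat$n_scoring > 0)) {
    r <- estimate_screen_rates(cat, library_size = 90)
    expect_lte(r$fp_reagent_rate, r$fp_hit_fraction)
  }
})

test_that("the packaged screen hit table is internally consistent", {
  kp <- kp_jakstat_hits()
  expect_equal(nrow(kp), 24L)
  expect_equal(kp$n_reagents - kp$n_scoring, kp$n_nonscoring)
  # recomputing every category from the reagent counts reproduces the
  # published column
  expect_identical(categorize_counts(kp$n_reagents, kp$n_scoring),
                   kp$category)
})
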