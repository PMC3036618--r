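# Shared helpers: an independent brute-force UPGMA oracle and small
# in-code fixtures.

# Brute-force average-linkage merge heights: at every step, scan all
# cluster pairs and merge the pair with the smallest mean of the ORIGINAL
# pairwise distances (the defining property of unweighted average linkage).
upgma_heights_bruteforce <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- Inf; bi <- bj <- NA_integer_
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best) { best <- avg; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters <- clusters[-bj]
  }
  heights
}

# Z-profile matrix with two planted signature blocks plus background rows.
make_two_block_matrix <- function(n_per_block = 5, n_noise = 6,
                                  n_screens = 12, noise_sd = 0.3,
                                  seed = 42) {
  set.seed(seed)
  sig_a <- rnorm(n_screens, 0, 2)
  sig_b <- rnorm(n_screens, 0, 2)
  rows <- c(
    lapply(seq_len(n_per_block), function(i) sig_a + rnorm(n_screens, 0, noise_sd)),
    lapply(seq_len(n_per_block), function(i) sig_b + rnorm(n_screens, 0, noise_sd)),
    lapply(seq_len(n_noise), function(i) rnorm(n_screens, 0, 1))
  )
  m <- do.call(rbind, rows)
  rownames(m) <- c(sprintf("a%d", seq_len(n_per_block)),
                   sprintf("b%d", seq_len(n_per_block)),
                   sprintf("x%d", seq_len(n_noise)))
  m
}

# Minimal one-plate reading table.
make_plate <- function(values, screen_id = "S01", replicate = 1L,
                       plate_id = "P01",
                       role = rep("sample", length(values)),
                       reagent_id = sprintf("r%02d", seq_along(values))) {
  reagent_id[role != "sample"] <- ""
  data.frame(screen_id = screen_id, replicate = replicate,
             plate_id = plate_id,
             row = rep(1L, length(values)), col = seq_along(values),
             well_role = role, reagent_id = reagent_id, value = values,
             stringsAsFactors = FALSE)
}
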