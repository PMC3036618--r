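# The m-of-k binomial model of hit disambiguation for libraries with k
# independently tested RNAi reagents per gene.  Each reagent on a true-hit
# gene scores with probability 1 - r_fn, each reagent on a non-hit gene
# scores with probability r_fp, independently; a gene is called a hit when
# at least m of its k reagents score.

#' Resolve a disambiguation rule to its m-of-k threshold
#'
#' * `lenient` — any reagent scoring calls the gene (`m = 1`);
#' * `stringent` — all reagents must score (`m = k`);
#' * `majority` — more than half must score (`m = floor(k/2) + 1`);
#' * `m_of_k` — explicit `m`.
#'
#' @param rule rule name.
#' @param k reagents per gene (>= 1).
#' @param m explicit threshold, required for `rule = "m_of_k"`.
#' @return integer `m` with `1 <= m <= k`.
#' @export
rule_m <- function(rule = c("lenient", "stringent", "majority", "m_of_k"),
                   k, m = NULL) {
  rule <- match.arg(rule)
  stopifnot(length(k) == 1L, k >= 1)
  m <- switch(rule,
              lenient = 1L,
              stringent = as.integer(k),
              majority = as.integer(k %/% 2 + 1),
              m_of_k = m)
  if (is.null(m) || length(m) != 1L || is.na(m) || m < 1 || m > k)
    stop("m must satisfy 1 <= m <= k")
  as.integer(m)
}

#' Expected false-negative and false-positive gene counts
#'
#' Closed form of the m-of-k model.  With `H` true-hit and `N` non-hit
#' genes,
#'
#' \deqn{E[FN] = P(\mathrm{Bin}(k, 1 - r_{FN}) < m) \cdot H, \qquad
#'       E[FP] = P(\mathrm{Bin}(k, r_{FP}) \ge m) \cdot N.}
#'
#' For `k <= 3` these reduce to the polynomial expansions in
#' [rule_polynomial()].
#'
#' @param r_fn per-reagent false-negative probability (a reagent on a
#'   true-hit gene fails to score).
#' @param r_fp per-reagent false-positive probability (a reagent on a
#'   non-hit gene scores).
#' @param h number of true-hit genes (`H`).
#' @param n number of non-hit genes (`N`).
#' @param k reagents per gene.
#' @param rule,m see [rule_m()].
#' @return list `expected_fn`, `expected_fp`, `k`, `m`, `rule`.
#' @export
#' @examples
#' expected_error_counts(0.1, 0.01, h = 100, n = 13635, k = 3,
#'                       rule = "majority")
expected_error_counts <- function(r_fn, r_fp, h, n, k, rule = "majority",
                                  m = NULL) {
  stopifnot(r_fn >= 0, r_fn <= 1, r_fp >= 0, r_fp <= 1, h >= 0, n >= 0)
  m <- rule_m(rule, k, m)
  list(expected_fn = pbinom(m - 1, k, 1 - r_fn) * h,
       expected_fp = (1 - pbinom(m - 1, k, r_fp)) * n,
       k = as.integer(k), m = m, rule = rule)
}

#' Literal polynomial error probabilities for k up to 3
#'
#' The per-gene error probabilities of the three named rules written out as
#' expanded polynomials in the per-reagent rate, exactly as they appear in
#' the published model table for one, two and three reagents per gene
#' (e.g. lenient false positives at `k = 3`:
#' `3 r - 3 r^2 + r^3`).  This is an independent formulation of
#' [expected_error_counts()] and serves as its oracle in tests; multiply by
#' `H` (for `which = "fn"`) or `N` (`"fp"`) to get expected counts.
#'
#' @param rate the per-reagent rate: `r_fn` for `which = "fn"`, `r_fp` for
#'   `which = "fp"`.
#' @param k 1, 2 or 3.
#' @param rule `"lenient"`, `"stringent"` or `"majority"`.
#' @param which `"fn"` or `"fp"`.
#' @return the per-gene error probability.
#' @export
#' @examples
#' rule_polynomial(0.1, k = 3, rule = "majority", which = "fn")  # 0.028
rule_polynomial <- function(rate, k,
                            rule = c("lenient", "stringent", "majority"),
                            which = c("fn", "fp")) {
  rule <- match.arg(rule)
  which <- match.arg(which)
  stopifnot(rate >= 0, rate <= 1)
  if (!k %in% 1:3) stop("polynomials are tabulated for k in 1..3 only")
  r <- rate
  # FN polynomials answer "gene missed"; FP polynomials answer "gene
  # called".  Lenient misses only when all reagents fail (r^k) and calls
  # when any scores; stringent is the mirror image; majority needs more
  # than half.
  if (k == 1L) return(r)
  any_of <- function(r, k) if (k == 2L) 2 * r - r^2 else 3 * r - 3 * r^2 + r^3
  all_of <- function(r, k) r^k
  maj_of <- function(r, k) if (k == 2L) r^2 else 3 * r^2 - 2 * r^3
  switch(rule,
    lenient = if (which == "fn") all_of(r, k) else any_of(r, k),
    stringent = if (which == "fn") any_of(r, k) else all_of(r, k),
    majority = {
      # failing a majority call means more than half failed; for k = 2 the
      # majority threshold is 2 of 2, identical to the stringent rule
      if (which == "fn") {
        if (k == 2L) any_of(r, k) else maj_of(r, k)
      } else {
        maj_of(r, k)
      }
    })
}

#' Monte-Carlo simulation of the disambiguation model
#'
#' Per replicate, draws every reagent's score as an independent Bernoulli
#' (success `1 - r_fn` on hit genes, `r_fp` on non-hit genes), applies the
#' m-of-k call, and counts missed hit genes and called non-hit genes.
#'
#' @inheritParams expected_error_counts
#' @param n_reps number of simulation replicates.
#' @param seed integer seed; identical seeds give identical output.
#' @return list `mean_fn`, `mean_fp`, `se_fn`, `se_fp`, `n_reps`, `k`,
#'   `m`, `rule`.
#' @export
simulate_disambiguation <- function(r_fn, r_fp, h, n, k, rule = "majority",
                                    m = NULL, n_reps = 10000L, seed = 1L) {
  stopifnot(n_reps >= 1)
  m <- rule_m(rule, k, m)
  set.seed(seed)
  fn <- integer(n_reps)
  fp <- integer(n_reps)
  # chunk replicates so the per-gene binomial draws stay within memory
  chunk <- max(1L, min(n_reps, floor(2e6 / max(1, h + n))))
  done <- 0L
  while (done < n_reps) {
    this <- min(chunk, n_reps - done)
    if (h > 0) {
      sc <- matrix(rbinom(this * h, k, 1 - r_fn), nrow = h)
      fn[done + seq_len(this)] <- colSums(sc < m)
    }
    if (n > 0) {
      sc <- matrix(rbinom(this * n, k, r_fp), nrow = n)
      fp[done + seq_len(this)] <- colSums(sc >= m)
    }
    done <- done + this
  }
  list(mean_fn = mean(fn), mean_fp = mean(fp),
       se_fn = sd(fn) / sqrt(n_reps), se_fp = sd(fp) / sqrt(n_reps),
       n_reps = as.integer(n_reps), k = as.integer(k), m = m, rule = rule)
}

#' Enumerate every m-of-k rule up to k_max
#'
#' Tabulates expected false-negative and false-positive counts for every
#' threshold `m` at every library size `k <= k_max` and flags the rule
#' minimizing their sum.
#'
#' @inheritParams expected_error_counts
#' @param k_max largest reagents-per-gene value to enumerate.
#' @return data.frame `k`, `m`, `rule`, `expected_fn`, `expected_fp`,
#'   `expected_total`, `best`.
#' @export
rule_frontier <- function(r_fn, r_fp, h, n, k_max) {
  stopifnot(k_max >= 1)
  rows <- list()
  for (k in seq_len(k_max)) {
    for (m in seq_len(k)) {
      e <- expected_error_counts(r_fn, r_fp, h, n, k, rule = "m_of_k", m = m)
      name <- if (m == 1L) "lenient"
              else if (m == k) "stringent"
              else if (m == k %/% 2 + 1) "majority"
              else sprintf("%d_of_%d", m, k)
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, m = m, rule = name,
        expected_fn = e$expected_fn, expected_fp = e$expected_fp,
        expected_total = e$expected_fn + e$expected_fp,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$best <- seq_len(nrow(out)) == which.min(out$expected_total)
  out
}
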