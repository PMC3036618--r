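# Reagent-level hit calling from replicate Z-scores, the gene-level
# category 1/2/3 scheme, transcriptome (FPKM) filtering, and screen-level
# false-positive / false-negative rate estimates.

#' Call reagent hits from replicate Z-scores
#'
#' A reagent is a hit when `|Z| >= threshold` in **every** replicate and,
#' by default, all replicate Z-scores share one sign (a reagent scoring
#' +2.5 in one replicate and -2.5 in the other is noise, not a reproduced
#' effect).  Reagents with any missing replicate value are marked
#' non-evaluable and should be excluded from rate denominators.
#'
#' @param z numeric matrix of Z-scores, reagents in rows (row names
#'   required), replicates in columns.
#' @param threshold positive Z cutoff (default 2).
#' @param same_sign require a consistent effect direction across
#'   replicates.
#' @return data.frame `reagent_id`, `hit`, `evaluable`.
#' @export
#' @examples
#' z <- rbind(a = c(-4.5, -4.3), b = c(1.9, 2.5), c = c(2.5, -2.5))
#' call_reagent_hits(z)
call_reagent_hits <- function(z, threshold = 2, same_sign = TRUE) {
  if (is.data.frame(z)) z <- as.matrix(z)
  if (is.null(dim(z))) z <- matrix(z, ncol = 1,
                                   dimnames = list(names(z), NULL))
  if (is.null(rownames(z))) stop("Z matrix must have reagent row names")
  if (ncol(z) < 1L) stop("need at least one replicate column")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a positive Z value")
  evaluable <- rowSums(!is.finite(z)) == 0L
  above <- rowSums(abs(z) >= threshold) == ncol(z)
  consistent <- if (same_sign)
    abs(rowSums(sign(z))) == ncol(z) | ncol(z) == 1L
  else TRUE
  hit <- evaluable & above & consistent
  data.frame(reagent_id = rownames(z), hit = hit, evaluable = evaluable,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene category from reagent counts
#'
#' The category scheme for a gene with `n_reagents` evaluable reagents of
#' which `n_scoring` are hits: category 1 when all reagents scored,
#' category 2 when at least two scored but at least one did not, category 3
#' when exactly one scored, and `"none"` when none did.  "All scored" takes
#' precedence, so a single-reagent gene whose reagent scores is category 1.
#'
#' @param n_reagents,n_scoring integer vectors (recycled to equal length).
#' @return character vector in `c("1", "2", "3", "none")`.
#' @export
#' @examples
#' categorize_counts(c(4, 3, 2, 3), c(4, 2, 1, 0))
categorize_counts <- function(n_reagents, n_scoring) {
  n <- pmax(length(n_reagents), length(n_scoring))
  n_reagents <- rep_len(n_reagents, n)
  n_scoring <- rep_len(n_scoring, n)
  if (any(n_scoring > n_reagents))
    stop("n_scoring exceeds n_reagents")
  ifelse(n_scoring == 0L, "none",
         ifelse(n_scoring == n_reagents, "1",
                ifelse(n_scoring >= 2L, "2", "3")))
}

#' Assign gene-level hit categories
#'
#' Aggregates reagent hit calls per target gene and applies
#' [categorize_counts()].  Non-evaluable reagents are dropped from both
#' counts; genes with no scoring reagent are retained with category
#' `"none"` so that false-negative analyses can see them.
#'
#' @param hits data.frame from [call_reagent_hits()].
#' @param map data.frame `reagent_id`, `gene_id` covering every reagent.
#' @return data.frame `gene_id`, `n_reagents`, `n_scoring`, `category`.
#' @export
assign_gene_categories <- function(hits, map) {
  gene <- map$gene_id[match(hits$reagent_id, map$reagent_id)]
  if (anyNA(gene))
    stop("unmapped reagent(s): ",
         paste(hits$reagent_id[is.na(gene)][1:min(3, sum(is.na(gene)))],
               collapse = ", "))
  ev <- hits$evaluable
  gene_f <- factor(gene[ev], levels = unique(gene))
  n_reagents <- as.integer(table(gene_f))
  n_scoring <- as.integer(tapply(hits$hit[ev], gene_f, sum, default = 0L))
  out <- data.frame(gene_id = levels(gene_f),
                    n_reagents = n_reagents,
                    n_scoring = n_scoring,
                    stringsAsFactors = FALSE)
  out <- out[out$n_reagents > 0L, , drop = FALSE]
  out$category <- categorize_counts(out$n_reagents, out$n_scoring)
  rownames(out) <- NULL
  out
}

.fpkm_compare <- function(fpkm, threshold, comparator) {
  if (comparator == ">=") fpkm >= threshold else fpkm > threshold
}

#' Flag gene expression from an FPKM table
#'
#' Joins a cell line's FPKM values onto gene categories and flags each gene
#' as expressed (`FPKM >= threshold`, default 1) and elevated
#' (`FPKM >= elevated_threshold`, default 5).  Genes absent from the table
#' get `NA` — unknown, never counted as unexpressed.  The comparator is
#' configurable (`">="` or `">"`) because published descriptions of the
#' FPKM-1 cutoff differ on boundary handling.
#'
#' @param categories data.frame with a `gene_id` column (e.g. from
#'   [assign_gene_categories()]).
#' @param fpkm data.frame `gene_id` plus one numeric column per cell line.
#' @param line cell-line column to use.
#' @param threshold FPKM cutoff for "expressed".
#' @param elevated_threshold FPKM cutoff for "elevated".
#' @param comparator `">="` (default) or `">"`.
#' @return `categories` with added `fpkm`, `expressed`, `elevated` columns.
#' @export
apply_expression_filter <- function(categories, fpkm, line, threshold = 1,
                                    elevated_threshold = 5,
                                    comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  if (!line %in% names(fpkm))
    stop("unknown cell line: ", line)
  v <- fpkm[[line]][match(categories$gene_id, fpkm$gene_id)]
  categories$fpkm <- v
  categories$expressed <- .fpkm_compare(v, threshold, comparator)
  categories$elevated <- .fpkm_compare(v, elevated_threshold, comparator)
  categories
}

#' Count genes expressed in every listed cell line
#'
#' @inheritParams apply_expression_filter
#' @param lines character vector of cell-line columns (at least one).
#' @return integer count of genes with FPKM passing the threshold in all
#'   listed lines.
#' @export
#' @examples
#' tab <- data.frame(gene_id = c("a", "b"), S2 = c(2, 0.2), Kc = c(5, 8))
#' count_expressed_intersection(tab, c("S2", "Kc"), threshold = 1)
count_expressed_intersection <- function(fpkm, lines, threshold = 1,
                                         comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  if (length(lines) < 1L) stop("need at least one cell line")
  unknown <- setdiff(lines, names(fpkm))
  if (length(unknown))
    stop("unknown cell line(s): ", paste(unknown, collapse = ", "))
  pass <- vapply(lines, function(l)
    .fpkm_compare(fpkm[[l]], threshold, comparator), logical(nrow(fpkm)))
  pass <- matrix(pass, nrow = nrow(fpkm))
  sum(rowSums(pass) == length(lines))
}

#' Screen-level false-positive and false-negative rate estimates
#'
#' Treats category-3 genes (a single scoring reagent, unconfirmed by any
#' sibling reagent) as presumptive false positives and the non-scoring
#' reagents of category-1/2 genes (confirmed hits) as presumptive false
#' negatives:
#'
#' * `fp_reagent_rate` — category-3 genes / total reagents screened;
#' * `fp_hit_fraction` — category-3 genes / genes with any scoring reagent;
#' * `fn_reagent_rate` — non-scoring reagents of category-1/2 genes /
#'   reagents of category-1/2 genes.
#'
#' @param categories data.frame from [assign_gene_categories()].
#' @param library_size total number of reagents screened (>= the reagents
#'   represented in `categories`).
#' @return list of the three rates plus their underlying counts.
#' @export
estimate_screen_rates <- function(categories, library_size) {
  if (length(library_size) != 1L || library_size < 1)
    stop("library_size must be a positive count")
  n_cat <- function(k) sum(categories$category == k)
  n1 <- n_cat("1"); n2 <- n_cat("2"); n3 <- n_cat("3")
  n_hit_genes <- n1 + n2 + n3
  if (n_hit_genes == 0L) stop("no gene with a scoring reagent")
  c12 <- categories$category %in% c("1", "2")
  reag12 <- sum(categories$n_reagents[c12])
  nonscoring12 <- sum(categories$n_reagents[c12] - categories$n_scoring[c12])
  if (library_size < sum(categories$n_scoring))
    stop("library_size smaller than the number of scoring reagents")
  list(
    n_category_1 = n1, n_category_2 = n2, n_category_3 = n3,
    n_hit_genes = n_hit_genes,
    fp_reagent_rate = n3 / library_size,
    fp_hit_fraction = n3 / n_hit_genes,
    fn_reagent_rate = if (reag12 > 0) nonscoring12 / reag12 else NA_real_,
    n_reagents_cat12 = reag12,
    n_nonscoring_cat12 = nonscoring12,
    library_size = as.integer(library_size)
  )
}
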