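# Cross-screen phenotype-profile clustering, consensus screen signatures,
# multi-reagent concordance classification and reagent-level false-negative
# rate estimation.

#' Pearson similarity between two Z-score profiles
#'
#' Standard Pearson correlation over the screens where both profiles have a
#' value (pairwise-complete).  Requires at least `min_shared` shared
#' positions and nonzero variance in both profiles over the shared set.
#'
#' @param a,b numeric profiles of equal length, `NA` allowed.
#' @param min_shared minimum number of shared non-missing positions.
#' @return correlation in `[-1, 1]`.
#' @export
#' @examples
#' profile_cor(c(1, 2, 3, 4), c(2, 4, 6, 8))   # 1
#' profile_cor(c(1, -1, 1, -1), c(1, 1, -1, -1)) # 0
profile_cor <- function(a, b, min_shared = 3L) {
  if (length(a) != length(b)) stop("profiles differ in length")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < min_shared)
    stop("correlation undefined: fewer than ", min_shared,
         " shared screen values")
  if (var(a[ok]) == 0 || var(b[ok]) == 0)
    stop("correlation undefined: zero variance over shared screens")
  cor(a[ok], b[ok])
}

# Pairwise-complete 1 - r distance matrix; rows that cannot be correlated
# with the rest (too few shared screens, or no variance) are dropped with a
# warning, most-offending row first, until the matrix is complete.
.correlation_distance <- function(zmat, min_shared = 3L) {
  n_shared <- crossprod(!is.na(t(zmat)) * 1)
  suppressWarnings(r <- cor(t(zmat), use = "pairwise.complete.obs"))
  r[n_shared < min_shared] <- NA
  diag(r) <- 1
  while (anyNA(r) && nrow(r) > 2L) {
    bad <- which.max(rowSums(is.na(r)))
    warning("excluding profile '", rownames(r)[bad],
            "' from clustering: undefined correlation with other profiles",
            call. = FALSE)
    r <- r[-bad, -bad, drop = FALSE]
  }
  if (anyNA(r))
    stop("profiles cannot be correlated: too few shared screens or no variance")
  1 - r
}

#' Average-linkage hierarchical clustering of reagent profiles
#'
#' Clusters the rows of a Z-score profile matrix with distance
#' `1 - Pearson r` (pairwise-complete over shared screens) and average
#' linkage (UPGMA).  Rows whose correlation with the remaining rows is
#' undefined — fewer than `min_shared` shared screens, or a constant
#' profile — are excluded with a warning.  The result is deterministic for
#' a given row order.
#'
#' @param zmat numeric matrix from [assemble_profile_matrix()] (reagents in
#'   rows, screens in columns, row names required).
#' @param min_shared minimum shared non-missing screens per profile pair.
#' @return An [stats::hclust] object; `$merge` and `$height` give the merge
#'   list, `$labels` the reagent ids that survived the preconditions.
#' @seealso [extract_clusters()], [write_dendrogram_newick()]
#' @export
cluster_profiles <- function(zmat, min_shared = 3L) {
  if (is.null(rownames(zmat))) stop("profile matrix must have row names")
  if (nrow(zmat) < 2L) stop("need at least 2 profiles to cluster")
  d <- .correlation_distance(zmat, min_shared)
  hclust(as.dist(d), method = "average")
}

#' Cut a dendrogram into clusters at a correlation-distance height
#'
#' Members merged at distance `<= cut_height` form one cluster; cutting
#' below the first merge gives all singletons, cutting above the last merge
#' gives a single cluster.
#'
#' @param hc an [stats::hclust] object from [cluster_profiles()].
#' @param cut_height correlation distance (`1 - r`); the default 0.5
#'   corresponds to `r = 0.5`.
#' @return named integer vector of cluster ids, one per leaf.
#' @export
extract_clusters <- function(hc, cut_height = 0.5) {
  stopifnot(inherits(hc, "hclust"), cut_height >= 0)
  cutree(hc, h = cut_height)
}

#' Consensus screen signature of a cluster
#'
#' The per-screen arithmetic mean Z-score over the member reagents,
#' ignoring missing entries.
#'
#' @param members character vector of member reagent ids (non-empty).
#' @param zmat the Z-score profile matrix.
#' @return named numeric vector, one value per screen column.
#' @export
#' @examples
#' m <- rbind(a = c(1, 3), b = c(3, 1))
#' consensus_signature(c("a", "b"), m)  # 2 2
consensus_signature <- function(members, zmat) {
  if (length(members) == 0L) stop("empty member set")
  missing_m <- setdiff(members, rownames(zmat))
  if (length(missing_m))
    stop("members absent from matrix: ", paste(missing_m, collapse = ", "))
  colMeans(zmat[members, , drop = FALSE], na.rm = TRUE)
}

# Majority annotation label among the genes of the member reagents;
# ties broken lexicographically, NA if no member gene is annotated.
.cluster_label <- function(members, map, annotation) {
  genes <- map$gene_id[match(members, map$reagent_id)]
  labels <- annotation$set_label[match(genes, annotation$gene_id)]
  labels <- labels[!is.na(labels)]
  if (!length(labels)) return(NA_character_)
  tab <- table(labels)
  names(tab)[order(-tab, names(tab))][1L]
}

#' Classify multi-reagent genes against a signature cluster
#'
#' For every gene with at least two reagents in the profile matrix, flags
#' each reagent as *in* the given cluster (cluster membership **and**
#' correlation of at least `r_threshold` to the cluster's consensus
#' signature) and classifies the gene:
#'
#' * `concordant_in` — every reagent in the cluster;
#' * `concordant_out` — no reagent in the cluster;
#' * `discordant` — a mix.
#'
#' Discordant genes are attributed: `false_negative` when the gene's
#' annotation matches the cluster's majority set label (the out-of-cluster
#' reagent failed to knock down), `false_positive` when it does not match
#' (the in-cluster reagent is spurious, e.g. off-target), and `ambiguous`
#' when the gene is unannotated.
#'
#' @param membership named cluster-id vector from [extract_clusters()].
#' @param zmat the Z-score profile matrix.
#' @param map data.frame `reagent_id`, `gene_id`.
#' @param annotation data.frame `gene_id`, `set_label`.
#' @param cluster the cluster id (a value of `membership`) to test against.
#' @param r_threshold minimum correlation to the consensus signature for a
#'   reagent to count as in-cluster.
#' @return list with `calls` (per gene: `gene_id`, `n_reagents`, `n_in`,
#'   `classification`, `attribution`), `reagents` (per reagent:
#'   `in_cluster`, `r_consensus`), `cluster` and `label`.
#' @export
classify_multireagent_genes <- function(membership, zmat, map, annotation,
                                        cluster, r_threshold = 0.5) {
  members <- names(membership)[membership == cluster]
  if (!length(members)) stop("cluster ", cluster, " has no members")
  cons <- consensus_signature(members, zmat)
  label <- .cluster_label(members, map, annotation)

  reagents <- intersect(rownames(zmat), map$reagent_id)
  genes <- map$gene_id[match(reagents, map$reagent_id)]
  if (anyNA(genes)) stop("reagent(s) missing from the reagent map")
  multi <- names(which(table(genes) >= 2L))

  keep <- genes %in% multi
  reagents <- reagents[keep]
  genes <- genes[keep]
  r_cons <- vapply(reagents, function(rg) {
    tryCatch(profile_cor(zmat[rg, ], cons), error = function(e) NA_real_)
  }, numeric(1))
  in_cluster <- reagents %in% members & !is.na(r_cons) & r_cons >= r_threshold

  per_gene <- lapply(split(seq_along(reagents), genes), function(idx) {
    n_in <- sum(in_cluster[idx])
    n <- length(idx)
    cls <- if (n_in == n) "concordant_in"
           else if (n_in == 0L) "concordant_out"
           else "discordant"
    attr_ <- NA_character_
    if (cls == "discordant") {
      g_label <- annotation$set_label[match(genes[idx][1L], annotation$gene_id)]
      attr_ <- if (is.na(g_label) || is.na(label)) "ambiguous"
               else if (g_label == label) "false_negative"
               else "false_positive"
    }
    data.frame(gene_id = genes[idx][1L], n_reagents = n, n_in = n_in,
               classification = cls, attribution = attr_,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, per_gene)
  rownames(calls) <- NULL
  list(calls = calls,
       reagents = data.frame(reagent_id = reagents, gene_id = genes,
                             in_cluster = in_cluster, r_consensus = r_cons,
                             stringsAsFactors = FALSE),
       cluster = cluster, label = label)
}

#' Reagent-level false-negative rate from concordance calls
#'
#' The numerator counts the out-of-cluster reagents of discordant genes
#' attributed `false_negative`; the denominator is the caller-supplied
#' total reagent count of the gene set under audit (e.g. all reagents of
#' multi-reagent genes represented in the signature clusters).
#'
#' @param calls the `calls` data.frame from
#'   [classify_multireagent_genes()], or any data.frame with `n_reagents`,
#'   `n_in`, `classification` and `attribution` columns.
#' @param total_reagents denominator (must be >= 1).
#' @return list with `n_false_negative`, `n_reagents`, `rate` and the exact
#'   binomial 95% `conf_int`.
#' @export
#' @examples
#' calls <- data.frame(n_reagents = 2, n_in = 1,
#'                     classification = "discordant",
#'                     attribution = "false_negative")
#' estimate_cluster_fn_rate(calls[rep(1, 8), ], total_reagents = 103)$rate
estimate_cluster_fn_rate <- function(calls, total_reagents) {
  if (length(total_reagents) != 1L || total_reagents < 1)
    stop("total_reagents must be a positive count")
  disc <- calls$classification == "discordant" &
    !is.na(calls$attribution) & calls$attribution == "false_negative"
  n_fn <- sum(calls$n_reagents[disc] - calls$n_in[disc])
  ci <- binom.test(n_fn, total_reagents)$conf.int
  list(n_false_negative = n_fn,
       n_reagents = as.integer(total_reagents),
       rate = n_fn / total_reagents,
       conf_int = as.numeric(ci))
}

#' Pooled non-signature rate over gene sets
#'
#' Pools counts of genes that failed to show their set's screen signature:
#' the sum of the numerators over the sum of the set sizes.  With the
#' cytosolic-ribosome and proteasome sets this is the upper, set-level
#' false-negative estimate that also counts genes that never scored.
#'
#' @param set_counts data.frame (or 2-column matrix) with columns
#'   `n_nonsignature` and `set_size`.
#' @return list with `n_nonsignature`, `n_genes` and `rate`.
#' @export
#' @examples
#' pooled_nonsignature_rate(
#'   data.frame(n_nonsignature = c(22, 29), set_size = c(94, 58)))$rate
pooled_nonsignature_rate <- function(set_counts) {
  set_counts <- as.data.frame(set_counts)
  if (nrow(set_counts) == 0L) stop("no gene sets supplied")
  if (!all(c("n_nonsignature", "set_size") %in% names(set_counts)))
    stop("set_counts needs columns n_nonsignature and set_size")
  if (any(set_counts$n_nonsignature > set_counts$set_size))
    stop("a non-signature count exceeds its set size")
  num <- sum(set_counts$n_nonsignature)
  den <- sum(set_counts$set_size)
  list(n_nonsignature = num, n_genes = den, rate = num / den)
}

#' Magnitude-based concordance audit
#'
#' Alternative to the correlation route of [audit_fn_rate()] for the
#' noiseless / near-noiseless regime, where per-plate Z-normalization
#' leaves every profile constant across screens and Pearson correlation is
#' undefined.  A reagent *shows the signature* when `|Z| >= z_threshold`
#' in at least `min_frac` of its non-missing screens; genes of the
#' annotated signature set with at least two reagents are classified
#' concordant/discordant on that flag, and the false-negative rate is the
#' fraction of non-showing reagents among genes with at least one showing
#' reagent.
#'
#' @inheritParams audit_fn_rate
#' @param z_threshold absolute Z cutoff for "shows the signature".
#' @param min_frac minimum fraction of screens above the cutoff.
#' @return list with `n_false_negative`, `n_reagents`, `rate`, `conf_int`
#'   and per-gene `calls`.
#' @export
magnitude_concordance <- function(zmat, map, annotation,
                                  labels = unique(annotation$set_label),
                                  z_threshold = 2, min_frac = 0.5) {
  sig_genes <- annotation$gene_id[annotation$set_label %in% labels]
  genes <- map$gene_id[match(rownames(zmat), map$reagent_id)]
  keep <- !is.na(genes) & genes %in% sig_genes
  reagents <- rownames(zmat)[keep]
  genes <- genes[keep]
  multi <- names(which(table(genes) >= 2L))
  keep2 <- genes %in% multi
  reagents <- reagents[keep2]
  genes <- genes[keep2]
  if (!length(reagents))
    return(list(n_false_negative = 0L, n_reagents = 0L, rate = NA_real_,
                conf_int = c(NA_real_, NA_real_), calls = NULL))
  shows <- vapply(reagents, function(rg) {
    z <- zmat[rg, ]
    z <- z[is.finite(z)]
    length(z) > 0L && mean(abs(z) >= z_threshold) >= min_frac
  }, logical(1))
  per_gene <- lapply(split(shows, genes), function(s) {
    data.frame(n_reagents = length(s), n_in = sum(s),
               classification = if (all(s)) "concordant_in"
                                else if (!any(s)) "concordant_out"
                                else "discordant",
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, per_gene)
  calls$gene_id <- names(per_gene)
  audited <- calls[calls$n_in >= 1L, , drop = FALSE]
  n_fn <- sum(audited$n_reagents - audited$n_in)
  n_total <- sum(audited$n_reagents)
  ci <- if (n_total > 0) as.numeric(binom.test(n_fn, n_total)$conf.int)
        else c(NA_real_, NA_real_)
  list(n_false_negative = n_fn, n_reagents = n_total,
       rate = if (n_total > 0) n_fn / n_total else NA_real_,
       conf_int = ci, calls = calls)
}

#' Full clustering-based false-negative audit of a profile matrix
#'
#' Composes the signature workflow: cluster the profiles, cut at
#' `cut_height`, locate for each annotation set label the largest cluster
#' whose majority label matches, classify that cluster's multi-reagent
#' genes, and pool false-negative counts across set labels.  A gene enters
#' the audited denominator when it is annotated (in any audited set — the
#' audit mirrors a curated-gene-set analysis, so unannotated genes carried
#' into a cluster by off-target reagents are out of scope) and at least
#' one of its reagents is in the signature cluster.  A gene whose reagents
#' all failed is not counted here; see [pooled_nonsignature_rate()] for
#' the set-level view.
#'
#' @param zmat Z-score profile matrix.
#' @param map data.frame `reagent_id`, `gene_id`.
#' @param annotation data.frame `gene_id`, `set_label`.
#' @param labels set labels to audit (default: all labels in `annotation`).
#' @param cut_height dendrogram cut, correlation distance.
#' @param r_threshold consensus-correlation threshold for in-cluster.
#' @param min_cluster_size smallest cluster considered a signature cluster.
#' @return list with pooled `n_false_negative`, `n_reagents`, `rate`,
#'   `conf_int`, and `per_label` detail (one
#'   [classify_multireagent_genes()] result per audited label).
#' @export
audit_fn_rate <- function(zmat, map, annotation,
                          labels = unique(annotation$set_label),
                          cut_height = 0.5, r_threshold = 0.5,
                          min_cluster_size = 3L) {
  hc <- cluster_profiles(zmat)
  membership <- extract_clusters(hc, cut_height)
  sizes <- table(membership)
  candidates <- as.integer(names(sizes)[sizes >= min_cluster_size])
  cluster_labels <- vapply(candidates, function(cl) {
    .cluster_label(names(membership)[membership == cl], map, annotation)
  }, character(1))

  n_fn <- 0L
  n_total <- 0L
  per_label <- list()
  for (lab in labels) {
    match_cl <- candidates[!is.na(cluster_labels) & cluster_labels == lab]
    if (!length(match_cl)) next
    cl <- match_cl[which.max(sizes[as.character(match_cl)])]
    res <- classify_multireagent_genes(membership, zmat, map, annotation,
                                       cluster = cl,
                                       r_threshold = r_threshold)
    audited <- res$calls[res$calls$n_in >= 1L &
                           res$calls$gene_id %in% annotation$gene_id, ,
                         drop = FALSE]
    fn <- audited$classification == "discordant" &
      !is.na(audited$attribution) & audited$attribution == "false_negative"
    n_fn <- n_fn + sum(audited$n_reagents[fn] - audited$n_in[fn])
    n_total <- n_total + sum(audited$n_reagents)
    res$audited_genes <- audited$gene_id
    per_label[[lab]] <- res
  }
  if (n_total == 0L)
    stop("no signature cluster found for the requested labels")
  ci <- binom.test(n_fn, n_total)$conf.int
  list(n_false_negative = n_fn, n_reagents = n_total,
       rate = n_fn / n_total, conf_int = as.numeric(ci),
       per_label = per_label)
}
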