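# Synthetic screens, reagent libraries and expression tables with known
# ground truth.  These emulate the statistical structure of DRSC-style
# Drosophila cell screens: 384-well plates with an empty outer perimeter,
# 1-4 long-dsRNA reagents per gene, a set of true-hit genes whose effective
# reagents shift the plate Z-score, per-reagent inefficacy (rate r_fn) and
# off-target activity (rate r_fp), and per-screen Gaussian noise.

#' Parameters for a synthetic multi-screen RNAi experiment
#'
#' Bundles and validates every knob of the screen simulator.  The defaults
#' describe a focused sub-library experiment: 384-well plates (16 x 24)
#' whose outer perimeter is left empty to buffer edge effects, two reagents
#' per gene, and a negative effect size (knockdown of a true hit lowers the
#' readout, as for canonical pathway components scoring at Z below -4).
#'
#' Screens in a meta-analysis differ sharply in how strongly a phenotype
#' signature manifests: a knockdown that abolishes viability dominates one
#' assay and barely registers in another.  The simulator models this with a
#' per-screen effect weight `w_s`, drawn once per simulation: with
#' probability `screen_responsive_prob` the screen is *responsive* and
#' `w_s ~ Uniform(1 - screen_effect_spread, 1 + screen_effect_spread)`;
#' otherwise it is nearly silent,
#' `w_s ~ Uniform(0, 0.1)`.  An active reagent's mean shift in screen `s`
#' is `effect_size * w_s`, so `effect_size` is the typical shift in a
#' responsive screen, and the contrast between responsive and silent
#' screens is what gives functionally related reagents a correlated
#' "screen signature".  Set `screen_responsive_prob = 1` and
#' `screen_effect_spread = 0` for an identical response in every screen.
#'
#' @param n_genes number of genes in the library.
#' @param n_true_hits number of genes planted as true hits (`H`).
#' @param reagents_per_gene either a single count in 1..4 or an integer
#'   vector of length `n_genes` with per-gene reagent counts in 1..4.
#' @param reagent_fn_rate probability that a reagent is generated as
#'   ineffective (`r_fn`); an ineffective reagent on a true-hit gene never
#'   shows the phenotype.
#' @param reagent_fp_rate probability that a reagent is generated as
#'   off-target active (`r_fp`); such a reagent shows the phenotype
#'   regardless of its target gene.
#' @param effect_size mean Z-unit shift produced by an active reagent;
#'   negative by default.
#' @param noise_sd standard deviation of the per-well Gaussian noise, in
#'   raw assay units (the baseline is 0, so these behave as Z-units).
#' @param n_screens number of independent screens.
#' @param n_replicates number of replicates per screen.
#' @param plate_rows,plate_cols plate dimensions (default 16 x 24 = 384).
#' @param perimeter_empty leave the outer ring of wells empty (`TRUE`) or
#'   use the full plate for samples.
#' @param screen_responsive_prob probability that a screen responds to the
#'   planted signature (see Details); in `(0, 1]`.
#' @param screen_effect_spread half-width of the responsive-screen effect
#'   weight distribution (see Details); in `[0, 1)`.
#' @param baseline raw value of a phenotype-free well.
#' @param seed integer seed; identical parameters and seed give
#'   bit-identical output.
#'
#' @return A validated list of class `"sim_params"`.
#' @seealso [generate_library()], [generate_screen_plates()]
#' @export
#' @examples
#' p <- sim_params(n_genes = 50, n_true_hits = 5, seed = 1)
sim_params <- function(n_genes,
                       n_true_hits,
                       reagents_per_gene = 2L,
                       reagent_fn_rate = 0,
                       reagent_fp_rate = 0,
                       effect_size = -5,
                       noise_sd = 1,
                       n_screens = 16L,
                       n_replicates = 1L,
                       plate_rows = 16L,
                       plate_cols = 24L,
                       perimeter_empty = TRUE,
                       screen_responsive_prob = 0.6,
                       screen_effect_spread = 0.3,
                       baseline = 0,
                       seed = 1L) {
  stopifnot(length(n_genes) == 1L, n_genes >= 1,
            length(n_true_hits) == 1L, n_true_hits >= 0)
  if (n_true_hits > n_genes)
    stop("n_true_hits must not exceed n_genes")
  for (p in c(reagent_fn_rate, reagent_fp_rate)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("reagent_fn_rate and reagent_fp_rate must be probabilities in [0, 1]")
  }
  if (!is.numeric(screen_effect_spread) || screen_effect_spread < 0 ||
      screen_effect_spread >= 1)
    stop("screen_effect_spread must be in [0, 1)")
  if (!is.numeric(screen_responsive_prob) || screen_responsive_prob <= 0 ||
      screen_responsive_prob > 1)
    stop("screen_responsive_prob must be in (0, 1]")
  if (length(reagents_per_gene) == 1L)
    reagents_per_gene <- rep.int(as.integer(reagents_per_gene), n_genes)
  if (length(reagents_per_gene) != n_genes)
    stop("reagents_per_gene must be scalar or length n_genes")
  if (any(reagents_per_gene < 1L) || any(reagents_per_gene > 4L))
    stop("reagents_per_gene values must be in 1..4")
  stopifnot(plate_rows >= 1, plate_cols >= 1, n_screens >= 1,
            n_replicates >= 1, noise_sd >= 0)
  capacity <- .plate_capacity(plate_rows, plate_cols, perimeter_empty)
  if (capacity < 1L)
    stop("plate has no interior sample wells; enlarge plate_rows/plate_cols ",
         "or set perimeter_empty = FALSE")
  structure(list(
    n_genes = as.integer(n_genes),
    n_true_hits = as.integer(n_true_hits),
    reagents_per_gene = as.integer(reagents_per_gene),
    reagent_fn_rate = reagent_fn_rate,
    reagent_fp_rate = reagent_fp_rate,
    effect_size = effect_size,
    noise_sd = noise_sd,
    n_screens = as.integer(n_screens),
    n_replicates = as.integer(n_replicates),
    plate_rows = as.integer(plate_rows),
    plate_cols = as.integer(plate_cols),
    perimeter_empty = isTRUE(perimeter_empty),
    screen_responsive_prob = screen_responsive_prob,
    screen_effect_spread = screen_effect_spread,
    baseline = baseline,
    seed = as.integer(seed)
  ), class = "sim_params")
}

.plate_capacity <- function(rows, cols, perimeter_empty) {
  if (perimeter_empty) max(0L, (rows - 2L) * (cols - 2L)) else rows * cols
}

#' Generate a synthetic reagent library with ground truth
#'
#' Draws the reagent-to-gene map and the hidden truth table: which genes are
#' planted hits, which reagents are ineffective (probability `reagent_fn_rate`,
#' i.i.d.), and which carry off-target activity (probability
#' `reagent_fp_rate`, i.i.d. over all reagents, so an off-target reagent may
#' sit on a hit or a non-hit gene).  A reagent is *active* in the screens if
#' its gene is a hit and it is effective, or if it is off-target active.
#'
#' @param params a [sim_params()] object.
#' @return A list with `map` (data.frame `reagent_id`, `gene_id`) and
#'   `truth` (data.frame `reagent_id`, `gene_id`, `gene_is_hit`,
#'   `effective`, `off_target`).
#' @export
#' @examples
#' lib <- generate_library(sim_params(n_genes = 10, n_true_hits = 2, seed = 7))
#' table(lib$truth$gene_is_hit)
generate_library <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  gene_ids <- sprintf("g%05d", seq_len(params$n_genes))
  hit_genes <- sample(gene_ids, params$n_true_hits)
  k <- params$reagents_per_gene
  gene_of_reagent <- rep(gene_ids, times = k)
  reagent_ids <- paste0(gene_of_reagent, "_r",
                        unlist(lapply(k, seq_len), use.names = FALSE))
  n_r <- length(reagent_ids)
  map <- data.frame(reagent_id = reagent_ids, gene_id = gene_of_reagent,
                    stringsAsFactors = FALSE)
  truth <- data.frame(
    reagent_id = reagent_ids,
    gene_id = gene_of_reagent,
    gene_is_hit = gene_of_reagent %in% hit_genes,
    effective = rbinom(n_r, 1L, 1 - params$reagent_fn_rate) == 1L,
    off_target = rbinom(n_r, 1L, params$reagent_fp_rate) == 1L,
    stringsAsFactors = FALSE
  )
  list(map = map, truth = truth)
}

# Interior (sample) well coordinates in row-major order, then the perimeter.
.plate_layout <- function(rows, cols, perimeter_empty) {
  all_rc <- expand.grid(col = seq_len(cols), row = seq_len(rows))[, 2:1]
  on_edge <- all_rc$row %in% c(1L, rows) | all_rc$col %in% c(1L, cols)
  if (!perimeter_empty) on_edge[] <- FALSE
  list(sample = all_rc[!on_edge, , drop = FALSE],
       empty = all_rc[on_edge, , drop = FALSE])
}

#' Simulate raw plate readings for every screen and replicate
#'
#' Reagents fill the interior sample wells of consecutive plates in
#' row-major order.  A sample well's raw value is
#' `baseline + effect_size * w_s * active + N(0, noise_sd)`, where `w_s`
#' is the screen's responsiveness weight (see [sim_params()]) and `active` indicates
#' that the reagent shows the phenotype.  Activity flags are fixed across
#' screens — signatures are a property of the reagent, noise is the only
#' per-screen stochastic term.  Perimeter wells, when present, are emitted
#' with `well_role = "empty"`, a blank `reagent_id`, and baseline + noise.
#'
#' @param library,truth output of [generate_library()] (`map` and `truth`).
#' @param params the same [sim_params()] object used for the library.
#' @return data.frame with columns `screen_id`, `replicate`, `plate_id`,
#'   `row`, `col`, `well_role`, `reagent_id`, `value`.
#' @export
generate_screen_plates <- function(library, truth, params) {
  stopifnot(inherits(params, "sim_params"))
  if (!identical(library$reagent_id, truth$reagent_id) ||
      !identical(library$gene_id, truth$gene_id))
    stop("library map and truth table do not describe the same reagents")
  n_r <- nrow(library)
  capacity <- .plate_capacity(params$plate_rows, params$plate_cols,
                              params$perimeter_empty)
  n_plates <- ceiling(n_r / capacity)
  layout <- .plate_layout(params$plate_rows, params$plate_cols,
                          params$perimeter_empty)

  # deterministic derivation: screen weights and noise use seed + 1 so the
  # library draw (seed) and the plate draw are independently reproducible
  set.seed(params$seed + 1L)
  responsive <- runif(params$n_screens) < params$screen_responsive_prob
  w <- ifelse(responsive,
              1 + runif(params$n_screens, -1, 1) * params$screen_effect_spread,
              runif(params$n_screens, 0, 0.1))

  active <- (truth$gene_is_hit & truth$effective) | truth$off_target
  plate_of <- rep(seq_len(n_plates), each = capacity, length.out = n_r)
  idx_on_plate <- sequence(tabulate(plate_of, nbins = n_plates))
  sample_rows <- layout$sample$row[idx_on_plate]
  sample_cols <- layout$sample$col[idx_on_plate]

  n_empty <- nrow(layout$empty)
  out <- vector("list", params$n_screens * params$n_replicates)
  i <- 0L
  for (s in seq_len(params$n_screens)) {
    for (rep_j in seq_len(params$n_replicates)) {
      value <- params$baseline + params$effect_size * w[s] * active +
        rnorm(n_r, 0, params$noise_sd)
      rec <- data.frame(
        screen_id = sprintf("S%02d", s),
        replicate = rep_j,
        plate_id = sprintf("S%02d.%d.P%02d", s, rep_j, plate_of),
        row = sample_rows,
        col = sample_cols,
        well_role = "sample",
        reagent_id = library$reagent_id,
        value = value,
        stringsAsFactors = FALSE
      )
      if (n_empty > 0L) {
        emp <- data.frame(
          screen_id = sprintf("S%02d", s),
          replicate = rep_j,
          plate_id = sprintf("S%02d.%d.P%02d", s, rep_j,
                             rep(seq_len(n_plates), each = n_empty)),
          row = rep(layout$empty$row, times = n_plates),
          col = rep(layout$empty$col, times = n_plates),
          well_role = "empty",
          reagent_id = "",
          value = params$baseline +
            rnorm(n_empty * n_plates, 0, params$noise_sd),
          stringsAsFactors = FALSE
        )
        rec <- rbind(rec, emp)
      }
      i <- i + 1L
      out[[i]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Simulate a gene-level FPKM expression table
#'
#' Emulates Cufflinks-style gene-level FPKM output for a panel of cell
#' lines.  Per line, each gene is independently expressed with probability
#' `expressed_fraction`; expressed genes draw FPKM from
#' `Lognormal(meanlog, sdlog)` and unexpressed genes draw uniformly on
#' `[0, unexpressed_fpkm_max)`.
#'
#' @param genes character vector of gene ids (non-empty).
#' @param cell_lines labels for the columns.
#' @param expressed_fraction probability a gene is expressed in a line;
#'   either scalar or one value per line.
#' @param meanlog,sdlog log-FPKM location and scale for expressed genes.
#' @param unexpressed_fpkm_max upper bound of the unexpressed draw.
#' @param seed integer seed.
#' @return data.frame with `gene_id` and one numeric FPKM column per line.
#' @export
#' @examples
#' fpkm <- generate_expression_table(sprintf("g%03d", 1:20),
#'   cell_lines = c("S2R+", "Kc167"), expressed_fraction = 0.5, seed = 3)
generate_expression_table <- function(genes,
                                      cell_lines = c("Kc167", "Clone8", "S2",
                                                     "BG3", "S2R+"),
                                      expressed_fraction = 0.53,
                                      meanlog = 3,
                                      sdlog = 1.5,
                                      unexpressed_fpkm_max = 1,
                                      seed = 1L) {
  if (length(genes) == 0L) stop("gene list is empty")
  stopifnot(length(cell_lines) >= 1L, unexpressed_fpkm_max >= 0)
  if (length(expressed_fraction) == 1L)
    expressed_fraction <- rep(expressed_fraction, length(cell_lines))
  if (length(expressed_fraction) != length(cell_lines))
    stop("expressed_fraction must be scalar or one value per cell line")
  if (any(expressed_fraction < 0) || any(expressed_fraction > 1))
    stop("expressed_fraction must be in [0, 1]")
  set.seed(seed)
  n <- length(genes)
  out <- data.frame(gene_id = as.character(genes), stringsAsFactors = FALSE)
  for (j in seq_along(cell_lines)) {
    expressed <- rbinom(n, 1L, expressed_fraction[j]) == 1L
    fpkm <- numeric(n)
    fpkm[expressed] <- rlnorm(sum(expressed), meanlog, sdlog)
    fpkm[!expressed] <- runif(sum(!expressed), 0, unexpressed_fpkm_max)
    out[[cell_lines[j]]] <- fpkm
  }
  out
}
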