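# Per-plate Z-score normalization and assembly of the reagent-by-screen
# profile matrix.

#' Per-plate Z-scores
#'
#' Computes `Z = (x - mu) / sigma` for every sample well of one plate,
#' where `mu` and `sigma` are taken over the plate's sample wells only:
#' empty perimeter wells and control wells carry no reagent and are kept out
#' of the plate statistics (controls can be included with
#' `include_controls = TRUE`).  `sigma` defaults to the sample (n - 1)
#' standard deviation, so three wells at 10/20/30 score exactly -1/0/+1;
#' `sd_type = "population"` divides by n instead.
#'
#' @param readings data.frame of plate readings for a single plate, with
#'   columns `row`, `col`, `well_role` (`sample`/`empty`/`control`),
#'   `reagent_id` and `value`.
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @param include_controls also use control wells for `mu` and `sigma`.
#' @return The input data.frame with an added numeric `z` column; wells
#'   that did not enter the statistics (empty, and controls unless
#'   included) get `NA`.
#' @export
#' @examples
#' p <- data.frame(row = 1, col = 1:3, well_role = "sample",
#'                 reagent_id = c("a", "b", "c"), value = c(10, 20, 30))
#' plate_zscores(p)$z
plate_zscores <- function(readings, sd_type = c("sample", "population"),
                          include_controls = FALSE) {
  sd_type <- match.arg(sd_type)
  required <- c("row", "col", "well_role", "reagent_id", "value")
  missing_cols <- setdiff(required, names(readings))
  if (length(missing_cols))
    stop("plate readings lack column(s): ", paste(missing_cols, collapse = ", "))
  use <- readings$well_role == "sample"
  if (include_controls) use <- use | readings$well_role == "control"
  x <- readings$value[use]
  if (length(x) < 3L)
    stop("plate has fewer than 3 wells available for normalization")
  mu <- mean(x)
  sigma <- if (sd_type == "sample") sd(x) else
    sqrt(mean((x - mu)^2))
  if (!is.finite(sigma) || sigma <= 0)
    stop("degenerate plate: zero spread among normalization wells")
  z <- rep(NA_real_, nrow(readings))
  z[use] <- (readings$value[use] - mu) / sigma
  readings$z <- z
  readings
}

#' Normalize every plate of a multi-screen reading table
#'
#' Splits the readings by screen, replicate and plate, applies
#' [plate_zscores()] to each plate, and returns the readings with the `z`
#' column filled in.
#'
#' @inheritParams plate_zscores
#' @param readings data.frame with additionally `screen_id`, `replicate`
#'   and `plate_id` columns (the format written by
#'   [generate_screen_plates()] / read by [read_plate_table()]).
#' @return The readings with a `z` column.
#' @export
normalize_plates <- function(readings, sd_type = c("sample", "population"),
                             include_controls = FALSE) {
  sd_type <- match.arg(sd_type)
  key <- paste(readings$screen_id, readings$replicate, readings$plate_id,
               sep = "\r")
  parts <- split(readings, factor(key, levels = unique(key)))
  parts <- lapply(parts, plate_zscores, sd_type = sd_type,
                  include_controls = include_controls)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Assemble the reagent-by-screen Z-score profile matrix
#'
#' Takes normalized readings (or a list of them, one per screen) and builds
#' the matrix with one row per reagent and one column per screen/replicate,
#' in input order.  A reagent absent from a screen yields a missing entry;
#' missing values are never imputed.  Columns are labeled
#' `"<screen_id>.<replicate>"` and the screen/replicate pairing is kept in
#' the `"screens"` attribute.
#'
#' @param readings normalized readings with a `z` column, or a list of such
#'   data.frames which are concatenated.
#' @return numeric matrix with reagent row names; attribute `screens` is a
#'   data.frame (`column`, `screen_id`, `replicate`).
#' @export
assemble_profile_matrix <- function(readings) {
  if (is.list(readings) && !is.data.frame(readings))
    readings <- do.call(rbind, readings)
  if (!"z" %in% names(readings))
    stop("readings carry no 'z' column; run normalize_plates() first")
  smp <- readings[readings$well_role == "sample" & nzchar(readings$reagent_id),
                  , drop = FALSE]
  col_key <- paste(smp$screen_id, smp$replicate, sep = ".")
  cols <- unique(col_key)
  rows <- unique(smp$reagent_id)
  dup <- duplicated(paste(col_key, smp$reagent_id, sep = "\r"))
  if (any(dup)) {
    d <- smp[dup, ][1L, ]
    stop("reagent '", d$reagent_id, "' appears more than once in screen ",
         d$screen_id, " replicate ", d$replicate)
  }
  mat <- matrix(NA_real_, nrow = length(rows), ncol = length(cols),
                dimnames = list(rows, cols))
  mat[cbind(match(smp$reagent_id, rows), match(col_key, cols))] <- smp$z
  first <- !duplicated(col_key)
  attr(mat, "screens") <- data.frame(column = cols,
                                     screen_id = smp$screen_id[first],
                                     replicate = smp$replicate[first],
                                     stringsAsFactors = FALSE)
  mat
}
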