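# Readers and writers for the package's plain-text dialects: plate
# readings, Z-score matrices, reagent maps, annotations, FPKM tables (all
# TSV, UTF-8, '.' decimal, missing = empty field), dendrograms as Newick,
# and reports as JSON.

.plate_columns <- c("screen_id", "replicate", "plate_id", "row", "col",
                    "well_role", "reagent_id", "value")

#' Read a plate-readings table
#'
#' Reads the TSV plate dialect (columns `screen_id`, `replicate`,
#' `plate_id`, `row`, `col`, `well_role`, `reagent_id`, `value`) with
#' validation: schema, numeric values, positive integer coordinates,
#' reagent ids on sample wells, and no duplicated wells.  Errors name the
#' offending file line (header = line 1).
#'
#' @param path file path.
#' @return typed data.frame of plate readings.
#' @seealso [write_plate_table()]
#' @export
read_plate_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(.plate_columns, names(df))
  if (length(missing_cols))
    stop("plate table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  line <- seq_len(nrow(df)) + 1L
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) & !(df[[col]] %in% c("", "NA"))
    if (any(bad))
      stop("non-numeric ", col, " in ", path, " at line ",
           line[which(bad)[1L]])
    v
  }
  out <- data.frame(
    screen_id = df$screen_id,
    replicate = as.integer(num("replicate")),
    plate_id = df$plate_id,
    row = as.integer(num("row")),
    col = as.integer(num("col")),
    well_role = df$well_role,
    reagent_id = df$reagent_id,
    value = num("value"),
    stringsAsFactors = FALSE
  )
  if (any(bad <- !out$well_role %in% c("sample", "empty", "control")))
    stop("unknown well_role in ", path, " at line ", line[which(bad)[1L]])
  if (any(bad <- is.na(out$row) | is.na(out$col) | out$row < 1 | out$col < 1))
    stop("invalid well coordinates in ", path, " at line ",
         line[which(bad)[1L]])
  if (any(bad <- out$well_role == "sample" & !nzchar(out$reagent_id)))
    stop("sample well without reagent_id in ", path, " at line ",
         line[which(bad)[1L]])
  if (any(bad <- is.na(out$value) & out$well_role == "sample"))
    stop("missing value on sample well in ", path, " at line ",
         line[which(bad)[1L]])
  key <- paste(out$screen_id, out$replicate, out$plate_id, out$row, out$col)
  if (any(dup <- duplicated(key)))
    stop("duplicate well in ", path, " at line ", line[which(dup)[1L]])
  out
}

#' Write a plate-readings table
#' @param readings data.frame in the plate dialect.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(readings, path) {
  write.table(readings[, .plate_columns], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a Z-score profile matrix
#'
#' TSV with a leading `reagent_id` column and one column per
#' screen/replicate; missing entries are empty fields.  The round trip is
#' lossless.
#'
#' @param zmat numeric matrix with reagent row names.
#' @param path file path.
#' @return `write_zmatrix()`: `path`, invisibly; `read_zmatrix()`: the
#'   matrix.
#' @export
write_zmatrix <- function(zmat, path) {
  df <- data.frame(reagent_id = rownames(zmat), zmat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_zmatrix
#' @export
read_zmatrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = "")
  if (names(df)[1L] != "reagent_id")
    stop("Z-matrix file must start with a reagent_id column")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  mode(mat) <- "double"
  rownames(mat) <- df$reagent_id
  mat
}

#' Write a dendrogram as Newick
#'
#' Converts the merge tree to a phylogeny (branch lengths from merge
#' heights) and writes standard Newick, readable by any tree viewer.
#'
#' @param hc an [stats::hclust] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Read/write two-column id tables (reagent maps, annotations)
#'
#' Thin TSV helpers for the `reagent_id`/`gene_id` map and the
#' `gene_id`/`set_label` annotation table.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param columns required column names.
#' @return the data.frame (readers) or `path`, invisibly (writer).
#' @export
read_id_table <- function(path, columns) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(columns, names(df))
  if (length(missing_cols))
    stop(path, " lacks column(s): ", paste(missing_cols, collapse = ", "))
  df
}

#' @rdname read_id_table
#' @export
write_id_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an FPKM table
#'
#' TSV with `gene_id` plus one numeric column per cell line.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_fpkm_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(df)) stop(path, " lacks a gene_id column")
  for (cl in setdiff(names(df), "gene_id")) {
    if (!is.numeric(df[[cl]]))
      stop("non-numeric FPKM column '", cl, "' in ", path)
  }
  df
}

#' The packaged kinase/phosphatase JAK/STAT screen hit table
#'
#' Gene-level summary of a published kinase-and-phosphatase sub-library
#' reporter screen for JAK/STAT pathway components in S2R+ cells: for each
#' of the 24 hit genes, the number of dsRNA reagents screened, how many
#' scored (|Z| >= 2 in both replicates), the assigned category and whether
#' the gene is expressed in S2R+ cells.
#'
#' @return data.frame `gene_id`, `n_reagents`, `n_scoring`,
#'   `n_nonscoring`, `category`, `expressed`.
#' @export
#' @examples
#' kp <- kp_jakstat_hits()
#' table(kp$category)
kp_jakstat_hits <- function() {
  path <- system.file("extdata", "kp_jakstat_hits.tsv", package = "rnaiqc",
                      mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$category <- as.character(df$category)
  df$expressed <- df$expressed == "yes"
  df
}
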