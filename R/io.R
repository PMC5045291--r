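# strict CSV/TSV reader: header required, named columns checked
# (case-insensitive), errors name the offending column
.read_table <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  df
}

.check_numeric <- function(df, cols, path) {
  for (col in cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(path, ": unparseable value in column '", col, "', row ", bad[1])
    df[[col]] <- v
  }
  df
}

#' Read a titration CSV
#'
#' Accepts a `titrant_m`, `titrant_nm` or `titrant_um` concentration column
#' (converted to molar) and either an `r` (anisotropy) column or the four
#' polarized-intensity columns `i_vv`, `i_vh`, `i_hv`, `i_hh` (anisotropy is
#' then computed per row).
#'
#' @param path CSV/TSV file path.
#' @param labeled_conc Labeled-species concentration (M).
#' @param meta Optional metadata list.
#' @return A [titration_series()].
#' @export
read_titration <- function(path, labeled_conc, meta = list()) {
  df <- .read_table(path, required = character())
  unit_col <- intersect(c("titrant_m", "titrant_nm", "titrant_um"), names(df))
  if (!length(unit_col))
    stop(path, ": need a titrant_M, titrant_nM or titrant_uM column")
  df <- .check_numeric(df, unit_col[1], path)
  scale <- c(titrant_m = 1, titrant_nm = 1e-9, titrant_um = 1e-6)[[unit_col[1]]]
  b <- df[[unit_col[1]]] * scale
  if ("r" %in% names(df)) {
    df <- .check_numeric(df, "r", path)
    sig <- df$r
  } else {
    pol <- c("i_vv", "i_vh", "i_hv", "i_hh")
    if (!all(pol %in% names(df)))
      stop(path, ": need column 'r' or the four intensity columns ",
           paste(pol, collapse = ", "))
    df <- .check_numeric(df, pol, path)
    sig <- mapply(anisotropy, df$i_vv, df$i_vh, df$i_hv, df$i_hh)
  }
  ord <- order(b)
  titration_series(labeled_conc, b[ord], sig[ord], meta = meta)
}

#' Read an emission spectrum CSV
#'
#' Expects columns `wavelength_nm` and `intensity`; a long-format file with
#' a `series` column can be subset with the `series` argument.
#'
#' @param path CSV/TSV file path.
#' @param series Optional series label to select from a long-format file.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, series = NULL) {
  df <- .read_table(path, required = c("wavelength_nm", "intensity"))
  if (!is.null(series)) {
    if (!"series" %in% names(df)) stop(path, ": no 'series' column")
    df <- df[df$series == series, , drop = FALSE]
    if (!nrow(df)) stop(path, ": no rows for series '", series, "'")
  }
  df <- .check_numeric(df, c("wavelength_nm", "intensity"), path)
  ord <- order(df$wavelength_nm)
  spectrum(df$wavelength_nm[ord], df$intensity[ord])
}

#' Read a peptide deuterium-uptake table
#'
#' DynamX-export-like layout: one row per peptide per exposure, columns
#' `protein`, `start`, `end`, `sequence`, `exposure_min`, `uptake_da`.
#'
#' @param path CSV/TSV file path.
#' @return List of [peptide_uptake()] records.
#' @export
read_uptake_table <- function(path) {
  df <- .read_table(path, required = c("protein", "start", "end", "sequence",
                                       "exposure_min", "uptake_da"))
  df <- .check_numeric(df, c("start", "end", "exposure_min", "uptake_da"), path)
  key <- paste(df$protein, df$start, df$end, df$sequence, sep = "|")
  lapply(split(seq_len(nrow(df)), key)[unique(key)], function(rows) {
    sub <- df[rows, , drop = FALSE]
    if (anyDuplicated(sub$exposure_min))
      stop(path, ": duplicate exposure for peptide ",
           sub$protein[1], " ", sub$start[1], "-", sub$end[1])
    peptide_uptake(sub$protein[1], sub$start[1], sub$end[1], sub$sequence[1],
                   stats::setNames(sub$uptake_da, sub$exposure_min))
  })
}

#' Read a cross-link result table
#'
#' Search-engine-export-like layout with columns `protein_a`, `res_a`,
#' `protein_b`, `res_b`, `chemistry`, `score`, `expect`.
#'
#' @param path CSV/TSV file path.
#' @return A validated cross-link data frame.
#' @export
read_crosslinks <- function(path) {
  df <- .read_table(path, required = c("protein_a", "res_a", "protein_b",
                                       "res_b", "chemistry", "score", "expect"))
  df <- .check_numeric(df, c("res_a", "res_b", "score", "expect"), path)
  crosslink_records(df)
}

#' Read a FASTA file of protein sequences
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop(path, ": no FASTA headers")
  names_out <- sub("^>\\s*(\\S+).*", "\\1", lines[hdr])
  bounds <- c(hdr, length(lines) + 1L)
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = "")
  }, character(1))
  stats::setNames(gsub("\\s", "", seqs), names_out)
}
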