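#' Number of exchangeable backbone amides of a peptide
#'
#' Residue count minus prolines (no backbone NH) minus one for the fast
#' back-exchanging N-terminal amide.
#'
#' @param sequence Amino-acid string (one-letter code).
#' @return Integer count (>= 0).
#' @export
exchangeable_amides <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  n <- nchar(sequence)
  np <- lengths(regmatches(sequence, gregexpr("P", sequence, fixed = TRUE)))
  max(n - np - 1L, 0L)
}

#' Peptide deuterium-uptake record
#'
#' One peptide's weighted-average deuteron uptake per exposure time in one
#' sample. The unit of differential HX analysis; identity is the full key
#' (protein, start, end, sequence) so that different digests cannot collide
#' on coordinates alone.
#'
#' @param protein Protein identifier.
#' @param start,end Residue numbers (1-based, inclusive).
#' @param sequence Amino-acid string of length `end - start + 1`.
#' @param uptake Named numeric vector: names are exposure times in minutes,
#'   values are deuterons incorporated (each in `[0, exchangeable_amides]`).
#' @return A `peptide_uptake` object.
#' @export
peptide_uptake <- function(protein, start, end, sequence, uptake) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end < start) stop("require 1 <= start <= end")
  if (nchar(sequence) != end - start + 1L)
    stop("sequence length must equal end - start + 1")
  if (is.null(names(uptake)) || any(!nzchar(names(uptake))))
    stop("uptake must be named by exposure time (minutes)")
  maxd <- exchangeable_amides(sequence)
  if (any(uptake < 0) || any(uptake > maxd + 1e-9))
    stop(sprintf("uptake outside [0, %d] for peptide %s %d-%d",
                 maxd, protein, start, end))
  structure(list(protein = protein, start = start, end = end,
                 sequence = sequence, uptake = uptake),
            class = "peptide_uptake")
}

.peptide_key <- function(p) paste(p$protein, p$start, p$end, p$sequence, sep = "|")

#' Per-peptide uptake difference between two samples
#'
#' Matches peptides on the full key (protein, start, end, sequence) and
#' computes `delta = bound - free` at one exposure time. Peptides present in
#' only one sample are excluded and counted. No back-exchange correction is
#' applied: the difference of two uncorrected uptakes cancels the
#' (condition-independent) back exchange.
#'
#' @param bound,free Lists of [peptide_uptake()] records.
#' @param time Exposure time (minutes) present in both samples' uptake maps
#'   for every matched peptide.
#' @return List with `diffs` (data frame: protein, start, end, sequence,
#'   delta) and `n_excluded` (peptides found in only one sample).
#' @export
match_and_difference <- function(bound, free, time) {
  key_of <- function(recs, label) {
    k <- vapply(recs, .peptide_key, character(1))
    if (anyDuplicated(k))
      stop("duplicate peptide key in ", label, " sample: ",
           k[duplicated(k)][1])
    k
  }
  kb <- key_of(bound, "bound"); kf <- key_of(free, "free")
  common <- intersect(kb, kf)
  n_excluded <- (length(kb) - length(common)) + (length(kf) - length(common))
  tchr <- as.character(time)
  rows <- lapply(common, function(k) {
    pb <- bound[[match(k, kb)]]; pf <- free[[match(k, kf)]]
    if (!tchr %in% names(pb$uptake) || !tchr %in% names(pf$uptake))
      stop(sprintf("exposure time %s missing for peptide %s", tchr, k))
    data.frame(protein = pb$protein, start = pb$start, end = pb$end,
               sequence = pb$sequence,
               delta = unname(pb$uptake[tchr] - pf$uptake[tchr]))
  })
  diffs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein = character(), start = integer(), end = integer(),
               sequence = character(), delta = numeric())
  list(diffs = diffs, n_excluded = n_excluded)
}

#' Classify uptake differences into ordinal protection bins
#'
#' Maps each delta to one of `2k + 1` bins defined by `k` positive
#' thresholds mirrored about zero. Negative deltas (less uptake when bound)
#' are protection; the integer bin runs from `-k` (strongest protection)
#' through `0` (no change) to `+k` (strongest deprotection).
#'
#' @param diffs Data frame with a `delta` column (as from
#'   [match_and_difference()]).
#' @param thresholds Strictly increasing positive deuteron cutoffs;
#'   default `c(0.3, 0.6, 1.0)` giving 7 bins.
#' @return `diffs` with an integer `bin` column added.
#' @export
classify_bins <- function(diffs, thresholds = c(0.3, 0.6, 1.0)) {
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be positive and strictly increasing")
  # |delta| exactly at a threshold belongs to the lower bin (left-open intervals)
  mag <- findInterval(abs(diffs$delta), thresholds, left.open = TRUE)
  diffs$bin <- as.integer(sign(diffs$delta) * mag)
  diffs
}

#' Paint per-residue protection classes from peptide differences
#'
#' Each residue covered by at least one peptide takes the bin of the
#' covering peptide with the largest `|delta|` (ties: the earlier peptide);
#' uncovered residues are `NA` ("no coverage").
#'
#' @param diffs Data frame with `start`, `end`, `delta` and `bin` columns
#'   (as from [classify_bins()]).
#' @param protein_length Number of residues.
#' @return Data frame: `residue`, `bin` (integer or `NA`), `delta` (the
#'   winning peptide's delta or `NA`).
#' @export
residue_paint <- function(diffs, protein_length) {
  if (protein_length <= 0) stop("protein_length must be positive")
  if (nrow(diffs) && any(diffs$end > protein_length | diffs$start < 1))
    stop("peptide outside [1, protein_length]")
  bin <- rep(NA_integer_, protein_length)
  delta <- rep(NA_real_, protein_length)
  best <- rep(-Inf, protein_length)
  for (i in seq_len(nrow(diffs))) {
    idx <- diffs$start[i]:diffs$end[i]
    take <- abs(diffs$delta[i]) > best[idx]
    idx <- idx[take]
    bin[idx] <- diffs$bin[i]
    delta[idx] <- diffs$delta[i]
    best[idx] <- abs(diffs$delta[i])
  }
  data.frame(residue = seq_len(protein_length), bin = bin, delta = delta)
}

#' Fraction of residues covered by at least one peptide
#'
#' @param records List of [peptide_uptake()] records (or any objects with
#'   `start`/`end` fields).
#' @param protein_length Number of residues (> 0).
#' @return Fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(records, protein_length) {
  if (protein_length <= 0) stop("protein_length must be positive")
  covered <- logical(protein_length)
  for (p in records) {
    if (p$end > protein_length || p$start < 1)
      stop("peptide outside [1, protein_length]")
    covered[p$start:p$end] <- TRUE
  }
  sum(covered) / protein_length
}
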