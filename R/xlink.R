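#' Validate a cross-link record table
#'
#' @param records Data frame with columns `protein_a`, `res_a`, `protein_b`,
#'   `res_b`, `chemistry` ("DSS" or "EDC"), `score`, `expect`.
#' @return The validated data frame (invisibly usable downstream).
#' @export
crosslink_records <- function(records) {
  req <- c("protein_a", "res_a", "protein_b", "res_b", "chemistry",
           "score", "expect")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(records)) {
    if (any(records$res_a < 1) || any(records$res_b < 1))
      stop("residue numbers must be >= 1")
    if (!all(records$chemistry %in% c("DSS", "EDC")))
      stop("chemistry must be DSS or EDC")
    if (any(records$expect < 0)) stop("expect values must be >= 0")
  }
  records
}

#' Filter cross-links on search score and expectation value
#'
#' Keeps records with `score > min_score` and `expect < max_expect`
#' (defaults: score above 20 and expectation below 1e-5, the confirmation
#' thresholds for high-confidence cross-linked peptide spectra). Order is
#' preserved; counts are attached as attributes `n_in` / `n_kept`.
#'
#' @param records Cross-link data frame (see [crosslink_records()]).
#' @param min_score Minimum score, exclusive (default 20).
#' @param max_expect Maximum expectation value, exclusive (default 1e-5).
#' @return The filtered subset.
#' @export
filter_crosslinks <- function(records, min_score = 20, max_expect = 1e-5) {
  records <- crosslink_records(records)
  keep <- records$score > min_score & records$expect < max_expect
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_in") <- nrow(records)
  attr(out, "n_kept") <- nrow(out)
  out
}

#' Build an intra/inter linkage map
#'
#' Classifies each cross-link as intra-protein or inter-protein,
#' deduplicates repeated residue pairs of the same chemistry (counting
#' multiplicity; A-B and B-A are the same pair), and records per-protein
#' lengths and a segmentation tick interval for plotting.
#'
#' @param records Cross-link data frame (see [crosslink_records()]).
#' @param lengths Named integer vector of protein lengths covering every
#'   protein referenced.
#' @param tick Segmentation tick interval in residues (default 50).
#' @return A `linkage_map`: list with `links` (data frame with `intra`
#'   logical and `multiplicity`), `lengths`, `tick`, and counts
#'   `n_intra` / `n_inter` (unique links).
#' @export
build_linkage_map <- function(records, lengths, tick = 50) {
  records <- crosslink_records(records)
  if (tick <= 0) stop("tick interval must be positive")
  prots <- unique(c(records$protein_a, records$protein_b))
  unknown <- setdiff(prots, names(lengths))
  if (length(unknown))
    stop("no length provided for protein(s): ", paste(unknown, collapse = ", "))
  bad <- which(records$res_a > lengths[records$protein_a] |
               records$res_b > lengths[records$protein_b])
  if (length(bad))
    stop(sprintf("record %d: residue beyond protein length", bad[1]))

  if (nrow(records)) {
    # canonical orientation so A-B and B-A dedupe together
    swap <- records$protein_a > records$protein_b |
      (records$protein_a == records$protein_b & records$res_a > records$res_b)
    pa <- ifelse(swap, records$protein_b, records$protein_a)
    ra <- ifelse(swap, records$res_b, records$res_a)
    pb <- ifelse(swap, records$protein_a, records$protein_b)
    rb <- ifelse(swap, records$res_a, records$res_b)
    key <- paste(pa, ra, pb, rb, records$chemistry, sep = "|")
    first <- !duplicated(key)
    links <- data.frame(protein_a = pa[first], res_a = ra[first],
                        protein_b = pb[first], res_b = rb[first],
                        chemistry = records$chemistry[first],
                        multiplicity = as.integer(table(key)[key[first]]))
    links$intra <- links$protein_a == links$protein_b
  } else {
    links <- data.frame(protein_a = character(), res_a = integer(),
                        protein_b = character(), res_b = integer(),
                        chemistry = character(), multiplicity = integer(),
                        intra = logical())
  }
  structure(list(links = links, lengths = lengths, tick = tick,
                 n_intra = sum(links$intra), n_inter = sum(!links$intra)),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf("Linkage map: %d intra + %d inter unique links over %d proteins (ticks every %d aa)\n",
              x$n_intra, x$n_inter, length(x$lengths), x$tick))
  invisible(x)
}

#' Validate cross-links against a structure
#'
#' Computes the Euclidean C-alpha--C-alpha distance for each cross-linked
#' residue pair after translating sequence numbering to structure numbering,
#' and flags whether the distance satisfies the chemistry-specific maximum.
#' Defaults: DSS (11.4 angstrom spacer between lysine amines) 24 angstrom;
#' EDC (zero-length amine-carboxyl coupling) 16 angstrom -- standard
#' C-alpha-level XL-MS practice values, recorded in the output.
#'
#' Links whose residues are absent from the structure (e.g. disordered
#' segments) are flagged `mapped = FALSE` and excluded from the satisfaction
#' summary.
#'
#' @param records Cross-link data frame (see [crosslink_records()]).
#' @param model A [structure_model()].
#' @param residue_mapping Named list per protein, each a function or a
#'   single numeric offset translating sequence residue numbers to the
#'   structure's residue numbering (and, via attribute, chain). Simplest
#'   form: `list(Cac1 = c(chain = "A", offset = 0))`.
#' @param thresholds Named numeric: maximum satisfied distance per
#'   chemistry, default `c(DSS = 24, EDC = 16)`.
#' @return List with `per_link` data frame (`distance`, `satisfied`,
#'   `mapped`) and `summary` (satisfaction fraction per chemistry over
#'   mapped links), plus the thresholds used.
#' @export
validate_against_structure <- function(records, model, residue_mapping,
                                       thresholds = c(DSS = 24, EDC = 16)) {
  records <- crosslink_records(records)
  stopifnot(inherits(model, "structure_model"))
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  atoms <- model$atoms
  ca <- atoms[atoms$atom_name == "CA", , drop = FALSE]

  locate <- function(protein, res) {
    mp <- residue_mapping[[protein]]
    if (is.null(mp)) return(NULL)
    chain <- mp[["chain"]]
    resno <- res + as.numeric(mp[["offset"]])
    hit <- which(ca$chain == chain & ca$resno == resno)
    if (!length(hit)) return(NULL)
    as.numeric(ca[hit[1], c("x", "y", "z")])
  }

  n <- nrow(records)
  distance <- rep(NA_real_, n); mapped <- logical(n); satisfied <- rep(NA, n)
  for (i in seq_len(n)) {
    p1 <- locate(records$protein_a[i], records$res_a[i])
    p2 <- locate(records$protein_b[i], records$res_b[i])
    if (is.null(p1) || is.null(p2)) {
      mapped[i] <- FALSE
      next
    }
    mapped[i] <- TRUE
    distance[i] <- sqrt(sum((p1 - p2)^2))
    thr <- thresholds[[records$chemistry[i]]]
    if (is.null(thr)) stop("no threshold for chemistry ", records$chemistry[i])
    satisfied[i] <- distance[i] <= thr
  }
  if (any(!mapped))
    warning(sum(!mapped), " link(s) could not be mapped onto the structure")
  per_link <- cbind(records,
                    data.frame(distance = distance, satisfied = satisfied,
                               mapped = mapped))
  summ <- vapply(unique(records$chemistry), function(ch) {
    sel <- mapped & records$chemistry == ch
    if (!any(sel)) return(NA_real_)
    mean(satisfied[sel])
  }, numeric(1))
  list(per_link = per_link, summary = summ, thresholds = thresholds)
}

# residue masses (Da): monoisotopic and IUPAC average, standard 20 residues
.aa_mono <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
              V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
              I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
              K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
              F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
.aa_avg <- c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
             V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
             I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
             K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
             F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.water_mono <- 18.010565
.water_avg <- 18.01528

#' Mass of a peptide or protein sequence
#'
#' Sum of residue masses plus one water, using IUPAC average atomic masses
#' (`mode = "average"`, appropriate for MALDI of intact proteins) or
#' monoisotopic masses.
#'
#' @param sequence Amino-acid string, standard 20 one-letter codes.
#' @param mode `"average"` (default) or `"monoisotopic"`.
#' @return Mass in Da.
#' @export
sequence_mass <- function(sequence, mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  if (!nzchar(sequence)) stop("empty sequence")
  aa <- strsplit(toupper(sequence), "")[[1]]
  tbl <- if (mode == "average") .aa_avg else .aa_mono
  unknown <- setdiff(aa, names(tbl))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unique(unknown), collapse = ", "))
  sum(tbl[aa]) + if (mode == "average") .water_avg else .water_mono
}
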