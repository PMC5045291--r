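#!/usr/bin/env Rscript
# Structural metrics: Shrake-Rupley SASA, buried interface area of a
# contacting pair, and Kabsch superposition RMSD. Runs on synthetic folds
# unconditionally; when deposited reference coordinates are supplied under
# inst/extdata/reference/ (5jbm.pdb, 5ejo.pdb, cac1_rlf2.fasta), the
# script additionally recomputes the crystallographic WH-domain homodimer
# interface area, the superposition r.m.s.d. onto the search model, and
# the C-terminal fragment mass.

suppressMessages(library(caf1arch))
dir.create("results", showWarnings = FALSE)

# --- synthetic demonstrations -------------------------------------------
fold <- synthetic_ca_model(80, seed = 600)
s <- sasa(fold)
cat(sprintf("synthetic fold SASA: %.0f A^2 (probe %.1f A, %d points/atom)\n",
            s$total, s$probe, s$n_points))

mate <- apply_transform(fold, rigid_transform(diag(3), c(6, 0, 0)))
bsa <- buried_surface_area(fold, mate)
cat(sprintf("contacting pair buries %.0f A^2 total (%.0f per interface half)\n",
            bsa$delta_total, bsa$delta_half))

set.seed(601)
q <- rnorm(4); q <- q / sqrt(sum(q^2))
R <- matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
              2 * (q[2] * q[4] + q[1] * q[3]),
              2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
              2 * (q[3] * q[4] - q[1] * q[2]),
              2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
              1 - 2 * (q[2]^2 + q[3]^2)), 3, byrow = TRUE)
moved <- apply_transform(fold, rigid_transform(R, c(10, -5, 3)))
cat(sprintf("superposition of a rigidly moved copy: rmsd %.2e A over %d atoms\n",
            superpose_rmsd(fold, moved)$rmsd, 80))

# --- reference recomputations (when coordinates are supplied) -----------
ref <- function(name) {
  p <- file.path("inst", "extdata", "reference", name)
  if (file.exists(p)) p else {
    q <- system.file("extdata", "reference", name, package = "caf1arch")
    if (nzchar(q)) q else NA_character_
  }
}

p5jbm <- ref("5jbm.pdb")
if (!is.na(p5jbm)) {
  mono <- read_structure(p5jbm)
  cell <- c(58.850, 58.830, 97.929, 90, 90, 90)
  # two-fold operators of the tetragonal 4(1)22 point setting, explicit
  ops <- list(
    list(R = matrix(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), 3, byrow = TRUE), t = c(0, 0, 0)),
    list(R = matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, byrow = TRUE), t = c(0, 0, 1 / 2)),
    list(R = matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), 3, byrow = TRUE), t = c(0, 0, 1 / 4)),
    list(R = matrix(c(0, -1, 0, -1, 0, 0, 0, 0, -1), 3, byrow = TRUE), t = c(0, 0, 3 / 4)))
  shifts <- expand.grid(i = -1:1, j = -1:1, k = -1:1)
  best <- 0
  ca <- as.matrix(mono$atoms[mono$atoms$atom_name == "CA", c("x", "y", "z")])
  for (op in ops) for (r in seq_len(nrow(shifts))) {
    mate <- symmetry_mate(mono, op$R, op$t + as.numeric(shifts[r, ]), cell)
    cb <- as.matrix(mate$atoms[mate$atoms$atom_name == "CA", c("x", "y", "z")])
    mind <- sqrt(min(outer(rowSums(ca^2), rowSums(cb^2), "+") -
                       2 * ca %*% t(cb)))
    if (!is.finite(mind) || mind > 15) next
    best <- max(best, buried_surface_area(mono, mate)$delta_total)
  }
  cat(sprintf("WH homodimer interface: %.0f A^2 total, %.0f per half\n",
              best, best / 2))
} else {
  cat("reference 5jbm.pdb not supplied; skipping interface recomputation\n")
}

p5ejo <- ref("5ejo.pdb")
if (!is.na(p5jbm) && !is.na(p5ejo)) {
  a <- read_structure(p5jbm); b <- read_structure(p5ejo)
  rmsds <- vapply(unique(b$atoms$chain), function(ch) {
    bb <- b$atoms[b$atoms$chain == ch, , drop = FALSE]
    bb$chain <- unique(a$atoms$chain)[1]
    tryCatch(superpose_rmsd(a, structure_model(bb))$rmsd,
             error = function(e) NA_real_)
  }, numeric(1))
  cat(sprintf("superposition onto search model: best rmsd %.2f A\n",
              min(rmsds, na.rm = TRUE)))
} else {
  cat("reference 5ejo.pdb not supplied; skipping superposition\n")
}

pfa <- ref("cac1_rlf2.fasta")
if (!is.na(pfa)) {
  seqs <- read_fasta_sequences(pfa)
  frag <- substr(seqs[[1]], 457, 606)
  cat(sprintf("Cac1 457-606 average mass: %.1f Da\n", sequence_mass(frag)))
} else {
  cat("reference cac1_rlf2.fasta not supplied; skipping fragment mass\n")
}
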