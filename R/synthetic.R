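# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a binding titration with optional fluorophore quenching
#'
#' Forward model of the fitting stage: per-point bound fraction from the
#' one-site ligand-depletion quadratic, observed signal formed as the
#' intensity-weighted mixture of the free and bound anisotropies (the bound
#' species' intensity scaled by `quench_ratio = Q_bound/Q_free`), plus
#' homoscedastic Gaussian noise. Ground truth is embedded in `meta`.
#'
#' @param kd Ground-truth dissociation constant (M).
#' @param a_star Labeled-species concentration (M).
#' @param b_grid Titrant concentrations (M); default 12 points log-spaced
#'   from 0.1 to 10 times `kd`.
#' @param f0 Baseline signal (free-species anisotropy on the normalized
#'   scale), default 1.
#' @param fmax Amplitude at saturation, default 0.5.
#' @param quench_ratio Bound/free intensity ratio `Q_b/Q_f` (> 0),
#'   default 1 (no quenching).
#' @param noise_sd Gaussian noise SD on the signal, default 0.005.
#' @param seed Optional integer seed (restores the caller's RNG state).
#' @return A [titration_series()] with ground truth in `$meta`.
#' @export
gen_titration <- function(kd, a_star, b_grid = NULL, f0 = 1, fmax = 0.5,
                          quench_ratio = 1, noise_sd = 0.005, seed = NULL) {
  if (quench_ratio <= 0) stop("quench_ratio must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (is.null(b_grid))
    b_grid <- exp(seq(log(0.1 * kd), log(10 * kd), length.out = 12))
  if (any(diff(b_grid) <= 0)) stop("b_grid must be strictly increasing")
  fb <- fraction_bound_ligand_depletion(kd, a_star, b_grid)
  r_free <- f0
  r_bound <- f0 + fmax
  wf <- (1 - fb)            # free-species intensity weight (Q_f = 1)
  wb <- fb * quench_ratio   # bound-species intensity weight
  r_obs <- (wf * r_free + wb * r_bound) / (wf + wb)
  signal <- .with_seed(seed, r_obs + stats::rnorm(length(b_grid), 0, noise_sd))
  titration_series(a_star, b_grid, signal,
                   meta = list(kd = kd, f0 = f0, fmax = fmax,
                               quench_ratio = quench_ratio,
                               noise_sd = noise_sd, seed = seed))
}

.gauss_band <- function(grid, center, sd, amplitude) {
  amplitude * exp(-(grid - center)^2 / (2 * sd^2))
}

#' Simulate donor/acceptor emission spectra with controllable FRET mixing
#'
#' Gaussian donor and acceptor emission bands. The dual-labeled spectrum
#' under donor excitation contains the donor band (scaled by `1 - eff`,
#' transfer-quenched) plus the acceptor band at `eff` times its amplitude
#' in the direct-excitation spectrum, so the acceptor-enhancement readout
#' of a noiseless, well-separated construction equals `eff`. When a
#' donor-acceptor `distance` is given instead of an efficiency,
#' `eff = 1 / (1 + (distance / r0)^6)`.
#'
#' @param efficiency FRET efficiency in `[0, 1]` (or `NULL` to use
#'   `distance`).
#' @param distance Donor-acceptor distance (angstrom), used when
#'   `efficiency` is `NULL`.
#' @param r0 Forster radius (angstrom), default 52 (CPM-FM pair).
#' @param grid Wavelength grid (nm), default `seq(400, 600, by = 1)`.
#' @param donor_center,donor_sd Donor band center/width (nm), defaults
#'   470 / 15.
#' @param acceptor_center,acceptor_sd Acceptor band center/width (nm),
#'   defaults 520 / 15.
#' @param donor_amp,acceptor_amp Band amplitudes, defaults 1 / 0.8.
#' @param noise_sd Gaussian noise SD added to every spectrum, default 0.
#' @param seed Optional integer seed.
#' @return A [spectra_set()] with ground truth attached as attribute
#'   `"truth"`.
#' @export
gen_spectra <- function(efficiency = NULL, distance = NULL, r0 = 52,
                        grid = seq(400, 600, by = 1),
                        donor_center = 470, donor_sd = 15,
                        acceptor_center = 520, acceptor_sd = 15,
                        donor_amp = 1, acceptor_amp = 0.8,
                        noise_sd = 0, seed = NULL) {
  if (is.null(efficiency)) {
    if (is.null(distance) || distance <= 0)
      stop("provide efficiency in [0,1] or a positive distance")
    efficiency <- 1 / (1 + (distance / r0)^6)
  }
  if (efficiency < 0 || efficiency > 1)
    stop("efficiency must lie in [0, 1]")
  donor <- .gauss_band(grid, donor_center, donor_sd, donor_amp)
  acceptor <- .gauss_band(grid, acceptor_center, acceptor_sd, acceptor_amp)
  dual_d <- (1 - efficiency) * donor + efficiency * acceptor
  dual_a <- acceptor
  out <- .with_seed(seed, {
    nz <- function(y) y + if (noise_sd > 0)
      stats::rnorm(length(y), 0, noise_sd) else 0
    spectra_set(spectrum(grid, nz(donor)),
                spectrum(grid, nz(dual_d)),
                spectrum(grid, nz(dual_a)))
  })
  attr(out, "truth") <- list(efficiency = efficiency, r0 = r0,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate gel band densitometry for a known tetrasome fraction
#'
#' A tetrasome carries two labeled H3/H4 dimers, so its band fluorescence
#' is `2 x (molar tetrasome amount) x per-dimer intensity`, while the
#' disome band is `1 x`. Local backgrounds are added and multiplicative
#' Gaussian noise applied to the band signals.
#'
#' @param fraction Molar tetrasome fraction in `[0, 1]`
#'   (tetrasomes / (tetrasomes + disomes)).
#' @param total_particles Total molar amount of DNA-bound species (arbitrary
#'   units), default 1000.
#' @param per_dimer_intensity Fluorescence per labeled dimer, default 1.
#' @param bg_tetrasome,bg_disome Local background IDVs, defaults 100.
#' @param noise_frac Fractional (multiplicative) noise SD on band signals,
#'   default 0.
#' @param seed Optional integer seed.
#' @return Named list with the four IDV fields consumed by
#'   [fraction_tetrasome()] plus `truth`.
#' @export
gen_gel <- function(fraction, total_particles = 1000, per_dimer_intensity = 1,
                    bg_tetrasome = 100, bg_disome = 100,
                    noise_frac = 0, seed = NULL) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (total_particles < 0 || per_dimer_intensity < 0)
    stop("totals must be nonnegative")
  n_tet <- fraction * total_particles
  n_di <- (1 - fraction) * total_particles
  sig_tet <- 2 * n_tet * per_dimer_intensity
  sig_di <- n_di * per_dimer_intensity
  .with_seed(seed, {
    nz <- function(s) s * (1 + if (noise_frac > 0)
      stats::rnorm(1, 0, noise_frac) else 0)
    list(idv_tetrasome = max(nz(sig_tet), 0) + bg_tetrasome,
         idv_tetrasome_bg = bg_tetrasome,
         idv_disome = max(nz(sig_di), 0) + bg_disome,
         idv_disome_bg = bg_disome,
         truth = fraction)
  })
}

#' Simulate paired HX-MS uptake tables with a known protection footprint
#'
#' Generates a random protein sequence, tiles it with peptides, draws each
#' peptide's free-state uptake, and sets the bound-state uptake to
#' `free + mean(profile over the peptide)` (negative profile = protection),
#' clamped to the exchangeable-amide range. Both tables share identical
#' peptide keys.
#'
#' @param protein_length Number of residues.
#' @param peptide_length,peptide_step Tiling window and stride (residues),
#'   defaults 15 / 10.
#' @param protection_profile Numeric vector of per-residue deltas
#'   (deuterons; negative = protection), length `protein_length`; default
#'   all zero.
#' @param times Exposure times in minutes, default `c(30, 60)`.
#' @param free_level Mean fractional exchange of the free state in `[0,1]`,
#'   default 0.5.
#' @param noise_sd Gaussian noise SD (deuterons) added independently to
#'   each table, default 0.
#' @param protein Protein identifier, default `"Cac1"`.
#' @param seed Optional integer seed.
#' @return List with `bound` and `free` (lists of [peptide_uptake()]),
#'   `sequence`, and `profile`.
#' @export
gen_hx_tables <- function(protein_length, peptide_length = 15,
                          peptide_step = 10, protection_profile = NULL,
                          times = c(30, 60), free_level = 0.5,
                          noise_sd = 0, protein = "Cac1", seed = NULL) {
  if (is.null(protection_profile))
    protection_profile <- numeric(protein_length)
  if (length(protection_profile) != protein_length)
    stop("protection_profile must have length protein_length")
  .with_seed(seed, {
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "Q", "R", "S", "T", "V", "W", "Y")  # no proline: keeps amide
                                                # counts equal to length - 1
    seqc <- sample(aa, protein_length, replace = TRUE)
    starts <- seq(1, max(protein_length - peptide_length + 1, 1),
                  by = peptide_step)
    bound <- list(); free <- list()
    for (s in starts) {
      e <- min(s + peptide_length - 1, protein_length)
      pep <- paste(seqc[s:e], collapse = "")
      maxd <- exchangeable_amides(pep)
      base <- free_level * maxd
      dprof <- mean(protection_profile[s:e])
      uf <- ub <- stats::setNames(numeric(length(times)), times)
      for (ti in seq_along(times)) {
        nf <- if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
        nb <- if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
        uf[ti] <- min(max(base + nf, 0), maxd)
        ub[ti] <- min(max(base + dprof + nb, 0), maxd)
      }
      free[[length(free) + 1]] <- peptide_uptake(protein, s, e, pep, uf)
      bound[[length(bound) + 1]] <- peptide_uptake(protein, s, e, pep, ub)
    }
    list(bound = bound, free = free,
         sequence = paste(seqc, collapse = ""),
         profile = protection_profile)
  })
}

#' Synthetic C-alpha trace model
#'
#' Self-similar random-walk C-alpha chain with 3.8 angstrom virtual bonds,
#' for exercising distance-based operations without real coordinates.
#'
#' @param n_res Number of residues.
#' @param chain Chain identifier, default `"A"`.
#' @param seed Optional integer seed.
#' @return A [structure_model()] of C-alpha atoms.
#' @export
synthetic_ca_model <- function(n_res, chain = "A", seed = NULL) {
  .with_seed(seed, {
    step <- matrix(stats::rnorm(3 * (n_res - 1)), ncol = 3)
    step <- step / sqrt(rowSums(step^2)) * 3.8
    xyz <- rbind(c(0, 0, 0), apply(step, 2, cumsum))
    structure_model(
      data.frame(chain = chain, resno = seq_len(n_res), resname = "ALA",
                 atom_name = "CA", element = "C",
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
      title = "synthetic CA trace")
  })
}

#' Simulate a cross-link list of true contacts plus decoys
#'
#' True links are drawn from residue pairs whose C-alpha distance in the
#' supplied model is within the chemistry threshold, with passing
#' score/expect statistics; decoys are drawn from pairs beyond the
#' threshold and are assigned failing statistics. Truth labels are attached
#' as the `is_true` column for evaluation only (never consumed by the
#' analysis).
#'
#' @param model A [structure_model()] providing C-alpha coordinates (single
#'   chain).
#' @param n_true,n_decoy Numbers of true and decoy links.
#' @param chemistry `"DSS"` or `"EDC"`, default `"DSS"`.
#' @param threshold Distance threshold (angstrom) separating true from
#'   decoy pairs; default 24 (DSS).
#' @param protein Protein identifier used in the records, default `"Cac1"`.
#' @param min_seq_sep Minimum sequence separation of sampled pairs,
#'   default 5.
#' @param seed Optional integer seed.
#' @return Cross-link data frame (see [crosslink_records()]) with an extra
#'   `is_true` column.
#' @export
gen_xlinks <- function(model, n_true, n_decoy, chemistry = "DSS",
                       threshold = 24, protein = "Cac1",
                       min_seq_sep = 5, seed = NULL) {
  stopifnot(inherits(model, "structure_model"), n_true >= 0, n_decoy >= 0)
  ca <- model$atoms[model$atoms$atom_name == "CA", , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  n <- nrow(ca)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  pairs <- pairs[abs(pairs[, 1] - pairs[, 2]) >= min_seq_sep, , drop = FALSE]
  dv <- d[pairs]
  near <- which(dv <= threshold)
  far <- which(dv > threshold)
  if (length(near) < n_true || length(far) < n_decoy)
    stop("insufficient eligible residue pairs for the requested counts")
  .with_seed(seed, {
    it <- sample(near, n_true)
    id <- sample(far, n_decoy)
    idx <- c(it, id)
    data.frame(
      protein_a = protein, res_a = ca$resno[pairs[idx, 1]],
      protein_b = protein, res_b = ca$resno[pairs[idx, 2]],
      chemistry = chemistry,
      score = c(stats::runif(n_true, 25, 60), stats::runif(n_decoy, 2, 15)),
      expect = c(10^stats::runif(n_true, -9, -6),
                 10^stats::runif(n_decoy, -4, -1)),
      is_true = rep(c(TRUE, FALSE), c(n_true, n_decoy)))
  })
}
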