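#' Fluorescence anisotropy from polarized intensities
#'
#' `r = (I_VV - G * I_VH) / (I_VV + 2 * G * I_VH)` with the grating factor
#' `G = I_HV / I_HH` correcting the detection-arm polarization bias.
#'
#' @param i_vv,i_vh,i_hv,i_hh Fluorescence intensities for the four
#'   excitation/emission polarizer orientations (arbitrary units, >= 0;
#'   `i_hh` must be positive).
#' @return Anisotropy `r` in `(-0.5, 1]`.
#' @export
anisotropy <- function(i_vv, i_vh, i_hv, i_hh) {
  vals <- c(i_vv, i_vh, i_hv, i_hh)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("intensities must be finite and nonnegative")
  if (any(i_hh <= 0)) stop("i_hh must be positive (grating factor undefined)")
  g <- i_hv / i_hh
  denom <- i_vv + 2 * g * i_vh
  if (any(denom <= 0)) stop("total intensity is zero; anisotropy undefined")
  (i_vv - g * i_vh) / denom
}

#' Quench-corrected anisotropy
#'
#' When binding changes the fluorophore quantum yield, the observed
#' anisotropy is an intensity-weighted mixture of the free and bound species
#' and over/under-weights whichever is brighter. This inverts that weighting:
#'
#' `r = (((A - Af)/(Ab - A)) * (Qf/Qb) * Ab + Af) / (1 + ((A - Af)/(Ab - A)) * (Qf/Qb))`
#'
#' When `q_free == q_bound` the correction is the identity. Intended for
#' titrations where quenching exceeds ~10% of the free-species intensity;
#' see [quench_exceeds_trigger()].
#'
#' @param a_obs Observed anisotropy, between `a_free` and `a_bound`
#'   (strictly below `a_bound`).
#' @param a_free,a_bound Anisotropy of the free and saturated labeled
#'   species (must differ).
#' @param q_free,q_bound Fluorescence intensity of the free and saturated
#'   species (> 0).
#' @return Corrected anisotropy, between `a_free` and `a_bound`.
#' @export
quench_corrected_anisotropy <- function(a_obs, a_free, a_bound, q_free, q_bound) {
  if (q_free <= 0 || q_bound <= 0) stop("q_free and q_bound must be positive")
  if (a_free == a_bound) stop("a_free and a_bound must differ")
  lo <- min(a_free, a_bound); hi <- max(a_free, a_bound)
  if (any(a_obs < lo) || any(a_obs > hi))
    stop("a_obs must lie between a_free and a_bound")
  if (any(a_obs == a_bound))
    stop("a_obs equals a_bound (saturation endpoint); correction is singular")
  x <- (a_obs - a_free) / (a_bound - a_obs) * (q_free / q_bound)
  (x * a_bound + a_free) / (1 + x)
}

#' Does quenching exceed the correction trigger?
#'
#' Advisory flag comparing the endpoint intensities of a titration: `TRUE`
#' when the saturated intensity deviates from the free intensity by more
#' than `trigger` (default 10%), the regime in which
#' [quench_corrected_anisotropy()] should be applied.
#'
#' @param q_free,q_bound Endpoint fluorescence intensities (> 0).
#' @param trigger Fractional intensity change that triggers correction.
#' @return Logical flag.
#' @export
quench_exceeds_trigger <- function(q_free, q_bound, trigger = 0.10) {
  if (q_free <= 0 || q_bound <= 0) stop("intensities must be positive")
  abs(q_bound - q_free) / q_free > trigger
}

#' Emission spectrum container
#'
#' @param wavelength_nm Strictly increasing wavelengths (nm).
#' @param intensity Intensities (arbitrary units), same length.
#' @return A `spectrum` object (data.frame with columns `wavelength_nm`,
#'   `intensity`).
#' @export
spectrum <- function(wavelength_nm, intensity) {
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelength_nm) != length(intensity))
    stop("wavelength and intensity must have equal length")
  if (length(wavelength_nm) < 2L) stop("spectrum needs at least 2 points")
  if (is.unsorted(wavelength_nm, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(wavelength_nm)) || any(!is.finite(intensity)))
    stop("spectrum values must be finite")
  structure(data.frame(wavelength_nm = wavelength_nm, intensity = intensity),
            class = c("spectrum", "data.frame"))
}

#' Spectra set for FRET-effect extraction
#'
#' @param donor_only_ex_d Donor-only sample, donor-band excitation.
#' @param dual_ex_d Dual-labeled sample, donor-band excitation.
#' @param dual_ex_a Dual-labeled sample, direct acceptor excitation.
#'   All three are [spectrum()] objects; spectra on different grids are
#'   interpolated onto the `dual_ex_d` grid before arithmetic.
#' @return A `spectra_set` object.
#' @export
spectra_set <- function(donor_only_ex_d, dual_ex_d, dual_ex_a) {
  for (s in list(donor_only_ex_d, dual_ex_d, dual_ex_a))
    stopifnot(inherits(s, "spectrum"))
  structure(list(donor_only_ex_d = donor_only_ex_d,
                 dual_ex_d = dual_ex_d, dual_ex_a = dual_ex_a),
            class = "spectra_set")
}

# trapezoidal integral of a spectrum restricted to [lo, hi] nm
.integrate_window <- function(wl, int, lo, hi) {
  keep <- wl >= lo & wl <= hi
  if (sum(keep) < 2L) stop("integration window contains fewer than 2 points")
  x <- wl[keep]; y <- int[keep]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# linear interpolation of spectrum s onto grid (no extrapolation growth:
# rule 2 holds endpoints, windows are required to sit inside all spectra)
.on_grid <- function(s, grid) {
  if (length(s$wavelength_nm) == length(grid) &&
      all(s$wavelength_nm == grid)) return(s$intensity)
  stats::approx(s$wavelength_nm, s$intensity, xout = grid, rule = 2)$y
}

#' FRET effect by acceptor enhancement
#'
#' Quantifies FRET as the ratio of sensitized acceptor emission (after
#' donor-band excitation) to directly excited acceptor emission. The donor
#' contribution to the dual-label spectrum is removed by a scalar
#' least-squares fit of the donor-only spectrum over a donor-dominated
#' window; the residual ("extracted") spectrum is integrated over the
#' acceptor window to give `F_donor_ex`, normalized by the same integral of
#' the direct-excitation spectrum `F_direct`:
#' `fret_effect = F_donor_ex / F_direct`.
#'
#' @param s A [spectra_set()].
#' @param donor_window Wavelength window (nm) used to fit the donor-only
#'   spectrum to the dual spectrum; default `c(400, 480)`.
#' @param acceptor_window Wavelength window (nm) over which acceptor
#'   emission is integrated; default `c(500, 560)`.
#' @return List with `fret_effect`, `scale` (donor fit coefficient),
#'   `extracted` ([spectrum()] of the donor-subtracted dual spectrum),
#'   `f_donor_ex`, `f_direct`, and `warning` (character, `NA` if clean).
#' @export
fret_effect <- function(s, donor_window = c(400, 480),
                        acceptor_window = c(500, 560)) {
  stopifnot(inherits(s, "spectra_set"))
  grid <- s$dual_ex_d$wavelength_nm
  rng <- function(sp) range(sp$wavelength_nm)
  for (sp in list(s$donor_only_ex_d, s$dual_ex_d)) {
    r <- rng(sp)
    if (donor_window[1] < r[1] || donor_window[2] > r[2])
      stop("donor fit window not contained in spectrum range")
  }
  if (acceptor_window[1] < rng(s$dual_ex_d)[1] ||
      acceptor_window[2] > rng(s$dual_ex_d)[2] ||
      acceptor_window[1] < rng(s$dual_ex_a)[1] ||
      acceptor_window[2] > rng(s$dual_ex_a)[2])
    stop("acceptor window not contained in spectrum range")

  donor <- .on_grid(s$donor_only_ex_d, grid)
  dual <- s$dual_ex_d$intensity
  acc_direct <- .on_grid(s$dual_ex_a, grid)

  w <- grid >= donor_window[1] & grid <= donor_window[2]
  if (sum(donor[w]^2) <= 0) stop("donor-only spectrum is zero over the fit window")
  scale <- sum(donor[w] * dual[w]) / sum(donor[w]^2)
  extracted <- dual - scale * donor

  f_donor_ex <- .integrate_window(grid, extracted,
                                  acceptor_window[1], acceptor_window[2])
  f_direct <- .integrate_window(grid, acc_direct,
                                acceptor_window[1], acceptor_window[2])
  if (f_direct <= 0)
    stop("no direct acceptor signal in the acceptor window (F_direct <= 0)")

  warn <- NA_character_
  tol <- 1e-9 * max(abs(f_direct), 1)
  if (f_donor_ex < -tol) {
    warn <- "extracted acceptor integral is negative; value reported as-is"
    warning(warn)
  }
  list(fret_effect = f_donor_ex / f_direct, scale = scale,
       extracted = spectrum(grid, extracted),
       f_donor_ex = f_donor_ex, f_direct = f_direct, warning = warn)
}

#' Pyrene excimer band ratio
#'
#' Mean intensity in a window around the excimer band (default 465 nm,
#' the red-shifted emission of two stacked pyrenes within ~10 angstrom)
#' divided by the mean around the monomer reference band (default 375 nm).
#'
#' @param s A [spectrum()].
#' @param band_center Excimer band center (nm), default 465.
#' @param reference_center Monomer reference band center (nm), default 375.
#' @param half_width Half-width of both averaging windows (nm), default 5.
#' @return Dimensionless band ratio.
#' @export
excimer_ratio <- function(s, band_center = 465, reference_center = 375,
                          half_width = 5) {
  stopifnot(inherits(s, "spectrum"))
  wl <- s$wavelength_nm
  for (ctr in c(band_center, reference_center))
    if (ctr - half_width < min(wl) || ctr + half_width > max(wl))
      stop("band window outside spectrum range")
  win_mean <- function(ctr) {
    keep <- wl >= ctr - half_width & wl <= ctr + half_width
    mean(s$intensity[keep])
  }
  ref <- win_mean(reference_center)
  if (ref <= 0) stop("reference window mean is not positive")
  win_mean(band_center) / ref
}
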