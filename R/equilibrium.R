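#' Titration series container
#'
#' Bundles one equilibrium binding titration: a fixed concentration of the
#' fluorescently labeled species and the signal (typically anisotropy)
#' measured at each titrant concentration.
#'
#' @param labeled_conc Molar concentration of the labeled species (kept fixed
#'   through the titration). Must be positive.
#' @param titrant_concs Numeric vector of titrant concentrations (M),
#'   nonnegative and strictly increasing.
#' @param signal Numeric vector of measured signals (e.g. anisotropy), same
#'   length as `titrant_concs`.
#' @param meta Optional named list of metadata (buffer, temperature, labels).
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(labeled_conc, titrant_concs, signal, meta = list()) {
  stopifnot(is.numeric(labeled_conc), length(labeled_conc) == 1L)
  if (!is.finite(labeled_conc) || labeled_conc <= 0)
    stop("labeled_conc must be a positive, finite molar concentration")
  titrant_concs <- as.numeric(titrant_concs)
  signal <- as.numeric(signal)
  if (length(signal) != length(titrant_concs))
    stop("signal and titrant_concs must have equal length")
  if (any(!is.finite(titrant_concs)) || any(titrant_concs < 0))
    stop("titrant_concs must be finite and nonnegative")
  if (is.unsorted(titrant_concs, strictly = TRUE))
    stop("titrant_concs must be strictly increasing")
  structure(
    list(labeled_conc = labeled_conc, titrant_concs = titrant_concs,
         signal = signal, meta = meta),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "Titration: %d points, [labeled] = %.3g M, titrant %.3g-%.3g M\n",
    length(x$titrant_concs), x$labeled_conc,
    min(x$titrant_concs), max(x$titrant_concs)))
  invisible(x)
}

#' Fraction of labeled species bound under ligand depletion
#'
#' Exact one-site bound fraction from the quadratic solution of the mass
#' balance `A = A_free + AB`, `B = B_free + AB`, `AB = A_free * B_free / Kd`.
#' Valid at any ratio of `a_star` to `kd`, i.e. in the ligand-depletion
#' regime where the hyperbolic approximation fails.
#'
#' @param kd Dissociation constant (M), > 0 (use `kd = 0` explicitly for the
#'   stoichiometric limit).
#' @param a_star Total concentration of the labeled species (M), > 0.
#' @param b Total titrant concentration(s) (M), >= 0. Vectorized.
#' @return Bound fraction(s) in `[0, 1]`.
#' @export
fraction_bound_ligand_depletion <- function(kd, a_star, b) {
  stopifnot(length(kd) == 1L, length(a_star) == 1L)
  if (!is.finite(a_star) || a_star <= 0)
    stop("a_star must be a positive molar concentration")
  if (!is.finite(kd) || kd < 0)
    stop("kd must be a nonnegative, finite molar constant")
  if (any(!is.finite(b)) || any(b < 0))
    stop("b must be finite and nonnegative")
  s <- kd + a_star + b
  disc <- s^2 - 4 * a_star * b
  # disc >= (kd + |a_star - b|)^2 >= 0 algebraically; clamp rounding error
  disc[disc < 0] <- 0
  # (s - sqrt(disc)) / (2 a*) rationalized to avoid cancellation when
  # s^2 >> 4 a* b
  f <- 2 * b / (s + sqrt(disc))
  pmin(pmax(f, 0), 1)
}

#' Signal predicted from a bound fraction
#'
#' Linear two-state observable: baseline plus amplitude times bound fraction.
#'
#' @param f0 Baseline signal (value at zero binding).
#' @param fmax Signal amplitude at saturation (change from baseline).
#' @param fraction Bound fraction(s) in `[0, 1]`.
#' @param tol Tolerance for the `[0, 1]` domain check.
#' @return Predicted signal(s) `f0 + fmax * fraction`.
#' @export
signal_from_fraction <- function(f0, fmax, fraction, tol = 1e-9) {
  if (any(fraction < -tol | fraction > 1 + tol))
    stop("fraction must lie in [0, 1]")
  f0 + fmax * pmin(pmax(fraction, 0), 1)
}

#' Fit a dissociation constant to a titration
#'
#' Weighted nonlinear least-squares fit of the one-site ligand-depletion
#' isotherm `F_i = f0 + fmax * fb(Kd, A*, B_i)` to a titration series, with
#' the labeled-species concentration fixed at `series$labeled_conc`.
#' Initialization is multi-start around the titrant concentration of
#' half-maximal signal; Kd is bounded positive.
#'
#' A fit is reported as not-calculable (`status = "n.c."`) rather than as a
#' number when the data do not constrain the upper plateau: estimated Kd
#' above the largest titrant concentration, relative standard error of Kd
#' above `max_rel_se`, or no convergence from any start.
#'
#' @param series A [titration_series()].
#' @param weights Optional per-point weights (default uniform).
#' @param max_rel_se Relative standard error of Kd above which the fit is
#'   declared not-calculable (default 0.5).
#' @return An object of class `binding_fit`: list with `kd`, `f0`, `fmax`,
#'   `se_kd`, `status` ("ok" or "n.c."), `fitted`, `residuals`, `rss`.
#' @export
fit_kd <- function(series, weights = NULL, max_rel_se = 0.5) {
  stopifnot(inherits(series, "titration_series"))
  b <- series$titrant_concs
  y <- series$signal
  n <- length(b)
  if (n < 5L) stop("need at least 5 titration points")
  if (is.null(weights)) weights <- rep(1, n)

  a_star <- series$labeled_conc
  f0_init <- y[which.min(b)]
  fmax_init <- max(y) - f0_init
  if (abs(fmax_init) < .Machine$double.eps) fmax_init <- 1e-3

  # titrant concentration at half-maximal signal change
  half <- f0_init + fmax_init / 2
  idx <- which(y >= half)
  kd_half <- if (length(idx)) max(b[min(idx)], min(b[b > 0], na.rm = TRUE)) else max(b)
  starts <- unique(pmax(kd_half * c(0.3, 1, 3), 1e-12))

  model <- function(kd, f0, fmax) {
    f0 + fmax * fraction_bound_ligand_depletion(kd, a_star, b)
  }
  best <- NULL
  for (kd0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ f0 + fmax * fraction_bound_ligand_depletion(kd, a_star, b),
        start = list(kd = kd0, f0 = f0_init, fmax = fmax_init),
        lower = c(kd = 1e-15, f0 = -Inf, fmax = -Inf),
        weights = weights,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(weights * stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15 * abs(best$rss))
      best <- list(fit = fit, rss = rss)
  }

  nc <- function(reason) {
    structure(list(kd = NA_real_, f0 = NA_real_, fmax = NA_real_,
                   se_kd = NA_real_, status = "n.c.", reason = reason,
                   fitted = NULL, residuals = NULL, rss = NA_real_),
              class = "binding_fit")
  }
  if (is.null(best)) return(nc("no convergence from any start"))

  cf <- stats::coef(best$fit)
  se_kd <- tryCatch(summary(best$fit)$coefficients["kd", "Std. Error"],
                    error = function(e) NA_real_)
  if (cf[["kd"]] > max(b))
    return(nc("estimated Kd exceeds maximum titrant concentration (no saturation)"))
  if (!is.finite(se_kd) || se_kd / cf[["kd"]] > max_rel_se)
    return(nc("Kd standard error too large (plateau unconstrained)"))

  structure(list(kd = cf[["kd"]], f0 = cf[["f0"]], fmax = cf[["fmax"]],
                 se_kd = se_kd, status = "ok", reason = NULL,
                 fitted = model(cf[["kd"]], cf[["f0"]], cf[["fmax"]]),
                 residuals = y - model(cf[["kd"]], cf[["f0"]], cf[["fmax"]]),
                 rss = best$rss),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$status == "n.c.") {
    cat("Binding fit: Kd not calculable (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("Binding fit: Kd = %.3g M (SE %.2g), f0 = %.4g, fmax = %.4g\n",
                x$kd, x$se_kd, x$f0, x$fmax))
  }
  invisible(x)
}

#' Coupled chaperone-binding / histone-tetramerization scheme
#'
#' Describes the equilibria `C + D <-> CD` (dissociation constant `k1`),
#' `CD + D <-> CD2` (`k2`), and free-dimer tetramerization
#' `D + D <-> T` (`ktet = [D]^2 / [T]`), with total chaperone and
#' histone-dimer concentrations. Weak `ktet` relative to the chaperone
#' affinity recovers the single-site picture.
#'
#' @param k1,k2,ktet Dissociation constants (M), all > 0.
#' @param c_total,d_total Total chaperone and histone-dimer concentrations
#'   (M), >= 0.
#' @return An object of class `equilibrium_scheme`.
#' @export
equilibrium_scheme <- function(k1, k2, ktet, c_total, d_total) {
  vals <- c(k1 = k1, k2 = k2, ktet = ktet)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all dissociation constants must be positive and finite")
  if (c_total < 0 || d_total < 0) stop("totals must be nonnegative")
  structure(list(k1 = k1, k2 = k2, ktet = ktet,
                 c_total = c_total, d_total = d_total),
            class = "equilibrium_scheme")
}

#' Solve the coupled binding/tetramerization equilibrium
#'
#' Root-finds the free histone-dimer concentration on the dimer mass-balance,
#' which is strictly increasing in free `[D]` (free chaperone eliminated in
#' closed form), then recovers all species. Deterministic; residuals of both
#' conservation laws are checked against `tol`.
#'
#' @param scheme An [equilibrium_scheme()].
#' @param tol Maximum allowed relative conservation residual (default 1e-9).
#' @return Named list of concentrations `c`, `d`, `t`, `cd`, `cd2` (M) plus
#'   `residual`, the larger relative conservation error.
#' @export
solve_coupled_equilibrium <- function(scheme, tol = 1e-9) {
  stopifnot(inherits(scheme, "equilibrium_scheme"))
  k1 <- scheme$k1; k2 <- scheme$k2; ktet <- scheme$ktet
  ct <- scheme$c_total; dt <- scheme$d_total

  species <- function(d) {
    cfree <- ct / (1 + d / k1 + d^2 / (k1 * k2))
    list(c = cfree, d = d, t = d^2 / ktet,
         cd = cfree * d / k1, cd2 = cfree * d^2 / (k1 * k2))
  }
  if (dt == 0) {
    out <- species(0)
    out$residual <- 0
    return(out)
  }
  # dimer conservation: d + 2t + cd + 2cd2 = dt; strictly increasing in d
  g <- function(d) {
    s <- species(d)
    s$d + 2 * s$t + s$cd + 2 * s$cd2 - dt
  }
  root <- stats::uniroot(g, lower = 0, upper = dt, tol = dt * 1e-15,
                         maxiter = 2000)
  d <- root$root
  # Newton polish for conservation at full double precision
  for (i in 1:5) {
    eps <- max(d, dt * 1e-6) * 1e-7
    gd <- (g(d + eps) - g(d - eps)) / (2 * eps)
    step <- g(d) / gd
    if (!is.finite(step)) break
    d_new <- d - step
    if (d_new <= 0 || d_new > dt) break
    d <- d_new
  }
  out <- species(d)
  res_d <- abs(out$d + 2 * out$t + out$cd + 2 * out$cd2 - dt) / dt
  res_c <- if (ct > 0) abs(out$c + out$cd + out$cd2 - ct) / ct else 0
  out$residual <- max(res_d, res_c)
  if (out$residual > tol)
    stop(sprintf("equilibrium solve did not converge: relative residual %.3g", out$residual))
  out
}
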