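# independent oracles used across the suite; each deliberately avoids the
# code path it checks

# bound fraction by numerical root-finding on the mass balance
# A = A_free + AB, B = B_free + AB, AB = A_free * B_free / kd
oracle_fraction_bound <- function(kd, a, b) {
  if (b == 0) return(0)
  g <- function(ab) ab * kd - (a - ab) * (b - ab)
  ab <- stats::uniroot(g, c(0, min(a, b)), tol = min(a, b) * 1e-12)$root
  # Newton polish to full double precision
  for (i in 1:4) {
    dg <- kd + (b - ab) + (a - ab)
    ab <- ab - g(ab) / dg
  }
  ab / a
}

# brute-force grid search minimizing the same residual sum of squares
oracle_grid_fit <- function(series, kd_grid, f0_grid, fmax_grid) {
  best <- list(rss = Inf)
  for (kd in kd_grid) {
    fb <- fraction_bound_ligand_depletion(kd, series$labeled_conc,
                                          series$titrant_concs)
    for (f0 in f0_grid) for (fmax in fmax_grid) {
      rss <- sum((series$signal - (f0 + fmax * fb))^2)
      if (rss < best$rss) best <- list(kd = kd, f0 = f0, fmax = fmax, rss = rss)
    }
  }
  best
}

# analytic mean of a Gaussian band over a wavelength window
gauss_window_mean <- function(center, sd, amp, lo, hi) {
  amp * sd * sqrt(2 * pi) *
    (stats::pnorm(hi, center, sd) - stats::pnorm(lo, center, sd)) / (hi - lo)
}

# minimal two-sphere model for SASA checks
two_atom_model <- function(sep, radius = 1.7) {
  structure_model(data.frame(
    chain = "A", resno = 1:2, resname = "X", atom_name = "CA",
    element = "C", x = c(0, sep), y = 0, z = 0, radius = radius))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}
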