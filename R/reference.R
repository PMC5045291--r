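#' Published CAF-1/histone equilibrium constants used as study conditions
#'
#' The dissociation constants measured by pyrene fluorescence anisotropy for
#' the CAF-1 subunit and Cac1-truncation interactions, with the
#' labeled-species concentration each titration used. These serve as
#' ground-truth inputs for parameter-recovery simulations; rows whose
#' titrations did not reach saturation are recorded with `kd = NA`
#' (not calculable).
#'
#' @return Data frame with columns `labeled`, `partner`, `kd` (M, `NA` for
#'   not-calculable), `se_kd` (M), `a_star` (labeled concentration, M).
#' @export
reference_affinities <- function() {
  data.frame(
    labeled = c("H3/H4", "H3/H4", "H3/H4", "H3/H4",
                "Cac1-386", "Cac1-454", "Cac1-386", "Cac1-454", "Cac1-386"),
    partner = c("CAF-1", "Cac1", "Cac2", "Cac3",
                "Cac1-386", "Cac1-454", "H3/H4", "H3/H4", "Cac2"),
    kd = c(5.3e-9, 9.7e-8, NA, NA,
           2.6e-8, 2.5e-8, 2.1e-7, NA, 1.3e-6),
    se_kd = c(0.9e-9, 1.8e-8, NA, NA,
              0.2e-8, 0.2e-8, 0.5e-7, NA, 0.4e-6),
    a_star = c(5e-9, 25e-9, 25e-9, 25e-9,
               10e-9, 10e-9, 10e-9, 10e-9, 10e-9))
}
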