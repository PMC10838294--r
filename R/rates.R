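#' First-order decay constant from a half-life
#'
#' @param lambda_half half-life in years (> 0; `Inf` disables decay).
#' @return decay constant in s^-1.
#' @examples
#' enzyme_decay_constant(1e4)  # 2.196e-12 s^-1
#' @export
enzyme_decay_constant <- function(lambda_half) {
  if (!is.numeric(lambda_half) || any(lambda_half <= 0))
    stop("lambda_half must be > 0")
  ifelse(is.infinite(lambda_half), 0, log(2) / (lambda_half * SECONDS_PER_YEAR))
}

#' Kinetic parameter set for the POC degradation network
#'
#' Bundles the rate constants of the reaction chain
#' POC -> HMW-DOC -> LMW-DOC -> CH4 + CO2, plus enzyme production and decay.
#' Derived members are computed here and kept consistent:
#' `K_o = beta * E0 * K_eh` (background hydrolysis driven by pore water) and
#' `K_ed = ln(2) / lambda_half` (enzyme decay).
#'
#' Units: `K_eh` is per mM enzyme per second; `K_fm` and `K_m` are per cell
#' per second and are multiplied in the rate laws by cell abundance per litre
#' of sediment (densities are supplied per cm^3; the factor 1000 keeps the
#' pairing consistent with mM = mmol/L concentrations).
#'
#' @param K_eh enzyme-driven hydrolysis constant, mM^-1 s^-1.
#' @param K_fm fermentation constant, s^-1 per cell (per litre pairing).
#' @param K_m methanogenesis constant; defaults to `K_fm` (the model's
#'   standard simplification).
#' @param beta dimensionless background-hydrolysis factor (<< 1).
#' @param E0 reference extracellular enzyme concentration, mM.
#' @param lambda_half extracellular enzyme half-life, years.
#' @param epsilon fraction of fermented carbon routed to enzyme production
#'   (0 < epsilon << 1).
#' @param gamma_ch4 fraction of metabolized LMW-DOC carbon emitted as methane;
#'   the remainder is CO2. Default 0.5 (2 CH2O -> CH4 + CO2).
#' @return an object of class `rate_constants`.
#' @export
rate_constants <- function(K_eh, K_fm, K_m = K_fm, beta = 0.01, E0 = 0.5,
                           lambda_half = 1e4, epsilon = 0.01, gamma_ch4 = 0.5) {
  stopifnot(K_eh >= 0, K_fm >= 0, K_m >= 0, beta >= 0, E0 >= 0)
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1) and << 1")
  if (gamma_ch4 <= 0 || gamma_ch4 > 1) stop("gamma_ch4 must be in (0, 1]")
  structure(list(
    K_eh = K_eh, K_fm = K_fm, K_m = K_m,
    beta = beta, E0 = E0,
    K_o = beta * E0 * K_eh,
    lambda_half = lambda_half,
    K_ed = enzyme_decay_constant(lambda_half),
    epsilon = epsilon, gamma_ch4 = gamma_ch4
  ), class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf(paste0("<rate_constants> K_eh = %.3g /mM/s, K_fm = %.3g, ",
                     "K_m = %.3g /cell/s\n  K_o = %.3g /s, K_ed = %.3g /s ",
                     "(half-life %g yr), eps = %g, gamma = %g\n"),
              x$K_eh, x$K_fm, x$K_m, x$K_o, x$K_ed, x$lambda_half,
              x$epsilon, x$gamma_ch4))
  invisible(x)
}

#' Effective sediment diffusivities of the four solutes
#'
#' Defaults are free-solution diffusivities near 4 deg C times a tortuosity
#' factor of ~0.5, size-ordered: extracellular enzymes (largest molecules)
#' slowest, methane fastest.
#'
#' @param D_hmw,D_lmw,D_enz,D_ch4 effective diffusivities, m^2/s.
#' @return an object of class `transport_params`.
#' @export
transport_params <- function(D_hmw = 5e-11, D_lmw = 2.5e-10,
                             D_enz = 2.5e-11, D_ch4 = 4.4e-10) {
  if (any(c(D_hmw, D_lmw, D_enz, D_ch4) < 0)) stop("diffusivities must be >= 0")
  if (!(D_enz <= D_hmw && D_hmw <= D_lmw && D_lmw <= D_ch4))
    stop("diffusivities must be size-ordered: D_enz <= D_hmw <= D_lmw <= D_ch4")
  structure(list(D_hmw = D_hmw, D_lmw = D_lmw, D_enz = D_enz, D_ch4 = D_ch4),
            class = "transport_params")
}
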