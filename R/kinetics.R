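#' Instantaneous reaction rates at one or more nodes
#'
#' Rate laws of the degradation network:
#' \describe{
#'   \item{hydrolysis}{`r_hyd = (K_o + K_eh * E) * P` — enzyme-driven plus a
#'     small pore-water background; extracellular enzymes are cell-free, so
#'     this rate does not scale with cell counts.}
#'   \item{fermentation}{`r_fm = K_fm * (1000 * n_ferm) * H`}
#'   \item{methanogenesis}{`r_m = K_m * (1000 * n_meth) * L`}
#'   \item{enzyme decay}{`r_ed = K_ed * E`}
#' }
#' Cell densities `n_ferm`, `n_meth` are in cells per cm^3 of sediment; the
#' factor 1000 expresses them per litre, matching mM concentrations.
#'
#' @param P,H,L,E per-node concentrations (mM); must be non-negative.
#' @param rc a [rate_constants()] object.
#' @param n_ferm,n_meth cell densities, cells/cm^3 sediment.
#' @return list of numeric vectors `r_hyd`, `r_fm`, `r_m`, `r_ed` in mM/s.
#' @export
reaction_rates <- function(P, H, L, E, rc, n_ferm, n_meth = n_ferm) {
  if (any(P < 0) || any(H < 0) || any(L < 0) || any(E < 0))
    stop("negative concentration passed to reaction_rates (upstream bug)")
  list(
    r_hyd = (rc$K_o + rc$K_eh * E) * P,
    r_fm  = rc$K_fm * CELLS_CM3_TO_L * n_ferm * H,
    r_m   = rc$K_m  * CELLS_CM3_TO_L * n_meth * L,
    r_ed  = rc$K_ed * E
  )
}

# Pool derivatives for the reaction step. theta = 1 - S is frozen over the
# step. P, G, Edec are per total pore volume; H, L, E, M per fluid volume.
# The combination P + G + Edec + theta*(H+L+E+M) is an exact linear invariant,
# so any Runge-Kutta step conserves tracked carbon to round-off.
.reaction_derivs <- function(P, H, L, E, rc, n_ferm, n_meth, theta) {
  r <- reaction_rates(P, H, L, E, rc, n_ferm, n_meth)
  eps <- rc$epsilon
  gam <- rc$gamma_ch4
  list(
    dP = -r$r_hyd,
    dH = r$r_hyd / theta - r$r_fm,
    dL = (1 - eps) * r$r_fm - r$r_m,
    dE = eps * r$r_fm - r$r_ed,
    dM = gam * r$r_m,
    dG = (1 - gam) * r$r_m * theta,
    dEdec = r$r_ed * theta
  )
}

#' Advance the reaction network over one full time step
#'
#' Explicit midpoint (RK2) integration of the coupled per-node ODEs
#' `dP/dt = -r_hyd`, `dH/dt = r_hyd - r_fm`,
#' `dL/dt = (1-eps) r_fm - r_m`, `dE/dt = eps r_fm - r_ed`,
#' `dM/dt = gamma r_m`, plus the CO2 and decayed-enzyme conservation ledgers.
#' Where hydrate is present the dissolved pools live in the residual fluid
#' fraction `1 - S`, which is held fixed during the step (hydrate exchange is
#' handled separately by [partition_methane()]).
#'
#' A stability guard keeps `dt` times the largest effective rate constant
#' below ~0.1 by sub-cycling the midpoint step internally when a caller
#' supplies a coarser `dt` (e.g. reduced-fidelity parameter sweeps), so the
#' explicit integrator stays in its accurate regime at any rate constant.
#'
#' @param state a `column_state`.
#' @param col the matching `sediment_column`.
#' @param rc a [rate_constants()] object.
#' @param dt time step, years.
#' @param n_ferm,n_meth optional per-node cell densities (cells/cm^3)
#'   overriding the column's (used by the simulator for depth-dependent
#'   profiles); default [cell_densities()] of the column at zero burial.
#' @return the advanced `column_state` (time incremented by `dt`).
#' @export
integrate_reactions <- function(state, col, rc, dt, n_ferm = NULL, n_meth = NULL) {
  stopifnot(inherits(state, "column_state"), inherits(col, "sediment_column"),
            inherits(rc, "rate_constants"))
  if (dt <= 0) stop("dt must be > 0")
  if (is.null(n_ferm) || is.null(n_meth)) {
    nd <- cell_densities(col, 0)
    if (is.null(n_ferm)) n_ferm <- nd$ferm
    if (is.null(n_meth)) n_meth <- nd$meth
  }
  dt_s <- dt * SECONDS_PER_YEAR

  kmax <- max(rc$K_o + rc$K_eh * max(state$E),
              rc$K_fm * CELLS_CM3_TO_L * max(n_ferm),
              rc$K_m * CELLS_CM3_TO_L * max(n_meth),
              rc$K_ed)
  n_sub <- max(1L, ceiling(dt_s * kmax / 0.1 - 0.05))
  h <- dt_s / n_sub

  th <- 1 - state$S
  out <- state
  for (sub in seq_len(n_sub)) {
    k1 <- .reaction_derivs(out$P, out$H, out$L, out$E, rc, n_ferm, n_meth, th)
    k2 <- .reaction_derivs(pmax(out$P + h / 2 * k1$dP, 0),
                           pmax(out$H + h / 2 * k1$dH, 0),
                           pmax(out$L + h / 2 * k1$dL, 0),
                           pmax(out$E + h / 2 * k1$dE, 0),
                           rc, n_ferm, n_meth, th)
    out$P <- out$P + h * k2$dP
    out$H <- out$H + h * k2$dH
    out$L <- out$L + h * k2$dL
    out$E <- out$E + h * k2$dE
    out$M <- out$M + h * k2$dM
    out$G <- out$G + h * k2$dG
    out$Edec <- out$Edec + h * k2$dEdec

    # round-off can leave tiny negatives; anything larger flags a real bug
    scale <- max(out$P, out$H, out$L, out$E, out$M, 1)
    for (f in c("P", "H", "L", "E", "M")) {
      v <- out[[f]]
      if (any(v < -1e-12 * scale))
        stop(sprintf("reaction step produced negative %s (min %.3g)", f, min(v)))
      out[[f]] <- pmax(v, 0)
    }
  }
  out$t <- state$t + dt
  out
}
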