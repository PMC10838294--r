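#' Tridiagonal linear system
#'
#' Container for the banded systems produced by the implicit diffusion step.
#' All four vectors have the node count as length; `lower[1]` and
#' `upper[n]` are ignored.
#'
#' @param lower,diag,upper the three bands.
#' @param rhs right-hand side.
#' @return an object of class `tridiagonal_system`.
#' @export
tridiagonal_system <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  if (length(lower) != n || length(upper) != n || length(rhs) != n)
    stop("all bands and rhs must have equal length")
  if (n < 1) stop("system dimension must be >= 1")
  structure(list(lower = lower, diag = diag, upper = upper, rhs = rhs),
            class = "tridiagonal_system")
}

#' Solve a tridiagonal system (Thomas algorithm)
#'
#' @param sys a [tridiagonal_system()].
#' @return the solution vector.
#' @export
solve_tridiagonal <- function(sys) {
  stopifnot(inherits(sys, "tridiagonal_system"))
  .thomas_solve(sys$lower, sys$diag, sys$upper, sys$rhs)
}

#' Implicit diffusion of one solute over a half time step
#'
#' Conservative finite-volume Crank-Nicolson update on the cell-centered grid
#' with zero-flux (closed-system) boundaries: boundary faces carry no flux, so
#' the discrete mass `sum(theta * field) * dz` is preserved to round-off.
#' An optional fluid-fraction weighting `theta` (= 1 - hydrate saturation)
#' makes the scheme solve `d(theta u)/dt = d/dz(theta D du/dz)` with `theta`
#' frozen during the step; face coefficients are arithmetic means.
#'
#' @param field per-node concentrations (mM); must be finite.
#' @param D effective diffusivity, m^2/s.
#' @param dz node spacing, m.
#' @param dt_half half time step, years.
#' @param theta optional per-node fluid fraction in (0, 1]; default 1.
#' @param scheme `"cn"` (Crank-Nicolson, second order, default) or `"be"`
#'   (backward Euler, first order but monotone).
#' @return the updated field.
#' @export
diffuse_half_step <- function(field, D, dz, dt_half, theta = NULL,
                              scheme = c("cn", "be")) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(field))) stop("non-finite value in field")
  if (D < 0) stop("D must be >= 0")
  n <- length(field)
  if (D == 0 || dt_half == 0 || n == 1) return(field)

  th <- if (is.null(theta)) rep(1, n) else theta
  if (length(th) != n || any(th <= 0) || any(th > 1))
    stop("theta must be per-node values in (0, 1]")

  w <- if (scheme == "cn") 0.5 else 1
  r <- dt_half * SECONDS_PER_YEAR / dz^2
  # interior face conductances theta*D (length n-1); boundary faces closed
  a <- D * (th[-n] + th[-1]) / 2
  am <- c(0, a)   # face below node i
  ap <- c(a, 0)   # face above node i

  # explicit part of the flux divergence
  lap <- am * (c(0, field[-n]) - field) + ap * (c(field[-1], 0) - field)
  lap[1] <- ap[1] * (field[2] - field[1])
  lap[n] <- am[n] * (field[n - 1] - field[n])

  sys <- tridiagonal_system(
    lower = -w * r * am,
    diag  = th + w * r * (am + ap),
    upper = -w * r * ap,
    rhs   = th * field + (1 - w) * r * lap
  )
  solve_tridiagonal(sys)
}

#' Diffuse all mobile solutes over a half time step
#'
#' Applies [diffuse_half_step()] to the four dissolved pools (HMW-DOC,
#' LMW-DOC, enzymes, methane) with the current fluid fraction `1 - S`.
#' POC, hydrate and the ledgers are immobile.
#'
#' @param state a `column_state`.
#' @param tp a [transport_params()] object.
#' @param dz node spacing, m.
#' @param dt_half half time step, years.
#' @param scheme passed to [diffuse_half_step()].
#' @return the state with updated `H`, `L`, `E`, `M`.
#' @export
diffuse_all <- function(state, tp, dz, dt_half, scheme = "cn") {
  stopifnot(inherits(state, "column_state"), inherits(tp, "transport_params"))
  th <- 1 - state$S
  # Crank-Nicolson can undershoot marginally below zero next to sharp
  # fronts. Clamp those; the run-level carbon ledger bounds the cumulative
  # mass this injects. Anything beyond 0.1 mM signals a real solver problem.
  clamp <- function(v) {
    if (min(v) < -0.1)
      stop(sprintf("diffusion produced a material negative value (min %.3g)", min(v)))
    pmax(v, 0)
  }
  state$H <- clamp(diffuse_half_step(state$H, tp$D_hmw, dz, dt_half, th, scheme))
  state$L <- clamp(diffuse_half_step(state$L, tp$D_lmw, dz, dt_half, th, scheme))
  state$E <- clamp(diffuse_half_step(state$E, tp$D_enz, dz, dt_half, th, scheme))
  state$M <- clamp(diffuse_half_step(state$M, tp$D_ch4, dz, dt_half, th, scheme))
  state
}
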