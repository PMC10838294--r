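#' Carbon molarity of pure methane hydrate
#'
#' Structure-I hydrate CH4 * n H2O: `density / (16.043 + n * 18.0153)` mol
#' CH4 per cm^3, returned in mM (mmol per litre of hydrate phase).
#'
#' @param hydrate_density hydrate density, g/cm^3.
#' @param hydration_number water molecules per methane (structure I: 5.75).
#' @return methane carbon molarity of the hydrate phase, mM.
#' @examples
#' hydrate_carbon_density()  # ~7623 mM
#' @export
hydrate_carbon_density <- function(hydrate_density = 0.912,
                                   hydration_number = 5.75) {
  if (hydrate_density <= 0) stop("hydrate_density must be > 0")
  if (hydration_number <= 0) stop("hydration_number must be > 0")
  hydrate_density / (16.043 + hydration_number * 18.0153) * 1e6
}

#' Depth-dependent methane solubility model
#'
#' Dissolved-methane concentration at equilibrium with hydrate, `C_eq(d)`,
#' non-decreasing with burial depth inside the gas hydrate stability zone.
#' Three forms are supported: `linear` — `c_ref * (1 + (d - d_ref)/d_scale)`;
#' `exponential` — `c_ref * exp((d - d_ref)/d_scale)`; `table` — linear
#' interpolation of a user-supplied `(depth_m, ceq_mM)` table. A
#' `mud_multiplier >= 1` raises the curve in mud to emulate the suppression of
#' hydrate formation in small pores; below `bghsz_depth` hydrate is disallowed
#' altogether (`C_eq = Inf`).
#'
#' @param form one of `"linear"`, `"exponential"`, `"table"`.
#' @param c_ref equilibrium concentration at the reference depth, mM.
#' @param d_ref reference depth, m.
#' @param d_scale depth scale of the increase, m.
#' @param mud_multiplier factor (>= 1) applied at mud nodes.
#' @param bghsz_depth base of the gas hydrate stability zone, m; `Inf` for none.
#' @param table data frame with columns `depth` and `ceq` (strictly increasing
#'   depth), required for `form = "table"`.
#' @return an object of class `solubility_model`.
#' @export
solubility_model <- function(form = c("linear", "exponential", "table"),
                             c_ref = 60, d_ref = 0, d_scale = 500,
                             mud_multiplier = 1, bghsz_depth = Inf,
                             table = NULL) {
  form <- match.arg(form)
  if (c_ref <= 0) stop("c_ref must be > 0")
  if (d_scale <= 0) stop("d_scale must be > 0")
  if (mud_multiplier < 1) stop("mud_multiplier must be >= 1")
  if (form == "table") {
    if (is.null(table) || !all(c("depth", "ceq") %in% names(table)))
      stop("form = 'table' requires a table with columns depth and ceq")
    if (any(diff(table$depth) <= 0)) stop("table depths must be strictly increasing")
    if (any(table$ceq <= 0)) stop("table ceq values must be > 0")
  }
  structure(list(form = form, c_ref = c_ref, d_ref = d_ref, d_scale = d_scale,
                 mud_multiplier = mud_multiplier, bghsz_depth = bghsz_depth,
                 table = table), class = "solubility_model")
}

#' Read a solubility table from a two-column text file
#'
#' Whitespace- or comma-delimited columns `depth_m`, `ceq_mM`; lines starting
#' with `#` are comments.
#'
#' @param path file path.
#' @return a data frame usable as the `table` of [solubility_model()].
#' @export
read_solubility_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           sep = "", col.names = c("depth", "ceq"))
  if (any(diff(tab$depth) <= 0)) stop("table depths must be strictly increasing")
  tab
}

#' Equilibrium methane solubility at given depths
#'
#' @param d depth below seafloor, m (>= 0); vectorized.
#' @param lith per-node lithology (`"mud"`/`"sand"`), recycled against `d`.
#' @param sm a [solubility_model()].
#' @return equilibrium concentration, mM (`Inf` below the BGHSZ).
#' @export
ceq <- function(d, lith, sm) {
  stopifnot(inherits(sm, "solubility_model"))
  if (any(d < 0)) stop("depth must be >= 0")
  base <- switch(sm$form,
    linear = sm$c_ref * (1 + (d - sm$d_ref) / sm$d_scale),
    exponential = sm$c_ref * exp((d - sm$d_ref) / sm$d_scale),
    table = stats::approx(sm$table$depth, sm$table$ceq, xout = d, rule = 2)$y
  )
  base <- pmax(base, .Machine$double.eps)
  out <- ifelse(lith == "mud", base * sm$mud_multiplier, base)
  out[d > sm$bghsz_depth] <- Inf
  out
}

#' Equilibrium partition of methane between solution and hydrate
#'
#' Conserves node methane carbon `T = M * (1 - S) + c_h * S`. If `T` exceeds
#' what solution can hold at `ceq_local`, excess precipitates:
#' `S' = (T - ceq_local) / (c_h - ceq_local)`, `M' = ceq_local`. If the
#' implied `S'` is negative the node is undersaturated: hydrate dissolves, and
#' once it is exhausted `M' = T` (below solubility). The operation is
#' idempotent and exactly carbon-conserving; `S' >= 1` is unphysical and
#' raises an error.
#'
#' @param M dissolved methane, mM per residual-fluid volume (>= 0).
#' @param S hydrate saturation, in `[0, 1)`.
#' @param ceq_local local equilibrium concentration, mM (`Inf` forbids hydrate).
#' @param c_h hydrate carbon molarity, mM ([hydrate_carbon_density()]).
#' @return list with updated vectors `M` and `S`.
#' @export
partition_methane <- function(M, S, ceq_local, c_h = hydrate_carbon_density()) {
  if (any(M < 0)) stop("M must be >= 0")
  if (any(S < 0) || any(S >= 1)) stop("S must be in [0, 1)")
  fin <- is.finite(ceq_local)
  if (any(ceq_local[fin] >= c_h))
    stop("ceq >= hydrate carbon density: solubility model unphysical")
  Tt <- M * (1 - S) + c_h * S
  S1 <- numeric(length(Tt))
  S1[fin] <- pmax((Tt[fin] - ceq_local[fin]) / (c_h - ceq_local[fin]), 0)
  if (any(S1 >= 1))
    stop("partition would give hydrate saturation >= 1 (unphysical parameters)")
  M1 <- ifelse(S1 > 0, ceq_local, Tt)
  list(M = M1, S = S1)
}

# State-level equilibrium projection: partitions methane at every node and
# rescales the other dissolved pools for the change in residual fluid volume
# so their bulk inventories are conserved.
apply_partition <- function(state, ceq_vec, c_h) {
  p <- partition_methane(state$M, state$S, ceq_vec, c_h)
  shrink <- (1 - state$S) / (1 - p$S)
  state$H <- state$H * shrink
  state$L <- state$L * shrink
  state$E <- state$E * shrink
  state$M <- p$M
  state$S <- p$S
  state
}
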