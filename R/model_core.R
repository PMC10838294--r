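#' Convert POC weight percent to carbon molarity per pore-fluid volume
#'
#' POC content is conventionally reported as a mass fraction of the sediment
#' grains (wt%). The rate laws operate on carbon molarity per volume of pore
#' fluid, so the solid-phase inventory is re-expressed as
#' `wt/100 * grain_density * (1 - porosity) / porosity / 12.011` mol per cm^3,
#' returned in mM (mmol/L).
#'
#' @param wt_percent organic carbon content, mass percent of sediment grains
#'   (0 <= wt_percent < 100).
#' @param grain_density sediment grain density, g/cm^3.
#' @param porosity pore volume fraction, strictly between 0 and 1.
#' @return carbon concentration in mM per pore-fluid volume.
#' @examples
#' convert_poc(0.5, 2.65, 0.5)  # ~1103 mM
#' @export
convert_poc <- function(wt_percent, grain_density = 2.65, porosity = 0.5) {
  stopifnot(is.numeric(wt_percent), is.numeric(grain_density), is.numeric(porosity))
  if (any(wt_percent < 0) || any(wt_percent >= 100))
    stop("wt_percent must be in [0, 100)")
  if (any(grain_density <= 0)) stop("grain_density must be positive")
  if (any(porosity <= 0) || any(porosity >= 1))
    stop("porosity must be strictly between 0 and 1")
  wt_percent / 100 * grain_density * (1 - porosity) / porosity / MOLAR_MASS_C * 1e6
}

#' Inverse of [convert_poc()]
#'
#' @param conc_mM carbon concentration per pore-fluid volume (mM).
#' @inheritParams convert_poc
#' @return POC content in wt% of sediment grains.
#' @export
convert_poc_inverse <- function(conc_mM, grain_density = 2.65, porosity = 0.5) {
  if (any(porosity <= 0) || any(porosity >= 1))
    stop("porosity must be strictly between 0 and 1")
  conc_mM * 1e-6 * MOLAR_MASS_C * porosity / (1 - porosity) / grain_density * 100
}

#' Constant-rate burial trajectory
#'
#' The modeled interval is fixed in a Lagrangian frame and subsides at the
#' sedimentation rate; compaction is neglected so the rate is constant.
#'
#' @param sed_rate sedimentation rate, mm/yr (> 0).
#' @param d0 burial depth of the interval top at t = 0, m below seafloor.
#' @return an object of class `burial_trajectory`.
#' @export
burial_trajectory <- function(sed_rate, d0 = 0) {
  if (!is.numeric(sed_rate) || sed_rate <= 0) stop("sed_rate must be > 0")
  if (d0 < 0) stop("d0 must be >= 0")
  structure(list(sed_rate = sed_rate, d0 = d0), class = "burial_trajectory")
}

#' Burial depth of the interval top at a given model time
#'
#' @param traj a [burial_trajectory()].
#' @param t model time in years (>= 0); vectorized.
#' @return depth in m below seafloor.
#' @export
burial_depth <- function(traj, t) {
  stopifnot(inherits(traj, "burial_trajectory"))
  if (any(t < 0)) stop("t must be >= 0")
  traj$d0 + traj$sed_rate * 1e-3 * t
}

#' Build a mud-sand-mud sediment column
#'
#' Constructs a uniformly gridded 1-D column with a single sand bed centered in
#' the domain, bounded by mud above and below. Sand carries no POC but a high
#' microbial cell density; mud carries the initial POC and fewer cells. The
#' grid is cell-centered (nodes at `dz/2, 3dz/2, ...`) so that zero-flux
#' boundaries conserve `sum(field) * dz` exactly.
#'
#' Mud cell density is a constant plateau by default. An optional near-seafloor
#' enhancement (`cell_decay`) lets mud density decay exponentially with current
#' burial depth from `n_surface` down to the `n_mud` plateau, emulating the
#' compaction-driven decline of cell counts in fine-grained sediments; sand
#' density is always constant.
#'
#' @param domain_length interval thickness, m.
#' @param sand_thickness sand bed thickness, m (0 for an all-mud column).
#' @param dz node spacing, m; must resolve the sand bed (`dz < sand_thickness`
#'   when sand is present). Lengths that are not integer multiples of `dz` are
#'   snapped to the nearest node with a warning.
#' @param n_sand,n_mud microbial cell densities, cells per cm^3 of sediment.
#' @param poc_mud_wt initial mud POC content, wt% of grains.
#' @param porosity constant porosity shared by both lithologies.
#' @param grain_density grain density, g/cm^3.
#' @param cell_decay `NULL`, or `list(n_surface =, efold =)` giving the
#'   seafloor mud cell density (cells/cm^3) and the e-folding depth (m) of its
#'   decay toward the `n_mud` plateau.
#' @return an object of class `sediment_column`.
#' @examples
#' col <- build_column(20, 3, 0.05)
#' range(col$node_depths[col$lithology == "sand"])  # sand spans 8.5-11.5 m
#' @export
build_column <- function(domain_length, sand_thickness = 0, dz,
                         n_sand = 1e9, n_mud = 1e6,
                         poc_mud_wt = 0.5, porosity = 0.5,
                         grain_density = 2.65, cell_decay = NULL) {
  if (domain_length <= 0 || dz <= 0) stop("domain_length and dz must be positive")
  if (sand_thickness < 0) stop("sand_thickness must be >= 0")
  if (sand_thickness >= domain_length) stop("sand_thickness must be < domain_length")
  if (sand_thickness > 0 && dz >= sand_thickness)
    stop("dz must be smaller than sand_thickness (sand bed unresolved)")
  if (n_sand <= 0 || n_mud <= 0) stop("cell densities must be > 0")
  if (porosity <= 0 || porosity >= 1) stop("porosity must be in (0, 1)")

  n <- round(domain_length / dz)
  if (n < 3) stop("column must have at least 3 nodes")
  if (abs(n * dz - domain_length) > 1e-9 * domain_length) {
    warning(sprintf("domain_length snapped from %g to %g m (nearest node)",
                    domain_length, n * dz))
    domain_length <- n * dz
  }
  m <- round(sand_thickness / dz)
  if (sand_thickness > 0 && abs(m * dz - sand_thickness) > 1e-9 * sand_thickness) {
    warning(sprintf("sand_thickness snapped from %g to %g m (nearest node)",
                    sand_thickness, m * dz))
    sand_thickness <- m * dz
  }

  lith <- rep("mud", n)
  if (m > 0) {
    i0 <- round((n - m) / 2)
    lith[(i0 + 1):(i0 + m)] <- "sand"
  }
  is_mud <- lith == "mud"
  poc <- ifelse(is_mud, convert_poc(poc_mud_wt, grain_density, porosity), 0)
  ncell <- ifelse(is_mud, n_mud, n_sand)

  if (!is.null(cell_decay)) {
    if (!all(c("n_surface", "efold") %in% names(cell_decay)))
      stop("cell_decay must be a list with elements n_surface and efold")
    if (cell_decay$n_surface < n_mud) stop("cell_decay$n_surface must be >= n_mud")
    if (cell_decay$efold <= 0) stop("cell_decay$efold must be > 0")
  }

  structure(list(
    node_depths = (seq_len(n) - 0.5) * dz,
    dz = dz,
    domain_length = domain_length,
    lithology = lith,
    n_ferm = ncell,
    n_meth = ncell,
    n_sand = n_sand,
    n_mud = n_mud,
    poc_init = poc,
    poc_mud_wt = poc_mud_wt,
    porosity = porosity,
    grain_density = grain_density,
    sand_thickness = sand_thickness,
    cell_decay = cell_decay
  ), class = "sediment_column")
}

#' Per-node microbial cell densities at a given burial depth
#'
#' Returns fermenter and methanogen densities (cells/cm^3 sediment) for every
#' node. With `cell_decay` disabled this is just the per-lithology plateau;
#' with it enabled, mud nodes take
#' `max(n_mud, n_surface * exp(-(burial + z)/efold))`.
#'
#' @param col a [build_column()] result.
#' @param burial burial depth of the interval top, m below seafloor.
#' @return list with numeric vectors `ferm` and `meth`.
#' @export
cell_densities <- function(col, burial = 0) {
  stopifnot(inherits(col, "sediment_column"))
  nf <- col$n_ferm
  nm <- col$n_meth
  if (!is.null(col$cell_decay)) {
    d <- burial + col$node_depths
    mud <- col$lithology == "mud"
    enh <- pmax(col$n_mud, col$cell_decay$n_surface * exp(-d / col$cell_decay$efold))
    nf[mud] <- enh[mud]
    nm[mud] <- enh[mud]
  }
  list(ferm = nf, meth = nm)
}

#' Initial column state (all dissolved pools zero)
#'
#' State fields, per node: `P` POC (mM C per total pore volume), `H` HMW-DOC,
#' `L` LMW-DOC, `E` extracellular enzymes, `M` dissolved methane (all mM C per
#' residual pore-fluid volume), `S` hydrate saturation (pore-volume fraction),
#' `G` cumulative CO2 carbon and `Edec` cumulative decayed-enzyme carbon
#' (conservation ledgers, mM C per total pore volume), and the model time `t`
#' in years.
#'
#' @param col a [build_column()] result.
#' @return an object of class `column_state`.
#' @export
init_state <- function(col) {
  stopifnot(inherits(col, "sediment_column"))
  n <- length(col$node_depths)
  z <- numeric(n)
  structure(list(t = 0, P = col$poc_init, H = z, L = z, E = z, M = z,
                 S = z, G = z, Edec = z), class = "column_state")
}

#' Total tracked carbon in a column state
#'
#' Closed-system ledger: `sum(dz * (P + G + Edec + (1-S)*(H+L+E+M) + c_h*S))`,
#' in mM carbon times meters (per unit column cross-section, per unit
#' porosity). Constant in time up to integrator error for any scenario.
#'
#' @param state a `column_state`.
#' @param col the matching `sediment_column`.
#' @param c_h hydrate carbon molarity (mM), see [hydrate_carbon_density()].
#' @return total carbon, mM * m.
#' @export
total_carbon <- function(state, col, c_h = hydrate_carbon_density()) {
  th <- 1 - state$S
  col$dz * sum(state$P + state$G + state$Edec +
                 th * (state$H + state$L + state$E + state$M) +
                 c_h * state$S)
}

#' @export
print.sediment_column <- function(x, ...) {
  cat(sprintf("<sediment_column> %g m, dz = %g m (%d nodes), sand bed %g m\n",
              x$domain_length, x$dz, length(x$node_depths), x$sand_thickness))
  cat(sprintf("  mud POC %g wt%% (%.1f mM), cells %g (sand) / %g (mud) per cm^3\n",
              x$poc_mud_wt, max(x$poc_init), x$n_sand, x$n_mud))
  invisible(x)
}

#' @export
print.column_state <- function(x, ...) {
  cat(sprintf("<column_state> t = %g yr | max DOC %.3g mM | max S %.3g\n",
              x$t, max(x$H + x$L), max(x$S)))
  invisible(x)
}
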