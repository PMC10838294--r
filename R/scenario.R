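#' Assemble a simulation scenario
#'
#' Bundles the column, kinetics, transport, burial and solubility models with
#' the discretization and output controls used by [run_scenario()].
#'
#' @param column a [build_column()] result.
#' @param rates a [rate_constants()] object.
#' @param transport a [transport_params()] object.
#' @param burial a [burial_trajectory()].
#' @param solubility a [solubility_model()].
#' @param dt time step, years.
#' @param t_end end of the run, years. If not an integer multiple of `dt`, a
#'   final shortened step is taken (with a message).
#' @param snapshot_times times (years) at which full profiles are kept; the
#'   final state is always included.
#' @param series_dt cadence (years) of the scalar diagnostics series.
#' @param c_h hydrate carbon molarity, mM.
#' @param s_hfz saturation threshold defining hydrate-free zones.
#' @param s_top saturation threshold defining hydrate onset.
#' @param scheme diffusion scheme, `"cn"` or `"be"`.
#' @param name scenario label.
#' @return an object of class `rtm_scenario`.
#' @export
scenario <- function(column, rates, transport = transport_params(),
                     burial, solubility,
                     dt = 10, t_end = 3e5,
                     snapshot_times = NULL, series_dt = 1000,
                     c_h = hydrate_carbon_density(),
                     s_hfz = 0.01, s_top = 0.05,
                     scheme = c("cn", "be"), name = "custom") {
  stopifnot(inherits(column, "sediment_column"), inherits(rates, "rate_constants"),
            inherits(transport, "transport_params"),
            inherits(burial, "burial_trajectory"),
            inherits(solubility, "solubility_model"))
  scheme <- match.arg(scheme)
  if (dt <= 0 || t_end <= 0) stop("dt and t_end must be > 0")
  if (is.null(snapshot_times))
    snapshot_times <- seq(0, t_end, length.out = 31)[-1]
  structure(list(column = column, rates = rates, transport = transport,
                 burial = burial, solubility = solubility,
                 dt = dt, t_end = t_end,
                 snapshot_times = sort(unique(c(snapshot_times, t_end))),
                 series_dt = series_dt, c_h = c_h,
                 s_hfz = s_hfz, s_top = s_top, scheme = scheme, name = name),
            class = "rtm_scenario")
}

#' @export
print.rtm_scenario <- function(x, ...) {
  cat(sprintf("<rtm_scenario> '%s': %g m column, dt = %g yr, t_end = %g kyr\n",
              x$name, x$column$domain_length, x$dt, x$t_end / 1000))
  cat(sprintf("  K_eh = 10^%.2f /mM/s, K_fm = K_m = 10^%.2f /cell/s, burial %g mm/yr\n",
              log10(x$rates$K_eh), log10(x$rates$K_fm), x$burial$sed_rate))
  invisible(x)
}

#' Preset: thick-sand passive-margin scenario (Walker Ridge 313-H type)
#'
#' A 20 m interval with a centered 3 m sand bed, 0.5 wt% POC in the muds,
#' buried at 1 mm/yr for 300 kyr. Representative rate constants
#' `K_eh = 10^-12.6` mM^-1 s^-1 and `K_fm = K_m = 10^-21.5` s^-1 per cell.
#' Free parameters (solubility anchor and depth scale, diffusivities, enzyme
#' yield) are frozen at the values documented in the methods vignette.
#'
#' @param dz node spacing, m.
#' @param dt time step, years.
#' @param ... overrides passed to [scenario()] (e.g. `t_end`, `scheme`).
#' @return an `rtm_scenario`.
#' @export
scenario_wr313h <- function(dz = 0.05, dt = 10, ...) {
  col <- build_column(domain_length = 20, sand_thickness = 3, dz = dz,
                      n_sand = 1e9, n_mud = 1e6, poc_mud_wt = 0.5,
                      porosity = 0.5, grain_density = 2.65,
                      cell_decay = list(n_surface = 1e9, efold = 200))
  rc <- rate_constants(K_eh = 10^-12.6, K_fm = 10^-21.5,
                       beta = 0.01, E0 = 0.5, lambda_half = 1e4,
                       epsilon = 0.025, gamma_ch4 = 0.5)
  sm <- solubility_model("linear", c_ref = 45, d_ref = 0, d_scale = 700,
                         mud_multiplier = 1.006, bghsz_depth = 900)
  tp <- transport_params(D_hmw = 1e-10, D_lmw = 2.5e-10,
                         D_enz = 2.5e-11, D_ch4 = 2.5e-10)
  args <- list(column = col, rates = rc, transport = tp,
               burial = burial_trajectory(1), solubility = sm,
               dt = dt, t_end = 3e5, series_dt = 1000,
               snapshot_times = seq(1e4, 3e5, by = 1e4),
               name = "wr313h")
  do.call(scenario, utils::modifyList(args, list(...)))
}

#' Preset: thin-sand active-margin scenario (IODP U1325 type)
#'
#' A 2.5 m interval with a centered 5 cm sand bed (one repeating unit of the
#' thin-sand succession), 0.5 wt% POC in the muds, buried at 0.19 mm/yr for
#' 1200 kyr. Representative rate constants `K_eh = 10^-12.7` mM^-1 s^-1 and
#' `K_fm = K_m = 10^-23` s^-1 per cell. Hydrate is disallowed below the local
#' BGHSZ at 245 m. This preset defaults to backward-Euler diffusion: its
#' centimeter grid puts Crank-Nicolson far beyond its oscillation-free mesh
#' ratio, and the undamped scheme leaves a standing node-to-node ripple at
#' the sand boundary.
#'
#' @inheritParams scenario_wr313h
#' @return an `rtm_scenario`.
#' @export
scenario_u1325 <- function(dz = 0.005, dt = 20, ...) {
  col <- build_column(domain_length = 2.5, sand_thickness = 0.05, dz = dz,
                      n_sand = 1e9, n_mud = 1e6, poc_mud_wt = 0.5,
                      porosity = 0.5, grain_density = 2.65,
                      cell_decay = list(n_surface = 1e9, efold = 1000))
  rc <- rate_constants(K_eh = 10^-12.7, K_fm = 10^-23,
                       beta = 0.01, E0 = 0.5, lambda_half = 1e4,
                       epsilon = 0.0085, gamma_ch4 = 0.75)
  sm <- solubility_model("linear", c_ref = 32, d_ref = 0, d_scale = 2000,
                         mud_multiplier = 1.006, bghsz_depth = 245)
  tp <- transport_params(D_hmw = 1e-10, D_lmw = 2.5e-10,
                         D_enz = 2.5e-11, D_ch4 = 2.5e-10)
  args <- list(column = col, rates = rc, transport = tp,
               burial = burial_trajectory(0.19), solubility = sm,
               dt = dt, t_end = 1.2e6, series_dt = 2000,
               snapshot_times = seq(4e4, 1.2e6, by = 4e4),
               scheme = "be", name = "u1325")
  do.call(scenario, utils::modifyList(args, list(...)))
}

# flat key=value serialization -------------------------------------------

#' Write a scenario to a flat key=value configuration file
#'
#' Human-readable plain text; one `key = value` pair per line, `#` comments.
#' [read_scenario_config()] round-trips the file back into an equivalent
#' scenario.
#'
#' @param sc an `rtm_scenario`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(sc, path) {
  stopifnot(inherits(sc, "rtm_scenario"))
  col <- sc$column; rc <- sc$rates; tp <- sc$transport
  sm <- sc$solubility
  kv <- c(
    "# hydrateRTM scenario configuration",
    sprintf("name = %s", sc$name),
    "# --- column geometry (m) and lithology ---",
    sprintf("domain_length = %.10g", col$domain_length),
    sprintf("sand_thickness = %.10g", col$sand_thickness),
    sprintf("dz = %.10g", col$dz),
    sprintf("n_sand = %.10g", col$n_sand),        # cells per cm^3 sediment
    sprintf("n_mud = %.10g", col$n_mud),
    sprintf("poc_mud_wt = %.10g", col$poc_mud_wt),# wt% of grains
    sprintf("porosity = %.10g", col$porosity),
    sprintf("grain_density = %.10g", col$grain_density),
    if (!is.null(col$cell_decay)) c(
      sprintf("cell_decay_n_surface = %.10g", col$cell_decay$n_surface),
      sprintf("cell_decay_efold = %.10g", col$cell_decay$efold)),
    "# --- kinetics (rate constants in s^-1 units; see rate_constants) ---",
    sprintf("K_eh = %.10g", rc$K_eh),
    sprintf("K_fm = %.10g", rc$K_fm),
    sprintf("K_m = %.10g", rc$K_m),
    sprintf("beta = %.10g", rc$beta),
    sprintf("E0 = %.10g", rc$E0),
    sprintf("lambda_half = %.10g", rc$lambda_half), # yr
    sprintf("epsilon = %.10g", rc$epsilon),
    sprintf("gamma_ch4 = %.10g", rc$gamma_ch4),
    "# --- transport (m^2/s) ---",
    sprintf("D_hmw = %.10g", tp$D_hmw),
    sprintf("D_lmw = %.10g", tp$D_lmw),
    sprintf("D_enz = %.10g", tp$D_enz),
    sprintf("D_ch4 = %.10g", tp$D_ch4),
    "# --- burial (mm/yr, m) ---",
    sprintf("sed_rate = %.10g", sc$burial$sed_rate),
    sprintf("d0 = %.10g", sc$burial$d0),
    "# --- methane solubility (mM, m) ---",
    sprintf("sol_form = %s", sm$form),
    sprintf("c_ref = %.10g", sm$c_ref),
    sprintf("d_ref = %.10g", sm$d_ref),
    sprintf("d_scale = %.10g", sm$d_scale),
    sprintf("mud_multiplier = %.10g", sm$mud_multiplier),
    sprintf("bghsz_depth = %.10g", sm$bghsz_depth),
    "# --- discretization and outputs (yr, mM) ---",
    sprintf("dt = %.10g", sc$dt),
    sprintf("t_end = %.10g", sc$t_end),
    sprintf("series_dt = %.10g", sc$series_dt),
    sprintf("snapshot_times = %s", paste(sc$snapshot_times, collapse = ",")),
    sprintf("c_h = %.10g", sc$c_h),
    sprintf("s_hfz = %.10g", sc$s_hfz),
    sprintf("s_top = %.10g", sc$s_top),
    sprintf("scheme = %s", sc$scheme)
  )
  writeLines(kv, path)
  invisible(path)
}

#' Read a scenario from a flat key=value configuration file
#'
#' @param path configuration file path, or one of the preset names
#'   `"wr313h"` / `"u1325"`.
#' @return an `rtm_scenario`.
#' @export
read_scenario_config <- function(path) {
  if (path %in% c("wr313h", "u1325"))
    return(switch(path, wr313h = scenario_wr313h(), u1325 = scenario_u1325()))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  num <- function(key, default = NULL) {
    if (!key %in% names(vals)) {
      if (is.null(default)) stop("missing config key: ", key)
      return(default)
    }
    as.numeric(vals[[key]])
  }
  chr <- function(key, default = NULL) {
    if (!key %in% names(vals)) {
      if (is.null(default)) stop("missing config key: ", key)
      return(default)
    }
    vals[[key]]
  }
  decay <- NULL
  if ("cell_decay_efold" %in% names(vals))
    decay <- list(n_surface = num("cell_decay_n_surface"),
                  efold = num("cell_decay_efold"))
  col <- build_column(num("domain_length"), num("sand_thickness"), num("dz"),
                      num("n_sand"), num("n_mud"), num("poc_mud_wt"),
                      num("porosity"), num("grain_density"), cell_decay = decay)
  rc <- rate_constants(num("K_eh"), num("K_fm"), num("K_m"),
                       num("beta"), num("E0"), num("lambda_half"),
                       num("epsilon"), num("gamma_ch4"))
  tp <- transport_params(num("D_hmw"), num("D_lmw"), num("D_enz"), num("D_ch4"))
  sm <- solubility_model(chr("sol_form"), num("c_ref"), num("d_ref"),
                         num("d_scale"), num("mud_multiplier"),
                         num("bghsz_depth"))
  snaps <- as.numeric(strsplit(chr("snapshot_times", ""), ",")[[1]])
  scenario(col, rc, tp, burial_trajectory(num("sed_rate"), num("d0")), sm,
           dt = num("dt"), t_end = num("t_end"),
           snapshot_times = if (length(snaps)) snaps else NULL,
           series_dt = num("series_dt"), c_h = num("c_h"),
           s_hfz = num("s_hfz"), s_top = num("s_top"),
           scheme = chr("scheme"), name = chr("name", "custom"))
}
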