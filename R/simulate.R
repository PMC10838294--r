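#' Advance the model by one full time step
#'
#' Three-fractional-step (Strang) update: a Crank-Nicolson diffusion half
#' step, the full reaction step with equilibrium hydrate partition, then the
#' second diffusion half step followed by a re-projection onto the
#' hydrate-solution equilibrium so emitted states always satisfy the
#' dichotomy (S > 0 implies M = C_eq, otherwise M <= C_eq). The solubility
#' curve is evaluated at the end-of-step burial depth of each node, and the
#' microbial densities at the mid-step burial depth.
#'
#' @param state a `column_state`.
#' @param sc an [scenario()] object.
#' @param dt optional override of the scenario time step (years).
#' @return the advanced state.
#' @export
step_state <- function(state, sc, dt = sc$dt) {
  col <- sc$column
  state <- diffuse_all(state, sc$transport, col$dz, dt / 2, sc$scheme)

  nd <- cell_densities(col, burial_depth(sc$burial, state$t + dt / 2))
  state <- integrate_reactions(state, col, sc$rates, dt,
                               n_ferm = nd$ferm, n_meth = nd$meth)

  d_nodes <- burial_depth(sc$burial, state$t) + col$node_depths
  ce <- ceq(d_nodes, col$lithology, sc$solubility)
  state <- apply_partition(state, ce, sc$c_h)

  state <- diffuse_all(state, sc$transport, col$dz, dt / 2, sc$scheme)
  apply_partition(state, ce, sc$c_h)
}

# HFZ thicknesses (m) above and below the sand bed: contiguous mud nodes with
# S < s_hfz walking away from each sand edge, stopping at the first
# hydrate-bearing node or the domain edge.
.hfz_thickness <- function(S, lith, dz, s_hfz) {
  sand <- which(lith == "sand")
  if (!length(sand)) return(c(above = NA_real_, below = NA_real_))
  count_free <- function(idx) {
    k <- 0
    for (i in idx) {
      if (lith[i] != "mud") break
      if (S[i] >= s_hfz) break
      k <- k + 1
    }
    k * dz
  }
  c(above = count_free(rev(seq_len(min(sand) - 1))),
    below = count_free(seq(max(sand) + 1, length.out = length(S) - max(sand))))
}

# Hydrate level in the mud beyond the HFZs: max S over mud nodes farther from
# the sand than the current hydrate-free zones (NA when there is no such
# hydrate).
.mud_sh_beyond_hfz <- function(S, lith, dz, s_hfz) {
  sand <- which(lith == "sand")
  if (!length(sand)) return(if (any(S > 0)) max(S) else NA_real_)
  hfz <- .hfz_thickness(S, lith, dz, s_hfz)
  i_top <- min(sand) - 1 - round(hfz["above"] / dz)
  i_bot <- max(sand) + 1 + round(hfz["below"] / dz)
  keep <- c(if (i_top >= 1) seq_len(i_top),
            if (i_bot <= length(S)) i_bot:length(S))
  if (!length(keep)) return(NA_real_)
  m <- max(S[keep])
  if (m >= s_hfz) m else NA_real_
}

#' Run a full scenario
#'
#' Integrates the model from a zero-DOC initial state to `t_end`, recording a
#' scalar diagnostics series (peak DOC, sand and mud hydrate saturations,
#' hydrate-free-zone thicknesses, total tracked carbon) at the `series_dt`
#' cadence and full profiles at the snapshot times. Running maxima (peak DOC
#' anywhere/anytime, peak sand saturation) and hydrate onset are tracked at
#' every step. Aborts if the closed-system carbon ledger drifts by more than
#' 0.1% relative.
#'
#' @param sc an [scenario()] object.
#' @param verbose print progress every 100 series points.
#' @return an object of class `rtm_result` with elements `scenario`,
#'   `snapshots` (named list of `column_state`s), `series` (data frame),
#'   `final` (final state) and `track` (running extrema and onset records).
#' @export
run_scenario <- function(sc, verbose = FALSE) {
  stopifnot(inherits(sc, "rtm_scenario"))
  col <- sc$column
  sand <- col$lithology == "sand"
  mud <- !sand
  state <- init_state(col)
  c0 <- total_carbon(state, col, sc$c_h)

  n_steps <- ceiling(sc$t_end / sc$dt - 1e-9)
  partial <- sc$t_end - (n_steps - 1) * sc$dt
  if (partial < sc$dt - 1e-9)
    message(sprintf("t_end is not a multiple of dt; final step shortened to %g yr", partial))

  series_every <- max(1L, round(sc$series_dt / sc$dt))
  snap_steps <- unique(pmin(round(sc$snapshot_times / sc$dt), n_steps))

  track <- list(max_DOC = 0, t_max_DOC = NA_real_, max_SH_sand = 0,
                onset_any_t = NA_real_, onset_sand_t = NA_real_,
                onset_sand_node = NA_integer_)
  series <- vector("list", floor(n_steps / series_every) + 2L)
  snapshots <- list()
  si <- 0L

  record_series <- function(state) {
    hfz <- .hfz_thickness(state$S, col$lithology, col$dz, sc$s_hfz)
    data.frame(
      t = state$t,
      burial = burial_depth(sc$burial, state$t),
      max_DOC = max(state$H + state$L),
      max_SH_sand = if (any(sand)) max(state$S[sand]) else NA_real_,
      max_SH_mud = if (any(mud)) max(state$S[mud]) else NA_real_,
      mud_SH_beyond_hfz = .mud_sh_beyond_hfz(state$S, col$lithology, col$dz, sc$s_hfz),
      hfz_above = hfz[["above"]], hfz_below = hfz[["below"]],
      total_carbon = total_carbon(state, col, sc$c_h)
    )
  }
  si <- si + 1L
  series[[si]] <- record_series(state)

  for (k in seq_len(n_steps)) {
    dt_k <- if (k == n_steps) partial else sc$dt
    state <- step_state(state, sc, dt_k)

    doc_max <- max(state$H + state$L)
    if (doc_max > track$max_DOC) {
      track$max_DOC <- doc_max
      track$t_max_DOC <- state$t
    }
    if (any(sand)) {
      s_sand <- max(state$S[sand])
      if (s_sand > track$max_SH_sand) track$max_SH_sand <- s_sand
      if (is.na(track$onset_sand_t) && s_sand >= sc$s_top) {
        track$onset_sand_t <- state$t
        track$onset_sand_node <- which(sand)[which.max(state$S[sand])]
      }
    }
    if (is.na(track$onset_any_t) && max(state$S) >= sc$s_top)
      track$onset_any_t <- state$t

    if (k %% series_every == 0L || k == n_steps) {
      si <- si + 1L
      row <- record_series(state)
      series[[si]] <- row
      drift <- abs(row$total_carbon - c0) / max(c0, .Machine$double.eps)
      if (drift > 1e-3)
        stop(sprintf(paste0("carbon ledger drift %.3g at t = %g yr exceeds 1e-3; ",
                            "max|P,H,L,E,M,S| = %.3g %.3g %.3g %.3g %.3g %.3g"),
                     drift, state$t, max(state$P), max(state$H), max(state$L),
                     max(state$E), max(state$M), max(state$S)))
      if (verbose && si %% 100L == 0L)
        message(sprintf("t = %g kyr, DOC max %.3g mM, S sand %.3g",
                        state$t / 1000, row$max_DOC, row$max_SH_sand))
    }
    if (k %in% snap_steps)
      snapshots[[sprintf("t%.0f", state$t)]] <- state
  }

  structure(list(scenario = sc,
                 snapshots = snapshots,
                 series = do.call(rbind, series[seq_len(si)]),
                 final = state,
                 track = track),
            class = "rtm_result")
}

#' @export
print.rtm_result <- function(x, ...) {
  s <- summarize_run(x)
  cat(sprintf("<rtm_result> '%s' to %g kyr\n", x$scenario$name, x$final$t / 1000))
  cat(sprintf("  peak DOC %.3g mM at %g kyr | max sand S_H %.3g (final %.3g)\n",
              s$max_DOC, s$t_max_DOC / 1000, s$max_SH_sand, s$final_max_SH_sand))
  cat(sprintf("  hydrate onset %s kyr | HFZ above/below %.3g/%.3g m\n",
              format(s$onset_any_t / 1000), s$hfz_above, s$hfz_below))
  invisible(x)
}

#' Summary metrics of a completed run
#'
#' @param result an [run_scenario()] result.
#' @param at_time optional time (years) selecting the snapshot (nearest) used
#'   for the mud-hydrate level metric; default the final state.
#' @return a list of metrics: `max_DOC` (mM, over all nodes and times) and
#'   `t_max_DOC` (yr); `max_SH_sand` (over time) and `final_max_SH_sand`;
#'   `onset_any_t` / `onset_sand_t` (yr, first exceedance of the onset
#'   threshold, NA if never); `top_hydrate_depth` (mbsf of the first
#'   hydrate-bearing sand node at onset); `hfz_above` / `hfz_below` (m, at the
#'   final state); `mud_SH_beyond_hfz` (max S in mud beyond the HFZs at the
#'   selected snapshot); `carbon_drift` (relative, full run).
#' @export
summarize_run <- function(result, at_time = NULL) {
  stopifnot(inherits(result, "rtm_result"))
  sc <- result$scenario
  col <- sc$column
  tr <- result$track
  fin <- result$final

  st <- fin
  if (!is.null(at_time) && length(result$snapshots)) {
    ts <- vapply(result$snapshots, function(s) s$t, 0)
    st <- result$snapshots[[which.min(abs(ts - at_time))]]
  }
  hfz <- .hfz_thickness(fin$S, col$lithology, col$dz, sc$s_hfz)
  top_depth <- if (is.na(tr$onset_sand_t)) NA_real_ else
    burial_depth(sc$burial, tr$onset_sand_t) + col$node_depths[tr$onset_sand_node]
  cser <- result$series$total_carbon
  list(
    max_DOC = tr$max_DOC,
    t_max_DOC = tr$t_max_DOC,
    max_SH_sand = tr$max_SH_sand,
    final_max_SH_sand = if (any(col$lithology == "sand"))
      max(fin$S[col$lithology == "sand"]) else NA_real_,
    onset_any_t = tr$onset_any_t,
    onset_sand_t = tr$onset_sand_t,
    top_hydrate_depth = top_depth,
    hfz_above = hfz[["above"]],
    hfz_below = hfz[["below"]],
    mud_SH_beyond_hfz = .mud_sh_beyond_hfz(st$S, col$lithology, col$dz, sc$s_hfz),
    carbon_drift = max(abs(cser - cser[1])) / cser[1]
  )
}

#' DOC and methane generation-rate profiles
#'
#' Gross production rates per node at the given state: DOC generation is the
#' POC hydrolysis rate; methane generation is the methane fraction of the
#' methanogenesis rate. Reported in mM per kyr.
#'
#' @param state a `column_state`.
#' @param sc the [scenario()] it belongs to.
#' @return data frame with `depth` (m within the interval), `lithology`,
#'   `doc_gen` and `ch4_gen` (mM/kyr).
#' @export
generation_rate_profiles <- function(state, sc) {
  col <- sc$column
  nd <- cell_densities(col, burial_depth(sc$burial, state$t))
  r <- reaction_rates(state$P, state$H, state$L, state$E, sc$rates,
                      nd$ferm, nd$meth)
  per_kyr <- SECONDS_PER_YEAR * 1000
  data.frame(depth = col$node_depths, lithology = col$lithology,
             doc_gen = r$r_hyd * per_kyr,
             ch4_gen = sc$rates$gamma_ch4 * r$r_m * per_kyr)
}

#' Write a profile snapshot as delimited text
#'
#' Tab-separated columns `depth, lithology, P, H, L, E, M, S, G`, one row per
#' node, with the model time in a header comment.
#'
#' @param state a `column_state`.
#' @param col the matching `sediment_column`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(state, col, path) {
  df <- data.frame(depth = col$node_depths, lithology = col$lithology,
                   P = state$P, H = state$H, L = state$L, E = state$E,
                   M = state$M, S = state$S, G = state$G)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t_yr = %.10g", state$t), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a profile snapshot written by [write_snapshot()]
#'
#' @param path snapshot file path.
#' @return a data frame with attribute `t_yr`.
#' @export
read_snapshot <- function(path) {
  first <- readLines(path, n = 1)
  t_yr <- if (grepl("^# t_yr", first)) as.numeric(sub(".*=", "", first)) else NA_real_
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  attr(df, "t_yr") <- t_yr
  df
}
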