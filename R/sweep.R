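#' Specify a rate-constant grid sweep
#'
#' Defines a log10 grid over the enzyme-driven hydrolysis constant `K_eh` and
#' the fermentation constant `K_fm` (with `K_m` tied to `K_fm` throughout),
#' run against a base scenario. Constraints are named predicates over the
#' summary metrics, e.g.
#' `list(doc = list(metric = "max_DOC", op = "le", value = 20))`.
#'
#' @param base an [scenario()] object supplying everything except the two
#'   swept constants.
#' @param log10_keh,log10_kfm numeric `c(min, max, n)` grid definitions
#'   (n >= 1; a single value when min == max or n == 1).
#' @param constraints named list of predicates; each is a list with elements
#'   `metric` (a [summarize_run()] metric name), `op` (one of `"lt"`, `"le"`,
#'   `"gt"`, `"ge"`, `"between"`) and `value` (length 2 for `"between"`).
#' @param fidelity `"fast"` (dz and dt doubled, default for grids) or
#'   `"full"`.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(base, log10_keh, log10_kfm, constraints = list(),
                       fidelity = c("fast", "full")) {
  stopifnot(inherits(base, "rtm_scenario"))
  fidelity <- match.arg(fidelity)
  axis <- function(x) {
    if (length(x) == 1) return(x)
    if (length(x) != 3) stop("grid axes must be c(min, max, n) or a single value")
    if (x[3] < 1) stop("grid must have n >= 1 per axis")
    seq(x[1], x[2], length.out = x[3])
  }
  structure(list(base = base, keh = axis(log10_keh), kfm = axis(log10_kfm),
                 constraints = constraints, fidelity = fidelity),
            class = "sweep_spec")
}

# Rebuild a scenario with new rate constants (K_m = K_fm, K_o re-derived) and
# optionally coarsened discretization.
.sweep_point_scenario <- function(base, log10_keh, log10_kfm, fidelity) {
  rc0 <- base$rates
  rc <- rate_constants(K_eh = 10^log10_keh, K_fm = 10^log10_kfm,
                       beta = rc0$beta, E0 = rc0$E0,
                       lambda_half = rc0$lambda_half,
                       epsilon = rc0$epsilon, gamma_ch4 = rc0$gamma_ch4)
  sc <- base
  sc$rates <- rc
  if (fidelity == "fast") {
    col0 <- base$column
    sc$column <- build_column(col0$domain_length, col0$sand_thickness,
                              col0$dz * 2, col0$n_sand, col0$n_mud,
                              col0$poc_mud_wt, col0$porosity,
                              col0$grain_density, col0$cell_decay)
    sc$dt <- base$dt * 2
  }
  sc
}

#' Run a rate-constant grid sweep
#'
#' Executes the base scenario at every grid point, collecting the summary
#' metrics and evaluating the constraint predicates. Individual point
#' failures (e.g. saturation overflow at extreme constants) are recorded and
#' the sweep continues. Deterministic given the spec.
#'
#' @param spec a [sweep_spec()].
#' @param star optional `c(log10_keh, log10_kfm)`; the matching cell is re-run
#'   at full fidelity regardless of the sweep fidelity.
#' @param verbose print one line per grid point.
#' @return an object of class `sweep_result`: a data frame of per-point
#'   metrics and constraint columns (`ok_<name>`), with the spec attached as
#'   an attribute.
#' @export
run_sweep <- function(spec, star = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- expand.grid(log10_Keh = spec$keh, log10_Kfm = spec$kfm,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fid <- spec$fidelity
    if (!is.null(star) &&
        isTRUE(all.equal(unname(unlist(grid[i, ])), unname(star), tolerance = 1e-9)))
      fid <- "full"
    sc <- .sweep_point_scenario(spec$base, grid$log10_Keh[i], grid$log10_Kfm[i], fid)
    m <- tryCatch(summarize_run(run_scenario(sc)), error = function(e) e)
    if (inherits(m, "error")) {
      rows[[i]] <- data.frame(grid[i, ], fidelity = fid,
                              max_DOC = NA_real_, t_max_DOC = NA_real_,
                              max_SH_sand = NA_real_, final_max_SH_sand = NA_real_,
                              top_hydrate_depth = NA_real_,
                              error = conditionMessage(m))
    } else {
      rows[[i]] <- data.frame(grid[i, ], fidelity = fid,
                              max_DOC = m$max_DOC, t_max_DOC = m$t_max_DOC,
                              max_SH_sand = m$max_SH_sand,
                              final_max_SH_sand = m$final_max_SH_sand,
                              top_hydrate_depth = m$top_hydrate_depth,
                              error = NA_character_)
    }
    if (verbose)
      message(sprintf("Keh 10^%.2f Kfm 10^%.2f: DOC %.3g, S %.3g",
                      grid$log10_Keh[i], grid$log10_Kfm[i],
                      rows[[i]]$max_DOC, rows[[i]]$max_SH_sand))
  }
  out <- do.call(rbind, rows)
  for (nm in names(spec$constraints))
    out[[paste0("ok_", nm)]] <- .eval_constraint(out, spec$constraints[[nm]])
  out$ok_all <- if (length(spec$constraints))
    Reduce(`&`, out[paste0("ok_", names(spec$constraints))]) else TRUE
  structure(out, spec = spec, class = c("sweep_result", "data.frame"))
}

.eval_constraint <- function(metrics, con) {
  v <- metrics[[con$metric]]
  if (is.null(v)) stop("unknown sweep metric: ", con$metric)
  ok <- switch(con$op,
    lt = v < con$value, le = v <= con$value,
    gt = v > con$value, ge = v >= con$value,
    between = v >= con$value[1] & v <= con$value[2],
    stop("unknown constraint op: ", con$op))
  ok & !is.na(v)
}

#' Constraint-satisfaction region of a sweep
#'
#' Evaluates the constraint mask on the grid and traces its boundary with a
#' marching-squares pass on the 0/1 mask (segments at the 0.5 level). Also
#' notes whether the region touches the high-`K_fm` edge, i.e. whether it is
#' open in that direction.
#'
#' @param result a [run_sweep()] result.
#' @param constraints optional constraint list overriding the spec's.
#' @return list with `mask` (matrix, Keh rows x Kfm columns), `boundary`
#'   (data frame of segment endpoints `x0, y0, x1, y1` in log10 units),
#'   `open_high_kfm` (logical) and `n_pass`.
#' @export
constraint_region <- function(result, constraints = NULL) {
  spec <- attr(result, "spec")
  if (is.null(constraints)) constraints <- spec$constraints
  ok <- Reduce(`&`, lapply(constraints, function(con) .eval_constraint(result, con)))
  mask <- matrix(ok, nrow = length(spec$keh), ncol = length(spec$kfm))
  if (!any(mask)) warning("constraint region is empty")
  boundary <- .marching_squares(spec$keh, spec$kfm, mask)
  structure(list(mask = mask, boundary = boundary,
                 open_high_kfm = any(mask[, ncol(mask)]),
                 n_pass = sum(mask)), class = "constraint_region")
}

# Segments of the 0.5-level contour of a binary mask on grid (x_i, y_j).
# The mask is padded with a FALSE ring (half a cell outside the grid) so a
# region reaching the grid edge — including an all-true mask — still yields a
# closed boundary along the grid frame.
.marching_squares <- function(x, y, mask) {
  nx0 <- length(x); ny0 <- length(y)
  dx <- if (nx0 > 1) x[2] - x[1] else 1
  dy <- if (ny0 > 1) y[2] - y[1] else 1
  x <- c(x[1] - dx, x, x[nx0] + dx)
  y <- c(y[1] - dy, y, y[ny0] + dy)
  padded <- matrix(FALSE, nx0 + 2, ny0 + 2)
  padded[2:(nx0 + 1), 2:(ny0 + 1)] <- mask
  mask <- padded
  segs <- list()
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) return(data.frame(x0 = numeric(), y0 = numeric(),
                                          x1 = numeric(), y1 = numeric()))
  mid <- function(a, b) (a + b) / 2
  for (i in seq_len(nx - 1)) for (j in seq_len(ny - 1)) {
    v <- c(mask[i, j], mask[i + 1, j], mask[i + 1, j + 1], mask[i, j + 1])
    if (all(v) || !any(v)) next
    # edge midpoints of the cell: bottom, right, top, left
    pts <- list(b = c(mid(x[i], x[i + 1]), y[j]),
                r = c(x[i + 1], mid(y[j], y[j + 1])),
                t = c(mid(x[i], x[i + 1]), y[j + 1]),
                l = c(x[i], mid(y[j], y[j + 1])))
    cross <- c(b = v[1] != v[2], r = v[2] != v[3],
               t = v[4] != v[3], l = v[1] != v[4])
    e <- names(cross)[cross]
    # 2 crossings -> one segment; 4 (saddle) -> two segments paired b-r, t-l
    if (length(e) == 2) {
      segs[[length(segs) + 1]] <- c(pts[[e[1]]], pts[[e[2]]])
    } else if (length(e) == 4) {
      segs[[length(segs) + 1]] <- c(pts$b, pts$r)
      segs[[length(segs) + 1]] <- c(pts$t, pts$l)
    }
  }
  if (!length(segs)) return(data.frame(x0 = numeric(), y0 = numeric(),
                                       x1 = numeric(), y1 = numeric()))
  m <- do.call(rbind, segs)
  data.frame(x0 = m[, 1], y0 = m[, 2], x1 = m[, 3], y1 = m[, 4])
}
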