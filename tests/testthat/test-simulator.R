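test_that("zero-POC column is a global fixed point of the full step", {
  col <- build_column(5, 1, 0.25, poc_mud_wt = 0)
  rc <- rate_constants(K_eh = 10^-12.6, K_fm = 10^-21.5, epsilon = 0.025)
  sc <- scenario(col, rc, transport_params(), burial_trajectory(1),
                 solubility_model(), dt = 50, t_end = 5000,
                 snapshot_times = 5000, name = "zero")
  res <- run_scenario(sc)
  for (f in c("P", "H", "L", "E", "M", "S", "G", "Edec"))
    expect_identical(res$final[[f]], rep(0, length(col$node_depths)))
})

test_that("step with all rates and diffusivities zero is the identity", {
  col <- build_column(5, 1, 0.25)
  rc <- rate_constants(K_eh = 0, K_fm = 0, lambda_half = Inf)
  sc <- scenario(col, rc, transport_params(0, 0, 0, 0), burial_trajectory(1),
                 solubility_model(), dt = 50, t_end = 5000, name = "inert")
  st <- init_state(col)
  st$H <- runif(length(st$P), 0, 3)
  st$M <- runif(length(st$P), 0, 10)
  out <- step_state(st, sc)
  expect_equal(out$t, 50)
  for (f in c("P", "H", "L", "E", "M", "S", "G", "Edec"))
    expect_equal(out[[f]], st[[f]], tolerance = 1e-14)
})

test_that("full split step self-converges at second order (Richardson)", {
  # rate constants sized so the reaction stage never sub-cycles, keeping the
  # splitting error the leading dt-dependence; horizon before hydrate onset
  col <- build_column(10, 1.5, 0.25, n_sand = 1e8, n_mud = 1e6)
  rc <- rate_constants(K_eh = 10^-12.3, K_fm = 10^-21.5, epsilon = 0.025)
  base <- scenario(col, rc, transport_params(), burial_trajectory(1),
                   solubility_model(), t_end = 4000, series_dt = 4000,
                   snapshot_times = 4000, name = "richardson")
  run_dt <- function(dt) {
    sc <- base
    sc$dt <- dt
    fin <- run_scenario(sc)$final
    unlist(fin[c("P", "H", "L", "E", "M")])
  }
  s40 <- run_dt(40); s20 <- run_dt(20); s10 <- run_dt(10)
  e1 <- sqrt(sum((s40 - s20)^2))
  e2 <- sqrt(sum((s20 - s10)^2))
  expect_gt(e1 / e2, 2.8)
  expect_lt(e1 / e2, 6)
})

test_that("hydrate-forming run conserves carbon and satisfies the dichotomy", {
  col <- build_column(10, 1.5, 0.25)
  rc <- rate_constants(K_eh = 10^-12, K_fm = 10^-21.5, epsilon = 0.025)
  sm <- solubility_model("linear", c_ref = 1, d_scale = 700,
                         mud_multiplier = 1.006)
  sc <- scenario(col, rc, transport_params(), burial_trajectory(1), sm,
                 dt = 20, t_end = 3e4, series_dt = 500,
                 snapshot_times = c(1e4, 2e4, 3e4), name = "hyd")
  res <- run_scenario(sc)
  expect_gt(max(res$final$S), 0)  # hydrate actually formed
  expect_lt(summarize_run(res)$carbon_drift, 1e-3)
  for (snap in res$snapshots) {
    d <- burial_depth(sc$burial, snap$t) + col$node_depths
    ce <- ceq(d, col$lithology, sc$solubility)
    hyd <- snap$S > 0
    if (any(hyd)) expect_lt(max(abs(snap$M[hyd] - ce[hyd])), 1e-8)
    expect_true(all(snap$M[!hyd] <= ce[!hyd] + 1e-8))
    expect_true(all(snap$S >= 0 & snap$S < 1))
  }
})

test_that("hydrate-free zone and mud-level metrics match a direct count", {
  col <- build_column(10, 2, 0.5)  # 8 mud nodes above, 8 below
  S <- numeric(20)
  S[col$lithology == "sand"] <- 0.2
  hfz <- hydrateRTM:::.hfz_thickness(S, col$lithology, col$dz, 0.01)
  # no mud hydrate at all: HFZ spans the full mud thickness on each side
  expect_equal(unname(hfz), c(4, 4))
  expect_true(is.na(hydrateRTM:::.mud_sh_beyond_hfz(S, col$lithology, col$dz, 0.01)))

  # hydrate beyond 1.5 m of clean mud above, 1 m below
  S[c(1:5, 15:20)] <- 0.12
  hfz2 <- hydrateRTM:::.hfz_thickness(S, col$lithology, col$dz, 0.01)
  expect_equal(unname(hfz2), c(1.5, 1.0))
  expect_equal(hydrateRTM:::.mud_sh_beyond_hfz(S, col$lithology, col$dz, 0.01), 0.12)
})

test_that("DOC responds monotonically to the rate constants", {
  base <- function(keh, kfm) {
    col <- build_column(10, 1.5, 0.25)
    rc <- rate_constants(K_eh = keh, K_fm = kfm, epsilon = 0.025)
    sc <- scenario(col, rc, transport_params(), burial_trajectory(1),
                   solubility_model(), dt = 40, t_end = 2e4,
                   series_dt = 2000, snapshot_times = 2e4, name = "mono")
    summarize_run(run_scenario(sc))$max_DOC
  }
  # more vigorous hydrolysis -> more DOC
  doc_keh <- vapply(10^c(-13, -12.6, -12.2), base, 0, kfm = 10^-21.5)
  expect_true(all(diff(doc_keh) > 0))
  # faster fermentation consumes DOC harder -> less DOC
  doc_kfm <- vapply(10^c(-22, -21.5, -21), base, 0, keh = 10^-12.6)
  expect_true(all(diff(doc_kfm) < 0))
})

test_that("generation-rate profiles are zero for a zero state", {
  sc <- scenario_wr313h(dz = 0.5, dt = 100, t_end = 1000)
  st <- init_state(sc$column)
  st$P[] <- 0
  g <- generation_rate_profiles(st, sc)
  expect_identical(g$doc_gen, rep(0, nrow(g)))
  expect_identical(g$ch4_gen, rep(0, nrow(g)))
})

test_that("scenario configs round-trip and presets resolve by name", {
  sc <- scenario_wr313h(dz = 0.5, dt = 100)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_scenario_config(sc, path)
  sc2 <- read_scenario_config(path)
  expect_equal(sc2$rates$K_eh, sc$rates$K_eh)
  expect_equal(sc2$rates$K_o, sc$rates$K_o)
  expect_equal(sc2$solubility$mud_multiplier, sc$solubility$mud_multiplier)
  expect_equal(sc2$column$poc_init, sc$column$poc_init)
  expect_equal(sc2$column$cell_decay, sc$column$cell_decay)
  expect_equal(sc2$transport, sc$transport)
  expect_equal(sc2$snapshot_times, sc$snapshot_times)

  pre <- read_scenario_config("u1325")
  expect_equal(pre$burial$sed_rate, 0.19)
  expect_equal(pre$scheme, "be")

  # shipped preset configs match the in-code presets
  shipped <- read_scenario_config(system.file("extdata", "wr313h.cfg",
                                              package = "hydrateRTM"))
  ref <- scenario_wr313h()
  expect_equal(shipped$rates, ref$rates)
  expect_equal(shipped$solubility, ref$solubility)
  expect_equal(shipped$column$n_ferm, ref$column$n_ferm)
})

test_that("a t_end off the dt grid takes a shortened final step", {
  col <- build_column(5, 1, 0.25)
  rc <- rate_constants(K_eh = 10^-12.6, K_fm = 10^-21.5, epsilon = 0.025)
  sc <- scenario(col, rc, transport_params(), burial_trajectory(1),
                 solubility_model(), dt = 30, t_end = 1000, name = "partial")
  expect_message(res <- run_scenario(sc), "shortened")
  expect_equal(res$final$t, 1000)
})
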