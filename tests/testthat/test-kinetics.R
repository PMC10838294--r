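test_that("enzyme decay constant follows the half-life closed form", {
  # ln2 / (1e4 yr * 3.15576e7 s/yr)
  expect_rel_equal(enzyme_decay_constant(1e4), 2.1963e-12, 1e-4)
  expect_rel_equal(enzyme_decay_constant(1), 2.1963e-8, 1e-4)
  expect_identical(enzyme_decay_constant(Inf), 0)
  # scales as 1/lambda
  expect_rel_equal(enzyme_decay_constant(500), 20 * enzyme_decay_constant(1e4), 1e-12)
  expect_error(enzyme_decay_constant(0))
  expect_error(enzyme_decay_constant(-3))
})

test_that("derived rate constants stay consistent", {
  rc <- rate_constants(K_eh = 10^-12.6, K_fm = 10^-21.5, beta = 0.01, E0 = 0.5,
                       lambda_half = 1e4)
  expect_identical(rc$K_o, 0.01 * 0.5 * 10^-12.6)
  expect_identical(rc$K_m, rc$K_fm)
  expect_identical(rc$K_ed, enzyme_decay_constant(1e4))
  expect_error(rate_constants(1e-13, 1e-22, epsilon = 0), "epsilon")
  expect_error(rate_constants(1e-13, 1e-22, gamma_ch4 = 1.5), "gamma")
})

test_that("rate laws match hand arithmetic (per-litre cell pairing)", {
  rc <- rate_constants(K_eh = 10^-12.6, K_fm = 10^-21.5, beta = 0.01, E0 = 0.5)
  # hydrolysis is cell-free: (K_o + K_eh E) P with E = E0 reference level
  r <- reaction_rates(P = 1103.2, H = 0, L = 0, E = 0.5, rc, n_ferm = 1e9)
  expect_rel_equal(r$r_hyd, (0.005 + 0.5) * 10^-12.6 * 1103.2, 1e-12)
  expect_rel_equal(r$r_hyd, 1.399e-10, 1e-3)
  # fermentation: K_fm x cells per litre x H; 1e9 cells/cm3 = 1e12 /L
  r2 <- reaction_rates(P = 0, H = 1, L = 0, E = 0, rc, n_ferm = 1e9)
  expect_rel_equal(r2$r_fm, 10^-21.5 * 1e12, 1e-12)
  # the mud/sand cell contrast carries through as exactly 1000x
  r3 <- reaction_rates(P = 0, H = 1, L = 0, E = 0, rc, n_ferm = 1e6)
  expect_rel_equal(r2$r_fm / r3$r_fm, 1000, 1e-12)
  # all-zero state gives all-zero rates
  r0 <- reaction_rates(0, 0, 0, 0, rc, 1e9)
  expect_identical(unlist(r0), c(r_hyd = 0, r_fm = 0, r_m = 0, r_ed = 0))
  expect_error(reaction_rates(-1, 0, 0, 0, rc, 1e9), "negative")
})

test_that("reaction step: fixed point at zero and exact enzyme decay", {
  col <- build_column(1, 0.25, 0.05)
  rc <- rate_constants(K_eh = 10^-12.6, K_fm = 10^-21.5, epsilon = 0.025)
  st <- init_state(col)
  st$P[] <- 0
  out <- integrate_reactions(st, col, rc, dt = 100)
  for (f in c("P", "H", "L", "E", "M", "G", "Edec"))
    expect_identical(out[[f]], st[[f]])

  # enzymes alone halve over one half-life (closed-form exponential oracle)
  st2 <- init_state(col)
  st2$P[] <- 0
  st2$E[] <- 1
  for (i in 1:1000) st2 <- integrate_reactions(st2, col, rc, dt = 10)
  expect_rel_equal(st2$E[1], 0.5, 1e-4)
  expect_equal(st2$t, 1e4)
  # decayed carbon accounted in the ledger
  expect_rel_equal(st2$E[1] + st2$Edec[1], 1, 1e-10)
})

test_that("reaction step agrees with a stiff adaptive ODE oracle", {
  col <- build_column(1, 0.25, 0.05)
  rc <- rate_constants(K_eh = 10^-12.6, K_fm = 10^-21.5, epsilon = 0.025,
                       gamma_ch4 = 0.5)
  n <- 1e9
  y0 <- c(P = 1103.2, H = 1, L = 1, E = 0.5, M = 0, G = 0, D = 0)
  f <- function(t, y, p) {
    r_hyd <- (rc$K_o + rc$K_eh * y["E"]) * y["P"]
    r_fm <- rc$K_fm * 1e3 * n * y["H"]
    r_m <- rc$K_m * 1e3 * n * y["L"]
    r_ed <- rc$K_ed * y["E"]
    list(c(-r_hyd, r_hyd - r_fm, (1 - rc$epsilon) * r_fm - r_m,
           rc$epsilon * r_fm - r_ed, rc$gamma_ch4 * r_m,
           (1 - rc$gamma_ch4) * r_m, r_ed))
  }
  t_end <- 1000  # yr
  ref <- deSolve::lsoda(y0, c(0, t_end * 31557600), f, NULL,
                        rtol = 1e-12, atol = 1e-12)
  ref <- ref[2, -1]

  st <- init_state(col)
  st$P[] <- y0["P"]; st$H[] <- y0["H"]; st$L[] <- y0["L"]; st$E[] <- y0["E"]
  for (i in seq_len(t_end / 0.25))
    st <- integrate_reactions(st, col, rc, dt = 0.25, n_ferm = rep(n, 20),
                              n_meth = rep(n, 20))
  got <- c(st$P[1], st$H[1], st$L[1], st$E[1], st$M[1], st$G[1], st$Edec[1])
  for (i in seq_along(got))
    expect_rel_equal(got[i], unname(ref[i]), 1e-6)
})

test_that("reaction step conserves carbon and is monotone where required", {
  col <- build_column(2, 0.5, 0.1)
  rc <- rate_constants(K_eh = 10^-12.6, K_fm = 10^-21.5, epsilon = 0.025)
  st <- init_state(col)
  st$H[] <- 2; st$L[] <- 1; st$E[] <- 0.3
  st$S[5] <- 0.2  # hydrate present: pools in residual fluid
  prev <- st
  for (i in 1:50) {
    st <- integrate_reactions(st, col, rc, dt = 50)
    th <- 1 - st$S
    tot <- st$P + th * (st$H + st$L + st$E + st$M) + st$G + st$Edec
    tot0 <- prev$P + (1 - prev$S) * (prev$H + prev$L + prev$E + prev$M) +
      prev$G + prev$Edec
    expect_lt(max(abs(tot - tot0) / tot0), 1e-10)
    expect_true(all(st$P <= prev$P))          # POC non-increasing
    expect_true(all(st$G >= prev$G))          # CO2 ledger non-decreasing
    prev <- st
  }

  # with epsilon -> 0 fermentation makes no enzymes: E decays from any start
  rc0 <- rate_constants(K_eh = 10^-12.6, K_fm = 10^-21.5, epsilon = 1e-12)
  st <- init_state(col); st$E[] <- 1; st$H[] <- 5
  for (i in 1:20) {
    prev_E <- st$E
    st <- integrate_reactions(st, col, rc0, dt = 100)
    expect_true(all(st$E <= prev_E))
  }

  # with K_eh = K_o = 0, POC is inert
  rc2 <- rate_constants(K_eh = 0, K_fm = 1e-22)
  st <- init_state(col); st$E[] <- 1
  st2 <- integrate_reactions(st, col, rc2, dt = 1000)
  expect_identical(st2$P, st$P)
})

test_that("reaction integrator is second order (error ~4x down when dt halves)", {
  col <- build_column(1, 0.25, 0.05)
  # constants sized so the stability guard takes no sub-steps at either dt,
  # leaving the pure midpoint order visible
  rc <- rate_constants(K_eh = 10^-11.5, K_fm = 10^-22, epsilon = 0.025)
  n <- 1e9
  y0 <- c(P = 1000, H = 5, L = 5, E = 1, M = 0, G = 0, D = 0)
  f <- function(t, y, p) {
    r_hyd <- (rc$K_o + rc$K_eh * y["E"]) * y["P"]
    r_fm <- rc$K_fm * 1e3 * n * y["H"]
    r_m <- rc$K_m * 1e3 * n * y["L"]
    r_ed <- rc$K_ed * y["E"]
    list(c(-r_hyd, r_hyd - r_fm, (1 - rc$epsilon) * r_fm - r_m,
           rc$epsilon * r_fm - r_ed, rc$gamma_ch4 * r_m,
           (1 - rc$gamma_ch4) * r_m, r_ed))
  }
  t_end <- 2000
  ref <- deSolve::lsoda(y0, c(0, t_end * 31557600), f, NULL,
                        rtol = 1e-13, atol = 1e-13)[2, -1]
  run_dt <- function(dt) {
    st <- init_state(col)
    st$P[] <- y0["P"]; st$H[] <- y0["H"]; st$L[] <- y0["L"]; st$E[] <- y0["E"]
    for (i in seq_len(t_end / dt))
      st <- integrate_reactions(st, col, rc, dt = dt,
                                n_ferm = rep(n, 20), n_meth = rep(n, 20))
    c(st$P[1], st$H[1], st$L[1], st$E[1], st$M[1], st$G[1], st$Edec[1])
  }
  err <- function(dt) sqrt(sum((run_dt(dt) - ref)^2))
  ratio <- err(20) / err(10)
  expect_gt(ratio, 2.8)
  expect_lt(ratio, 5.5)
})
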