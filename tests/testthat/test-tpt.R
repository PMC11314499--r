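test_that("committors satisfy boundary conditions and closed forms", {
  m2 <- estimate_msm(matrix(c(9, 1, 1, 9), 2), lag = 1)
  q <- committors(m2, A = 1, B = 2)
  expect_equal(q$q_plus, c(0, 1))
  expect_equal(q$q_minus, c(1, 0))

  # symmetric 3-state birth-death chain: midpoint committor 1/2
  C3 <- matrix(c(2, 2, 0,
                 1, 2, 1,
                 0, 2, 2), 3, byrow = TRUE) * 100
  m3 <- estimate_msm(C3, reversible = FALSE, lag = 1)
  expect_equal(m3$P[2, ], c(0.25, 0.5, 0.25))
  q3 <- committors(m3, A = 1, B = 3)
  expect_equal(q3$q_plus, c(0, 0.5, 1), tolerance = 1e-12)

  # gambler's ruin on 6 states: q+_i = (i-1)/5
  n <- 6
  P <- matrix(0, n, n)
  for (i in 2:(n - 1)) { P[i, i - 1] <- 0.5; P[i, i + 1] <- 0.5 }
  P[1, 2] <- 1; P[n, n - 1] <- 1
  C <- round(P * 1000)
  mg <- estimate_msm(C, reversible = FALSE, lag = 1)
  qg <- committors(mg, A = 1, B = 6)
  expect_equal(qg$q_plus, (0:5) / 5, tolerance = 1e-10)
})

test_that("linear solve and fixed-point iteration agree on random models", {
  for (sd_ in 1:5) {
    m <- random_reversible_msm(20, seed = sd_)
    qs <- committors(m, A = 1:2, B = 19:20, method = "solve")
    qi <- committors(m, A = 1:2, B = 19:20, method = "iterate")
    expect_lt(max(abs(qs$q_plus - qi$q_plus)), 1e-12)
    expect_true(all(qs$q_plus >= 0 & qs$q_plus <= 1))
  }
})

test_that("the flux matrix reproduces the hand-worked two-state example", {
  # P = [[0.9, 0.1], [0.2, 0.8]]: pi = (2/3, 1/3), flux = 2/3 * 0.1 = 1/15
  m <- estimate_msm(matrix(c(90, 20, 10, 80), 2), reversible = FALSE,
                    lag = 1, frame_interval = 1)
  fx <- flux_matrix(m, A = 1, B = 2)
  expect_equal(fx$total_flux, 1 / 15, tolerance = 1e-12)
  expect_equal(fx$gross[1, 2], 1 / 15, tolerance = 1e-12)
})

test_that("flux is conserved and vanishes for unreachable sinks", {
  for (sd_ in 1:5) {
    m <- random_reversible_msm(20, seed = 10 + sd_)
    fx <- flux_matrix(m, A = 1:3, B = 18:20)
    n <- nrow(m$P)
    out_A <- sum(fx$net[1:3, setdiff(1:n, 1:3)])
    in_B <- sum(fx$net[setdiff(1:n, 18:20), 18:20])
    expect_equal(out_A, in_B, tolerance = 1e-10)
    # conservation at every intermediate state
    inter <- setdiff(1:n, c(1:3, 18:20))
    imbalance <- rowSums(fx$net)[inter] - colSums(fx$net)[inter]
    expect_lt(max(abs(imbalance)), 1e-10)
    # reversed problem carries the same total flux
    fx_rev <- flux_matrix(m, A = 18:20, B = 1:3)
    expect_equal(fx_rev$total_flux, fx$total_flux, tolerance = 1e-10)
  }

  # disconnected sink: committor zero on the source component
  P <- matrix(0, 4, 4)
  P[1:2, 1:2] <- matrix(c(0.9, 0.1, 0.1, 0.9), 2)
  P[3:4, 3:4] <- matrix(c(0.8, 0.2, 0.2, 0.8), 2)
  model <- structure(list(P = P, pi = rep(0.25, 4), reversible = TRUE,
                          lag = 1L, lag_ns = 1, frame_interval = 1),
                     class = "msm_model")
  fx0 <- flux_matrix(model, A = 1, B = 3)
  expect_equal(fx0$total_flux, 0, tolerance = 1e-12)
})

test_that("pathway decomposition handles unique, parallel and random routes", {
  # strict chain 1 -> 2 -> 3: one pathway at 100%
  C <- matrix(c(8, 2, 0,
                2, 6, 2,
                0, 2, 8), 3, byrow = TRUE) * 50
  m <- estimate_msm(C, lag = 1)
  fx <- flux_matrix(m, A = 1, B = 3)
  pw <- decompose_pathways(fx)
  expect_equal(length(pw), 1)
  expect_equal(pw[[1]]$states, c(1, 2, 3))
  expect_equal(pw[[1]]$percentage, 100)

  # diamond with two equivalent branches: 50/50
  Cd <- matrix(c(0, 5, 5, 0,
                 5, 0, 0, 5,
                 5, 0, 0, 5,
                 0, 5, 5, 0), 4, byrow = TRUE) * 100 + diag(4)
  md <- estimate_msm(Cd, lag = 1)
  fd <- flux_matrix(md, A = 1, B = 4)
  pd <- decompose_pathways(fd)
  expect_equal(length(pd), 2)
  expect_equal(pd[[1]]$percentage, 50, tolerance = 1e-7)
  expect_equal(pd[[2]]$percentage, 50, tolerance = 1e-7)

  # random models: bookkeeping closes
  for (sd_ in 1:3) {
    mr <- random_reversible_msm(5, seed = 20 + sd_)
    fr <- flux_matrix(mr, A = 1, B = 5)
    pr <- decompose_pathways(fr, min_fraction = 0.01)
    pct <- vapply(pr, `[[`, numeric(1), "percentage")
    expect_equal(sum(pct), 100, tolerance = 0.1 / 100)
    fluxes <- vapply(pr, `[[`, numeric(1), "flux")
    expect_lte(sum(fluxes), fr$total_flux * (1 + 1e-9))
    expect_gte(sum(fluxes), fr$total_flux * (1 - 0.01) - 1e-12)
  }
})

test_that("pathway percentages are invariant to flux rescaling", {
  m <- random_reversible_msm(6, seed = 31)
  fx <- flux_matrix(m, A = 1, B = 6)
  pw1 <- decompose_pathways(fx)
  fx2 <- fx
  fx2$net <- fx$net * 1e6
  fx2$gross <- fx$gross * 1e6
  fx2$total_flux <- fx$total_flux * 1e6
  pw2 <- decompose_pathways(fx2)
  expect_equal(vapply(pw1, `[[`, numeric(1), "percentage"),
               vapply(pw2, `[[`, numeric(1), "percentage"),
               tolerance = 1e-9)
})

test_that("the pathway table reports ranked fluxes with a 100% total", {
  pws <- list(list(states = c(1, 2, 4), flux = 2.09e-4),
              list(states = c(1, 4), flux = 1.22e-6),
              list(states = c(1, 2, 3, 4), flux = 1.20e-6))
  tab <- pathway_report(pws, c("SA", "S1", "S2", "SB"))
  expect_equal(tab$Pathways,
               c("SA -> S1 -> SB", "SA -> SB", "SA -> S1 -> S2 -> SB",
                 "Total"))
  expect_equal(tab[["Path Flux (s^-1)"]],
               c(2.09e-4, 1.22e-6, 1.20e-6, 2.11e-4))
  expect_equal(tab[["Percentage of Total Coarse Flux (%)"]],
               c(98.9, 0.577, 0.568, 100))

  single <- pathway_report(list(list(states = 1:2, flux = 1)), c("A", "B"))
  expect_equal(single[["Percentage of Total Coarse Flux (%)"]], c(100, 100))

  expect_error(pathway_report(pws, c("SA", "S1", "S1", "SB")), "unique")

  # serialization round trip
  f <- tempfile(fileext = ".tsv")
  write_pathway_table(tab, f)
  back <- read_pathway_table(f)
  expect_equal(back$Pathways, tab$Pathways)
  expect_equal(back[["Path Flux (s^-1)"]], tab[["Path Flux (s^-1)"]])
})
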