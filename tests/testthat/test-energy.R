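two_atom_system <- function(r, q = c(1, 1), sigma = c(3, 3),
                            epsilon = c(0.1, 0.1), radii = c(1.5, 1.5),
                            groups = c("receptor", "ligand")) {
  molecular_system(rbind(c(0, 0, 0), c(r, 0, 0)), q, sigma, epsilon,
                   radii, c(12, 12), c(1L, 1L),
                   chain = c("R", "L"), group = groups)
}

test_that("Coulomb energies follow the closed form and brute force", {
  sys <- two_atom_system(332.0636)
  expect_equal(pairwise_coulomb(sys, pair_scope = "intra"), 1.0,
               tolerance = 1e-12)
  expect_equal(pairwise_coulomb(sys, pair_scope = "intra", dielectric = 2),
               0.5, tolerance = 1e-12)
  # neutral partner contributes nothing
  sys0 <- two_atom_system(5, q = c(0, 0.4))
  expect_equal(pairwise_coulomb(sys0, pair_scope = "intra"), 0)

  # brute-force double loop on random systems (intra and inter scope)
  for (sd_ in 1:3) {
    sys <- random_system(10, seed = 40 + sd_, two_groups = TRUE)
    brute <- 0; brute_inter <- 0
    for (i in 1:9) for (j in (i + 1):10) {
      r <- sqrt(sum((sys$coords[i, ] - sys$coords[j, ])^2))
      e <- 332.0636 * sys$charges[i] * sys$charges[j] / r
      brute <- brute + e
      if (sys$group[i] != sys$group[j]) brute_inter <- brute_inter + e
    }
    expect_equal(pairwise_coulomb(sys, pair_scope = "intra"), brute,
                 tolerance = 1e-10)
    expect_equal(pairwise_coulomb(sys, pair_scope = "inter"), brute_inter,
                 tolerance = 1e-10)
  }
  # coincident atoms are rejected
  expect_error(pairwise_coulomb(two_atom_system(1e-8), pair_scope = "intra"),
               "coincident")
})

test_that("Lennard-Jones energies hit the zero crossing and minimum", {
  sys <- two_atom_system(3)          # r = sigma_ij
  expect_equal(pairwise_lj(sys, pair_scope = "intra"), 0, tolerance = 1e-12)
  sysm <- two_atom_system(2^(1 / 6) * 3, epsilon = c(0.1, 0.4))
  expect_equal(pairwise_lj(sysm, pair_scope = "intra"), -sqrt(0.1 * 0.4),
               tolerance = 1e-12)

  for (sd_ in 1:3) {
    sys <- random_system(10, seed = 50 + sd_, two_groups = TRUE)
    brute <- 0
    for (i in 1:9) for (j in (i + 1):10) {
      r <- sqrt(sum((sys$coords[i, ] - sys$coords[j, ])^2))
      sig <- (sys$sigma[i] + sys$sigma[j]) / 2
      eps <- sqrt(sys$epsilon[i] * sys$epsilon[j])
      brute <- brute + 4 * eps * ((sig / r)^12 - (sig / r)^6)
    }
    expect_equal(pairwise_lj(sys, pair_scope = "intra"), brute,
                 tolerance = 1e-8 * max(1, abs(brute)))
  }
})

test_that("GB reduces to the Born formula for a single ion", {
  ion <- molecular_system(matrix(0, 1, 3), 1, 3, 0.1, 3, 12, 1L, "R",
                          "receptor")
  # offset 0: effective radius equals the intrinsic 3 A
  got <- gb_polar(ion, eps_solvent = 78.5, eps_solute = 1, offset = 0)
  born <- -(332.0636 / 2) * (1 - 1 / 78.5) * 1 / 3
  expect_equal(got, born, tolerance = 1e-12)
  expect_equal(got, -54.64, tolerance = 0.01 / 54.64)

  # zero charges: no polar energy
  ion0 <- molecular_system(matrix(0, 1, 3), 0, 3, 0.1, 3, 12, 1L, "R",
                           "receptor")
  expect_equal(gb_polar(ion0), 0)
})

test_that("distant atoms decouple into Born self-energies", {
  sys <- two_atom_system(1e4, q = c(1, -1), radii = c(2, 3))
  got <- gb_polar(sys, offset = 0)
  self <- -(332.0636 / 2) * (1 - 1 / 78.5) * (1 / 2 + 1 / 3)
  expect_lt(abs(got - self) / abs(self), 1e-3)
})

test_that("GB energy is invariant under rigid motions", {
  sys <- random_system(8, seed = 61)
  base <- gb_polar(sys)
  set.seed(62)
  for (i in 1:3) {
    R <- random_rotation(); tr <- stats::rnorm(3, sd = 10)
    moved <- sweep(sys$coords %*% t(R), 2, tr, "+")
    expect_equal(gb_polar(sys, coords = moved), base, tolerance = 1e-9)
  }
})

test_that("the nonpolar term is the documented linear map", {
  expect_equal(nonpolar_surf(0), 0)
  expect_equal(nonpolar_surf(100), 0.72, tolerance = 1e-12)
  expect_equal(nonpolar_surf(-295), -2.124, tolerance = 1e-12)
  expect_equal(nonpolar_surf(50, nonpolar_params(gamma = 0.01, beta = 1)),
               1.5, tolerance = 1e-12)
})

test_that("energy breakdowns reproduce the published worked examples", {
  # orthosteric+allosteric comparison set, per-term averages (kcal/mol)
  poj <- energy_breakdown(-21.51, -27.77, 30.09, -3.83, 20.60)
  expect_equal(poj$dGbind, -2.42, tolerance = 1e-9)
  expect_equal(poj$dGpol, 8.58, tolerance = 1e-9)

  i82_all <- energy_breakdown(-9.27, -18.50, 15.06, -2.45, 13.85)
  expect_equal(i82_all$dGbind, -1.31, tolerance = 1e-9)
  expect_equal(i82_all$dGpol, 5.79, tolerance = 1e-9)

  # internal identity holds for any stored breakdown
  eb <- energy_breakdown(-1.1, -2.2, 3.3, -0.4, 0.5)
  expect_equal(eb$dGbind, sum(eb$terms), tolerance = 1e-12)
})

test_that("MM-GBSA of a far-separated rigid pair is zero", {
  sys <- two_atom_system(1e6, q = c(0.3, -0.3))
  trj <- trajectory(list(sys$coords, sys$coords, sys$coords),
                    topology = sys)
  gb <- mmgbsa(trj, sys, n_snapshots = 3, n_sphere_points = 240)
  expect_lt(abs(gb$terms[["dEele"]]), 1e-3)
  expect_lt(abs(gb$terms[["dEvdW"]]), 1e-10)
  expect_lt(abs(gb$terms[["dGgb"]]), 1e-3)
  expect_lt(abs(gb$terms[["dGsurf"]]), 1e-10)
  expect_lt(abs(gb$dGbind), 2e-3)
})

test_that("MM-GBSA bookkeeping: averages equal per-snapshot means", {
  sys <- make_toy_complex(8, 3, seed = 71)
  set.seed(72)
  frames <- lapply(1:10, function(i)
    sys$coords + matrix(stats::rnorm(length(sys$coords), sd = 0.03),
                        ncol = 3))
  trj <- trajectory(frames, topology = sys)
  gb <- mmgbsa(trj, sys, n_snapshots = 10, n_sphere_points = 240,
               entropy_term = 1.5)
  for (term in c("dEele", "dEvdW", "dGgb", "dGsurf")) {
    expect_equal(gb$terms[[term]], mean(gb$per_snapshot[[term]]),
                 tolerance = 1e-12)
  }
  expect_equal(gb$terms[["minus_TdS"]], 1.5)
  expect_equal(gb$dGbind, sum(gb$terms), tolerance = 1e-10)
  expect_equal(gb$dGpol, gb$terms[["dEele"]] + gb$terms[["dGgb"]],
               tolerance = 1e-12)
  expect_error(mmgbsa(trj, sys, n_snapshots = 11), "exceeds")
})

test_that("per-residue shares are conservative and flag hotspots", {
  sys <- make_toy_complex(9, 3, seed = 81)
  trj <- trajectory(list(sys$coords, sys$coords), topology = sys)
  dec <- per_residue_decomposition(trj, sys, n_snapshots = 2,
                                   n_sphere_points = 240)
  gb <- mmgbsa(trj, sys, n_snapshots = 2, n_sphere_points = 240)
  # residue shares sum to the corresponding totals
  expect_equal(sum(dec$dEele), gb$terms[["dEele"]], tolerance = 1e-6)
  expect_equal(sum(dec$dEvdW), gb$terms[["dEvdW"]], tolerance = 1e-6)
  expect_equal(sum(dec$dGgb), gb$terms[["dGgb"]], tolerance = 1e-6)
  expect_equal(sum(dec$dGsurf), gb$terms[["dGsurf"]], tolerance = 1e-6)
  expect_equal(dec$hotspot, dec$total < -0.8)

  # single-residue receptor: its share is the whole receptor share
  mini <- two_atom_system(4, q = c(0.5, -0.5))
  trj2 <- trajectory(list(mini$coords, mini$coords), topology = mini)
  dec2 <- per_residue_decomposition(trj2, mini, n_snapshots = 2,
                                    n_sphere_points = 240)
  expect_equal(nrow(dec2), 2)
  gb2 <- mmgbsa(trj2, mini, n_snapshots = 2, n_sphere_points = 240)
  expect_equal(sum(dec2$total),
               gb2$dGbind, tolerance = 1e-6)

  # a distant uncharged residue contributes essentially nothing
  far <- molecular_system(
    rbind(c(0, 0, 0), c(3.5, 0, 0), c(60, 0, 0)),
    charges = c(0.4, -0.4, 0), sigma = rep(3, 3),
    epsilon = c(0.1, 0.1, 1e-6), radii = rep(1.5, 3),
    masses = rep(12, 3), residue = c(1L, 1L, 2L),
    chain = c("R", "L", "R"), group = c("receptor", "ligand", "receptor"))
  trj3 <- trajectory(list(far$coords, far$coords), topology = far)
  dec3 <- per_residue_decomposition(trj3, far, n_snapshots = 2,
                                    n_sphere_points = 240)
  null_row <- dec3[dec3$residue == 2 & dec3$group == "receptor", ]
  expect_lt(abs(null_row$total), 0.05)
  expect_false(null_row$hotspot)
})

test_that("the SIE function evaluates its calibrated form exactly", {
  z <- sie(0, 0, 0, 0)
  expect_equal(z$dGbind, -2.89, tolerance = 1e-12)

  s <- sie(-60, -15, -25, 0)
  expect_equal(s$bracket, -100, tolerance = 1e-12)
  expect_equal(s$dGbind, 0.1048 * (-100) - 2.89, tolerance = 1e-12)
  expect_equal(s$dGbind, -13.37, tolerance = 1e-9)

  # doubling alpha doubles dGbind - C
  p2 <- sie_params(alpha = 2 * 0.1048)
  s2 <- sie(-60, -15, -25, 0, params = p2)
  expect_equal(s2$dGbind - (-2.89), 2 * (s$dGbind - (-2.89)),
               tolerance = 1e-12)

  expect_error(sie(NaN, 0, 0, 0), "finite")
})

test_that("SIE components from a system respect the stored identity", {
  sys <- make_toy_complex(8, 3, seed = 91)
  sb <- sie_from_system(sys, n_sphere_points = 240)
  p <- sb$params
  expect_equal(sb$dGbind,
               p$alpha * (sb$E_c + sb$dG_R + sb$E_vdW + p$gamma * sb$dMSA) +
                 p$C, tolerance = 1e-10)
  # Coulomb term is screened by the interior dielectric
  expect_equal(sb$E_c,
               pairwise_coulomb(sys, pair_scope = "inter") / p$D_in,
               tolerance = 1e-10)
})

test_that("quasi-harmonic entropy is positive and grows with fluctuation", {
  set.seed(95)
  base <- matrix(stats::rnorm(15), 5, 3) * 3
  small <- lapply(1:20, function(i) base + matrix(stats::rnorm(15, sd = 0.05), 5, 3))
  large <- lapply(1:20, function(i) base + matrix(stats::rnorm(15, sd = 0.5), 5, 3))
  ts_small <- quasiharmonic_entropy(trajectory(small), masses = rep(12, 5))
  ts_large <- quasiharmonic_entropy(trajectory(large), masses = rep(12, 5))
  expect_gt(ts_small, 0)
  expect_gt(ts_large, ts_small)
})
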