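tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))

test_that("Kabsch superposition recovers rigid motions exactly", {
  fit <- kabsch_superpose(tetra, tetra)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  Rz <- rot_axis_angle(c(0, 0, 1), pi / 2)
  moved <- sweep(tetra %*% t(Rz), 2, c(3, -2, 7), "+")
  fit2 <- kabsch_superpose(moved, tetra)
  expect_lt(fit2$rmsd, 1e-10)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-10)
})

test_that("Kabsch RMSD matches brute-force rotation-grid minimization", {
  displaced <- tetra
  displaced[4, ] <- displaced[4, ] + c(1, 0, 0)
  fit <- kabsch_superpose(displaced, tetra)
  expect_equal(fit$rmsd, brute_force_rmsd(displaced, tetra),
               tolerance = 1e-3)
  expect_gt(fit$rmsd, 0.1)   # genuinely nonzero case
})

test_that("RMSD is invariant under common rigid motions", {
  set.seed(31)
  a <- matrix(stats::rnorm(30), 10, 3)
  b <- a + matrix(stats::rnorm(30, sd = 0.3), 10, 3)
  base <- kabsch_superpose(b, a)$rmsd
  for (i in 1:5) {
    R <- random_rotation(); tr <- stats::rnorm(3, sd = 5)
    a2 <- sweep(a %*% t(R), 2, tr, "+")
    b2 <- sweep(b %*% t(R), 2, tr, "+")
    expect_equal(kabsch_superpose(b2, a2)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("degenerate geometries are rejected", {
  expect_error(kabsch_superpose(tetra[1:2, ], tetra[1:2, ]), "3 atoms")
  line <- cbind(0:3, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch agrees with the bio3d reference fit", {
  set.seed(77)
  a <- matrix(stats::rnorm(36), 12, 3)
  b <- a + matrix(stats::rnorm(36, sd = 0.5), 12, 3)
  ours <- kabsch_superpose(b, a)$rmsd
  ref <- bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("RMSF and B-factors follow the fluctuation definitions", {
  # identical frames: zero fluctuation about the mean (need >= 2 frames)
  frames <- list(tetra, tetra, tetra)
  r0 <- rmsf(trajectory(frames))
  expect_equal(max(r0$rmsf), 0, tolerance = 1e-10)

  expect_error(rmsf(trajectory(list(tetra))), "single-frame")

  # breathing pair: two atoms oscillate +-1 A along their separation
  # axis (no net translation or rotation), flanked by two fixed anchors
  base <- rbind(c(5, 0, 0), c(-5, 0, 0), c(0, 5, 0), c(0, -5, 0))
  fr <- lapply(1:10, function(i) {
    d <- if (i %% 2 == 0) 1 else -1
    out <- base
    out[1, 1] <- 5 + d; out[2, 1] <- -5 - d
    out
  })
  r <- rmsf(trajectory(fr))
  expect_equal(r$rmsf[1:2], c(1, 1), tolerance = 1e-8)
  expect_equal(r$rmsf[3:4], c(0, 0), tolerance = 1e-8)
  # B = 8 pi^2 / 3 * rmsf^2 = 26.319 A^2 at rmsf = 1 A
  expect_equal(r$b_factor[1], 8 * pi^2 / 3, tolerance = 1e-8)
  expect_equal(r$b_factor[1], 26.319, tolerance = 1e-3)
})

test_that("radius of gyration matches closed forms and brute force", {
  one <- trajectory(list(matrix(c(1, 2, 3), 1)), frame_interval = 1)
  expect_equal(radius_of_gyration(one, mass_weighted = FALSE), 0)

  two <- trajectory(list(rbind(c(0, 0, 0), c(2, 0, 0))))
  expect_equal(radius_of_gyration(two, mass_weighted = FALSE), 1)

  set.seed(5)
  xyz <- matrix(stats::rnorm(300, sd = 4), 100, 3)
  rg <- radius_of_gyration(trajectory(list(xyz)), mass_weighted = FALSE)
  com <- colMeans(xyz)
  brute <- sqrt(mean(vapply(seq_len(100), function(i)
    sum((xyz[i, ] - com)^2), numeric(1))))
  expect_equal(rg, brute, tolerance = 1e-10)
})

test_that("DCCM captures correlated and anti-correlated motion", {
  base <- rbind(c(5, 0, 0), c(-5, 0, 0), c(0, 5, 0), c(0, -5, 0))
  set.seed(9)
  shifts <- stats::rnorm(20)
  # atoms 1 and 2 move identically along y; 3 and 4 oppositely along x
  fr <- lapply(1:20, function(i) {
    out <- base
    out[1, 2] <- out[1, 2] + shifts[i]
    out[2, 2] <- out[2, 2] + shifts[i]
    out[3, 1] <- out[3, 1] + shifts[i]
    out[4, 1] <- out[4, 1] - shifts[i]
    out
  })
  C <- dccm(trajectory(fr), superpose = FALSE)
  expect_equal(unname(diag(C)), rep(1, 4))
  expect_true(all(abs(C) <= 1 + 1e-12))
  expect_equal(C[1, 2], 1, tolerance = 1e-10)
  expect_equal(C[3, 4], -1, tolerance = 1e-10)
  expect_error(dccm(trajectory(list(base, base))), "zero-variance")
})

test_that("PCA modes are orthonormal with correctly ordered eigenvalues", {
  base <- rbind(c(5, 0, 0), c(-5, 0, 0), c(0, 5, 0), c(0, -5, 0))
  # dominant motion: breathing along x of atoms 1-2
  set.seed(13)
  amp <- stats::rnorm(30)
  fr <- lapply(1:30, function(i) {
    out <- base
    out[1, 1] <- out[1, 1] + amp[i]
    out[2, 1] <- out[2, 1] - amp[i]
    out
  })
  ms <- pca_modes(trajectory(fr), n_modes = 5)
  v1 <- ms$eigenvectors[, 1]
  # weight concentrated on the x coordinates of atoms 1 and 2
  expect_gt(sum(v1[c(1, 4)]^2), 0.99)
  expect_equal(sort(ms$eigenvalues, decreasing = TRUE), ms$eigenvalues)
  expect_equal(crossprod(ms$eigenvectors), diag(5), tolerance = 1e-8)
  expect_error(pca_modes(trajectory(fr), n_modes = 13), "3N")
})

test_that("PCA eigenvalues conserve the total variance and match power iteration", {
  set.seed(21)
  fr <- lapply(1:20, function(i) matrix(stats::rnorm(15), 5, 3))
  tr <- trajectory(fr)
  ms <- pca_modes(tr, n_modes = 15)
  st <- superpose_trajectory(tr)
  Xc <- sweep(st$coords, 2, colMeans(st$coords))
  expect_equal(sum(ms$eigenvalues), sum(Xc^2) / nrow(Xc), tolerance = 1e-8)

  # independent power-iteration oracle for the top eigenvalue
  C <- crossprod(Xc) / nrow(Xc)
  v <- rep(1, 15)
  for (i in 1:2000) { v <- C %*% v; v <- v / sqrt(sum(v^2)) }
  expect_equal(ms$eigenvalues[1], as.numeric(t(v) %*% C %*% v),
               tolerance = 1e-8)
})

test_that("porcupine export writes the mean and displaced structures", {
  set.seed(2)
  fr <- lapply(1:10, function(i) tetra + matrix(stats::rnorm(12, sd = 0.1), 4, 3))
  ms <- pca_modes(trajectory(fr), n_modes = 2)
  pdb <- tempfile(fileext = ".pdb"); csv <- tempfile(fileext = ".csv")
  export_porcupine(ms, mode = 1, scale = 5, pdb_path = pdb, csv_path = csv)
  back <- read_trajectory_pdb(pdb)
  expect_equal(n_frames(back), 2)
  vec <- utils::read.csv(csv)
  disp <- get_frame(back, 2) - get_frame(back, 1)
  expect_equal(disp, 5 * as.matrix(vec[, c("dx", "dy", "dz")]),
               tolerance = 1e-2, ignore_attr = TRUE)
})
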