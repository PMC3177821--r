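test_that("dPCA separates a two-state angular mixture", {
  two <- landscape_spec(list(
    list(phi = -139, psi = 135, sd = 10, weight = 0.5),
    list(phi = -57, psi = -47, sd = 10, weight = 0.5)), n_pairs = 3L)
  ang <- sample_dihedral_ensemble(two, 3000, seed = 5)
  dp <- dpca_project(ang, 2)
  st <- attr(ang, "state")
  gap <- abs(mean(dp$scores[st == 1, 1]) - mean(dp$scores[st == 2, 1]))
  spread <- sd(dp$scores[st == 1, 1]) + sd(dp$scores[st == 2, 1])
  expect_gt(gap, 3 * spread)            # clean bimodal separation
})

test_that("dPCA conserves trace and is isometric under common rotation", {
  ang <- sample_dihedral_ensemble(landscape_spec(list(
    list(phi = -100, psi = 90, sd = 25, weight = 1)), n_pairs = 2L),
    400, seed = 6)
  dp <- dpca_project(ang, 4)
  expect_equal(sum(dp$eigenvalues), dp$total_variance,
               tolerance = 1e-10)
  # common offset: loadings change, pairwise score distances do not
  wrap <- function(x) { y <- (x + 180) %% 360 - 180; y[y <= -180] <- 180; y }
  dp2 <- dpca_project(wrap(ang + 60), 4)
  d1 <- dist(dp2$scores[1:50, ])
  d0 <- dist(dpca_project(ang, 4)$scores[1:50, ])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-6)
  expect_warning(dpca_project(matrix(5, 10, 4)), "constant")
})

test_that("free-energy surface has an exact zero minimum and NA holes", {
  sc <- cbind(rep(0, 10), rep(0, 10))
  fes <- free_energy_surface(sc, 315, grid = c(8L, 8L))
  expect_equal(min(fes$V, na.rm = TRUE), 0)
  expect_equal(sum(is.finite(fes$V)), 1)
  # two equally populated states: both minima exactly 0
  sc2 <- rbind(matrix(rep(c(-1, 0), 50), ncol = 2, byrow = TRUE),
               matrix(rep(c(1, 0), 50), ncol = 2, byrow = TRUE))
  fes2 <- free_energy_surface(sc2, 315, grid = c(4L, 4L))
  expect_equal(sort(fes2$V[is.finite(fes2$V)]), c(0, 0))
})

test_that("90/10 bin split gives kT ln 9 and count scaling cancels", {
  kB <- dimerscope::phys_const$kB
  sc <- rbind(matrix(rep(c(-1, 0), 90), ncol = 2, byrow = TRUE),
              matrix(rep(c(1, 0), 10), ncol = 2, byrow = TRUE))
  fes <- free_energy_surface(sc, 315, grid = c(4L, 4L))
  vals <- sort(fes$V[is.finite(fes$V)])
  expect_equal(vals[2], kB * 315 * log(9), tolerance = 1e-9)
  # duplicating every frame multiplies all counts by 2: V unchanged
  fes2 <- free_energy_surface(rbind(sc, sc), 315, grid = c(4L, 4L))
  expect_equal(fes2$V, fes$V)
})

test_that("basin extraction recovers generator weights and representatives", {
  set.seed(10)
  sc <- cbind(c(rnorm(700, -2, 0.2), rnorm(300, 2, 0.2)),
              rnorm(1000, 0, 0.2))
  fes <- free_energy_surface(sc, 315, grid = c(30L, 30L))
  basins <- extract_basins(fes)
  expect_gte(nrow(basins), 2)
  expect_equal(basins$V_min[1], 0)
  top2 <- basins$population[1:2]
  expect_lt(abs(top2[1] - 0.7), 0.05)
  expect_lt(abs(top2[2] - 0.3), 0.05)
  # single-basin landscape
  b1 <- extract_basins(free_energy_surface(
    cbind(rnorm(500, 0, 0.1), rnorm(500, 0, 0.1)), 315, grid = c(10L, 10L)))
  expect_equal(sum(b1$population), 1)
  # representative of a zero-noise single-cluster ensemble is any frame
  # with zero RMSD to the shared template
  ens <- build_dimer_conformation(
    dimer_fixture_spec("antiparallel", 39), seed = 2, n_models = 4)
  sc0 <- cbind(rep(0, 4), rep(0, 4))
  fes0 <- free_energy_surface(sc0, 315, grid = c(4L, 4L))
  b0 <- extract_basins(fes0, ens, rmsd_cutoff = 0.2)
  rep_frame <- attr(b0, "representatives")[1]
  expect_true(rep_frame %in% 1:4)
  expect_equal(frame_coords(ens, rep_frame), frame_coords(ens, 1),
               tolerance = 1e-12)
})

test_that("quasiharmonic entropy matches the closed form mode by mode", {
  kB <- dimerscope::phys_const$kB; hbar <- dimerscope::phys_const$hbar
  T0 <- 315
  # lambda chosen so x = hbar*omega/(kB T) = 1 exactly
  lam1 <- hbar^2 / (kB * T0)
  xyz <- matrix(rnorm(4000), ncol = 1) * sqrt(lam1 / 12)
  # exact: use the definition directly on the *sample* eigenvalue
  qh <- quasiharmonic_entropy(xyz, 12, T0)
  x <- hbar * sqrt(kB * T0 / qh$lambda) / (kB * T0)
  expect_equal(qh$S, kB * (x / (exp(x) - 1) - log(1 - exp(-x))),
               tolerance = 1e-12)
  # and statistically: S within 3 s.e. of the generator value at x = 1
  tr <- sample_gaussian_coordinates(
    data.frame(mass = 12, lambda = lam1), 50000, seed = 11)
  qh2 <- quasiharmonic_entropy(tr$xyz, tr$masses, T0)
  S_true <- kB * (1 / (exp(1) - 1) - log(1 - exp(-1)))
  dS_dlam <- (function(l) {
    h <- l * 1e-5
    f <- function(ll) {
      om <- sqrt(kB * T0 / ll); xx <- hbar * om / (kB * T0)
      kB * (xx / (exp(xx) - 1) - log(1 - exp(-xx)))
    }
    (f(l + h) - f(l - h)) / (2 * h)
  })(lam1)
  se <- abs(dS_dlam) * lam1 * sqrt(2 / 50000)
  expect_lt(abs(qh2$S - S_true), 3 * se)
})

test_that("frozen modes contribute nothing and S is monotone in lambda", {
  kB <- dimerscope::phys_const$kB
  lam <- 1e-3
  xyz <- cbind(rnorm(3000, 0, sqrt(lam / 12)),
               rnorm(3000, 0, 1e-14))     # second mode frozen
  qh <- quasiharmonic_entropy(xyz, c(12, 12), 315)
  expect_equal(qh$n_modes, 1)             # frozen mode below the floor
  qh1 <- quasiharmonic_entropy(xyz[, 1, drop = FALSE], 12, 315)
  expect_equal(qh$S, qh1$S, tolerance = 1e-12)
  # per-mode entropy increases with lambda
  f <- function(l) quasiharmonic_entropy(
    matrix(seq(-1, 1, length.out = 101) * sqrt(3 * l / 12), ncol = 1),
    12, 315)$S
  lams <- 10^seq(-6, -2, length.out = 9)
  expect_true(all(diff(vapply(lams, f, 0)) > 0))
})

test_that("entropy is invariant under rigid motion and atom permutation", {
  tr <- sample_gaussian_coordinates(
    data.frame(mass = rep(12, 12), lambda = (12:1) * 1e-4), 3000,
    seed = 12)
  xyz <- tr$xyz                        # 4 atoms x 3 coords
  base <- quasiharmonic_entropy(xyz, rep(12, 4), 315, superpose = TRUE)
  R <- dimerscope:::.rotmat(c(0.2, 0.5, -0.3))
  rot <- t(apply(xyz, 1, function(fr) {
    m <- matrix(fr, ncol = 3, byrow = TRUE)
    as.numeric(t(t(R %*% t(m)) + 0.7))
  }))
  qr <- quasiharmonic_entropy(rot, rep(12, 4), 315, superpose = TRUE)
  expect_equal(qr$S, base$S, tolerance = 1e-6)
  # permuting atoms (with equal masses) leaves S unchanged
  perm <- xyz[, c(7:12, 1:6)]
  qp <- quasiharmonic_entropy(perm, rep(12, 4), 315, superpose = TRUE)
  expect_equal(qp$S, base$S, tolerance = 1e-9)
})

test_that("entropy time series plateaus for stationary input and grows on a switch", {
  kB <- dimerscope::phys_const$kB
  tr <- sample_gaussian_coordinates(
    data.frame(mass = c(12, 12), lambda = c(4e-4, 2e-4)), 6000, seed = 13)
  ts1 <- entropy_timeseries(tr$xyz, c(12, 12), 315, n_points = 10)
  expect_true(all(diff(ts1$time) > 0))
  expect_true(isTRUE(attr(ts1, "plateau")))
  tail_S <- ts1$S[nrow(ts1)]
  S_true <- quasiharmonic_entropy(tr$xyz, c(12, 12), 315)$S
  expect_equal(tail_S, S_true, tolerance = 1e-9)
  # distribution broadens mid-stream: -T S decreases (S increases)
  tr2 <- sample_gaussian_coordinates(
    data.frame(mass = c(12, 12), lambda = c(4e-3, 2e-3)), 3000, seed = 14)
  switched <- rbind(tr$xyz[1:3000, ], tr2$xyz)
  ts2 <- entropy_timeseries(switched, c(12, 12), 315, n_points = 10)
  expect_gt(ts2$S[10], ts2$S[5])
  # repeated single frame: no fluctuations, S = 0
  flat <- matrix(rep(c(0.1, 0.2), each = 50), ncol = 2)
  ts3 <- entropy_timeseries(flat, c(12, 12), 315, n_points = 5)
  expect_true(all(ts3$S == 0))
})
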