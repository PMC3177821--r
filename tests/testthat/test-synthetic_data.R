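test_that("dimer builder realizes the requested registry exactly at zero noise", {
  ens <- fx_ap39()
  g <- hbond_graph(ens)
  inter <- g[g$donor_chain != g$acc_chain, ]
  expect_gt(nrow(inter), 4)
  expect_true(all(inter$donor_res + inter$acc_res == 39))
  # in-register parallel ladder: all bridge pairs differ by 0
  ens0 <- build_dimer_conformation(
    dimer_fixture_spec("parallel", 0, span_a = c(15, 21)), seed = 1)
  cl <- classify_frame_registry(ens0)
  expect_equal(cl$orientation, "parallel")
  expect_true(all(cl$pairs$i - cl$pairs$j == 0))
})

test_that("registry survives 0.3 A coordinate noise", {
  spec <- dimer_fixture_spec("antiparallel", 38, span_a = c(15, 21),
                             noise_rms = 0.3)
  ens <- build_dimer_conformation(spec, seed = 4, n_models = 5)
  for (f in seq_len(n_frames(ens))) {
    cl <- classify_frame_registry(ens, f)
    expect_equal(cl$orientation, "antiparallel")
    expect_equal(cl$index, 38L)
  }
})

test_that("builder is deterministic given seed and rejects unreachable indices", {
  spec <- dimer_fixture_spec("antiparallel", 39, noise_rms = 0.2)
  a <- build_dimer_conformation(spec, seed = 5, n_models = 3)
  b <- build_dimer_conformation(spec, seed = 5, n_models = 3)
  expect_identical(a$xyz, b$xyz)
  expect_error(build_dimer_conformation(
    dimer_fixture_spec("antiparallel", 29, span_a = c(16, 22))),
    "unreachable")
  expect_error(dimer_fixture_spec("antiparallel", 39, span_a = c(5, 11)),
               "span")
  expect_error(build_dimer_conformation(
    dimer_fixture_spec("antiparallel", 30, span_a = c(16, 17),
                       span_b = c(13, 14))), "unreachable")
  expect_true(is.list(a$info) && a$info$seed == 5L)
})

test_that("angular mixture sampler reproduces state weights and spreads", {
  one <- landscape_spec(list(list(phi = -139, psi = 135, sd = 5,
                                  weight = 1)))
  m1 <- sample_dihedral_ensemble(one, 2000, seed = 1)
  expect_lt(sd(m1[, 1]), 6)
  expect_lt(abs(mean(m1[, 1]) + 139), 1)
  two <- landscape_spec(list(
    list(phi = -139, psi = 135, sd = 8, weight = 0.5),
    list(phi = -57, psi = -47, sd = 8, weight = 0.5)))
  m2 <- sample_dihedral_ensemble(two, 4000, seed = 2)
  st <- attr(m2, "state")
  p <- mean(st == 1)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 4000))
  skew <- landscape_spec(list(
    list(phi = -139, psi = 135, sd = 8, weight = 0.9),
    list(phi = -57, psi = -47, sd = 8, weight = 0.1)))
  m3 <- sample_dihedral_ensemble(skew, 6000, seed = 3)
  p3 <- mean(attr(m3, "state") == 1)
  expect_lt(abs(p3 - 0.9), 3 * sqrt(0.9 * 0.1 / 6000))
  # states actually land where requested
  expect_lt(abs(mean(m3[attr(m3, "state") == 2, 2]) + 47), 2)
})

test_that("Boltzmann distance sampler matches closed forms", {
  kB <- dimerscope::phys_const$kB
  flat <- model_potential("custom", list(fun = function(x) 0 * x))
  d <- sample_distance_ensemble(flat, 315, 4000, seed = 1,
                                r_range = c(0.2, 1.2))
  ks <- suppressWarnings(ks.test(d, "punif", 0.2, 1.2))
  expect_gt(ks$p.value, 0.01)
  k <- 2000
  well <- model_potential("harmonic", list(k = k, x0 = 0.8))
  d2 <- sample_distance_ensemble(well, 315, 50000, seed = 2,
                                 r_range = c(0.2, 1.4))
  expected <- kB * 315 / k
  expect_lt(abs(var(d2) - expected) / expected, 0.05)
  expect_lt(abs(mean(d2) - 0.8), 0.005)
})

test_that("Gaussian coordinate generator hits its covariance spectrum", {
  lam <- 4e-4
  tr <- sample_gaussian_coordinates(data.frame(mass = 12, lambda = lam),
                                    20000, seed = 7)
  mw_var <- var(tr$xyz[, 1]) * 12
  se <- lam * sqrt(2 / 20000)
  expect_lt(abs(mw_var - lam), 3 * se)
  iso <- sample_gaussian_coordinates(
    data.frame(mass = c(12, 12, 12), lambda = rep(2e-4, 3)), 20000,
    seed = 8)
  ev <- eigen(cov(sweep(iso$xyz, 2, sqrt(iso$masses), `*`)))$values
  expect_lt(max(abs(ev - 2e-4)), 3 * 2e-4 * sqrt(2 / 20000) * 2)
})

test_that("water-shell placement has the designed radial structure", {
  # single dense shell: RDF peak at r0
  s1 <- solvation_spec(box = 4, bulk_density = 40,
                       shells = data.frame(r0 = 0.8, width = 0.1,
                                           rel_density = 3))
  w1 <- place_water_shells(s1, seed = 3)
  g1 <- rdf(w1$solute, w1$waters, w1$box, bin_width = 0.05)
  expect_lt(abs(g1$r[which.max(g1$value)] - 0.8), 0.075)
  # two shells with 2:1 density ratio
  s2 <- solvation_spec(box = 6, bulk_density = 40,
                       shells = data.frame(r0 = c(0.8, 1.6),
                                           width = c(0.2, 0.2),
                                           rel_density = c(4, 2)))
  w2 <- place_water_shells(s2, seed = 4)
  g2 <- rdf(w2$solute, w2$waters, w2$box, bin_width = 0.1)
  h1 <- g2$value[which.min(abs(g2$r - 0.8))]
  h2 <- g2$value[which.min(abs(g2$r - 1.6))]
  expect_lt(abs(h1 / h2 - 2), 0.5)
  expect_error(solvation_spec(box = 4, shells = data.frame(
    r0 = c(0.8, 0.9), width = c(0.3, 0.3), rel_density = c(2, 2))),
    "overlap")
})

test_that("generators are seed-deterministic and log their parameters", {
  sp <- landscape_spec(list(list(phi = 0, psi = 0, sd = 10, weight = 1)))
  expect_identical(sample_dihedral_ensemble(sp, 50, seed = 9),
                   sample_dihedral_ensemble(sp, 50, seed = 9))
  expect_false(identical(sample_dihedral_ensemble(sp, 50, seed = 9),
                         sample_dihedral_ensemble(sp, 50, seed = 10)))
  dw <- model_potential("double_well", list(barrier = 12))
  d <- sample_distance_ensemble(dw, 315, 10, seed = 2)
  expect_equal(attr(d, "params")$seed, 2L)
  w <- place_water_shells(solvation_spec(box = 3, bulk_density = 5),
                          seed = 6)
  expect_equal(w$params$seed, 6L)
  expect_identical(w$waters,
                   place_water_shells(solvation_spec(box = 3,
                                                     bulk_density = 5),
                                      seed = 6)$waters)
})
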