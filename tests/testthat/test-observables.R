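test_that("block-averaged standard error matches its definition and a bootstrap", {
  expect_equal(block_average_error(rep(3.7, 100)), 0)
  vals <- c(1, 4, 2, 8, 5)
  series <- rep(vals, each = 20)
  expect_equal(block_average_error(series, 5), sd(vals) / sqrt(5))
  expect_error(block_average_error(1:10, 1), "n_blocks")
  # i.i.d. series: block s.e. agrees with a bootstrap of the mean
  set.seed(21)
  x <- rnorm(5000, 0, 2)
  se_block <- block_average_error(x, 5)
  boot <- replicate(400, mean(sample(x, replace = TRUE)))
  # both estimate sd(mean); block estimate is noisy (4 d.o.f.), compare
  # through their common target within broad factors
  expect_lt(abs(se_block - sd(boot)) / sd(boot), 1)
})

test_that("PMF estimator is exact on constructed bin counts", {
  kB <- dimerscope::phys_const$kB
  # uniform samples: all bins within counting noise of zero
  set.seed(22)
  d <- runif(20000, 0.2, 1.2)
  p <- pmf_from_distances(d, 315, 0.05)
  n_per_bin <- 20000 / nrow(p)
  expect_lt(max(abs(p$value), na.rm = TRUE),
            kB * 315 * 3 * sqrt(2 / n_per_bin) + 0.2)
  # a bin with N = Nmax/e sits at exactly kB*T
  d2 <- c(rep(0.30, 272), rep(0.50, 100))       # 272 ~ 100*e
  p2 <- pmf_from_distances(d2, 315, 0.05)
  v <- p2$value[is.finite(p2$value)]
  expect_equal(sort(v), c(0, kB * 315 * log(272 / 100)), tolerance = 1e-9)
  expect_equal(kB * 315, 2.619, tolerance = 1e-3)
  # single value: one-bin profile at 0
  p3 <- pmf_from_distances(rep(0.5, 10), 315, 0.05)
  expect_equal(sum(is.finite(p3$value)), 1)
  expect_equal(min(p3$value, na.rm = TRUE), 0)
})

test_that("1D PMF and 2D surface share the same estimator kernel", {
  kB <- dimerscope::phys_const$kB
  d <- rep(c(0.1, 0.5, 0.9), times = c(50, 30, 20))
  p <- pmf_from_distances(d, 315, 0.05)
  fes <- free_energy_surface(cbind(d, 0), 315, grid = c(40L, 1L))
  expect_equal(sort(p$value[is.finite(p$value)]),
               sort(fes$V[is.finite(fes$V)]), tolerance = 1e-9)
})

test_that("PMF recovery error is bounded by counting statistics", {
  kB <- dimerscope::phys_const$kB
  dw <- model_potential("double_well",
                        list(barrier = 8, halfsep = 0.25, x0 = 0.7))
  d <- sample_distance_ensemble(dw, 315, 1e5, seed = 23,
                                r_range = c(0.3, 1.1))
  p <- pmf_from_distances(d, 315, 0.02)
  ok <- which(p$count >= 100)
  v_true <- potential_energy(dw, p$r[ok])
  v_true <- v_true - min(v_true)
  v_est <- p$value[ok] - min(p$value[ok])
  err <- abs(v_est - v_true)
  tol <- 3 * kB * 315 / sqrt(p$count[ok])   # counting error per bin
  # allow the in-bin potential variation on top of pure counting noise
  expect_true(all(err <= tol + 0.35))
})

test_that("CHC inter-chain distance matches rigid translations and brute force", {
  ens <- fx_ap39()
  at <- ens$atoms
  # identical superposed chains: distance 0
  a_idx <- which(at$chain == "A")
  xyzA <- frame_coords(ens, 1)[a_idx, ]
  at2 <- rbind(at[a_idx, ], transform(at[a_idx, ], chain = "B"))
  sup <- dimer_ensemble(at2, matrix(as.numeric(t(rbind(xyzA, xyzA))),
                                    nrow = 1))
  expect_equal(interchain_chc_distance(sup), 0)
  # translating one chain by 1.1 nm moves the distance to exactly 1.1
  xyzB <- xyzA; xyzB[, 1] <- xyzB[, 1] + 1.1
  tr <- dimer_ensemble(at2, matrix(as.numeric(t(rbind(xyzA, xyzB))),
                                   nrow = 1))
  expect_equal(interchain_chc_distance(tr), 1.1, tolerance = 1e-12)
  # brute-force mass-weighted centroid oracle
  d <- interchain_chc_distance(ens)
  xyz <- frame_coords(ens, 1)
  cent <- function(chn) {
    idx <- which(at$chain == chn & at$resno >= 17 & at$resno <= 21)
    m <- dimerscope:::.atom_masses[at$elety[idx]]
    colSums(xyz[idx, ] * m) / sum(m)
  }
  expect_equal(d, sqrt(sum((cent("A") - cent("B"))^2)), tolerance = 1e-12)
  expect_error(interchain_chc_distance(ens, chc_range = c(40, 44)),
               "missing")
})

test_that("contact map hits designed contact fractions and is monotone in cutoff", {
  ens <- fx_short38()
  cm <- contact_map(ens)
  expect_true(all(cm$P >= 0 & cm$P <= 1))
  expect_equal(max(cm$P), 1)            # permanent contacts in the sheet
  expect_equal(cm$P, t(cm$P))           # symmetrized
  # dissociated chains: all zeros
  cm0 <- contact_map(fx_separated())
  expect_true(all(cm0$P == 0))
  # 50% of frames in contact -> 0.5 exactly
  far <- ens$xyz
  bidx <- which(ens$atoms$chain == "B")
  far[3 * (bidx - 1) + 1] <- far[3 * (bidx - 1) + 1] + 6
  mix <- dimer_ensemble(ens$atoms, rbind(ens$xyz, far))
  cm5 <- contact_map(mix)
  expect_equal(max(cm5$P), 0.5)
  # enlarging the cutoff never decreases any cell
  cm_wide <- contact_map(ens, cutoff = 0.6)
  expect_true(all(cm_wide$P >= cm$P - 1e-12))
})

test_that("RDF is flat for uniform placement and insensitive to density doubling", {
  w <- place_water_shells(solvation_spec(box = 3, bulk_density = 60),
                          seed = 2)
  g <- rdf(w$solute, w$waters, w$box, bin_width = 0.05)
  # per-bin counting tolerance: 3/sqrt(expected pairs per bin)
  rho <- nrow(w$waters) / w$box^3
  lo <- g$r - 0.025; hi <- g$r + 0.025
  expected <- rho * 4 / 3 * pi * (hi^3 - lo^3)
  keep <- expected >= 5
  expect_true(all(abs(g$value[keep] - 1) <= 3 / sqrt(expected[keep])))
  # duplicating every water doubles counts and density: g unchanged
  g2 <- rdf(w$solute, rbind(w$waters, w$waters), w$box, bin_width = 0.05)
  expect_equal(g2$value, g$value, tolerance = 1e-12)
  expect_error(rdf(w$solute, w$waters, w$box, r_max = 2.9), "half")
})

test_that("dwell fractions sum to one and diagnose mixing", {
  hp <- model_potential("harmonic", list(k = 100))
  # no exchange attempts: replica never leaves its rung
  e0 <- run_toy_remd(hp, geometric_ladder(315, 400, 3, 1000), 100,
                     seed = 3)
  d0 <- dwell_fractions(e0, 2)
  expect_equal(d0$value[2], 1)
  expect_equal(sum(d0$value), 1)
  # near-degenerate ladder mixes to ~ 1/n
  lad <- temperature_ladder(c(315, 315.001, 315.002), 2)
  e1 <- run_toy_remd(hp, lad, 6000, seed = 4)
  d1 <- dwell_fractions(e1, 1)
  expect_equal(sum(d1$value), 1)
  expect_true(all(abs(d1$value - 1 / 3) < 0.1))
  # fractions reconcile with the raw step log
  st <- e1$steps[e1$steps$replica == 1, ]
  expect_equal(d1$value, tabulate(st$temp_index, 3) / nrow(st))
})
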