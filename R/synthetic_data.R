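# Synthetic-ensemble generators. Every generator is deterministic given
# its seed and records its full parameterization in the result's `info`
# so round-trip tests can compare analysis output against ground truth.

#' Specify a two-chain beta-sheet fixture with a known registry
#'
#' Describes an idealized Abeta12-24 dimer in which the inter-chain
#' backbone hydrogen bonds realize exactly one beta-sheet registry:
#' parallel registries are indexed by the difference `i - j` of bridged
#' residue numbers, antiparallel registries by the sum `i + j` (Abeta
#' numbering, residues 12-24).
#'
#' @param registry_kind `"parallel"` or `"antiparallel"`.
#' @param registry_index integer: target `i - j` (parallel) or `i + j`
#'   (antiparallel).
#' @param span_a,span_b integer length-2 ranges of strand residues per
#'   chain, within 12-24.
#' @param noise_rms Gaussian coordinate jitter, Angstrom RMS per atom
#'   (0 = ideal geometry).
#' @param sequence,first_residue_number peptide identity (defaults:
#'   Abeta12-24).
#' @return An object of class `"dimer_fixture_spec"`.
#' @export
dimer_fixture_spec <- function(registry_kind = c("antiparallel", "parallel"),
                               registry_index,
                               span_a = c(16L, 22L), span_b = NULL,
                               noise_rms = 0,
                               sequence = "VHHQKLVFFAEDV",
                               first_residue_number = 12L) {
  registry_kind <- match.arg(registry_kind)
  resno <- seq.int(first_residue_number, length.out = nchar(sequence))
  span_a <- sort(as.integer(span_a))
  if (is.null(span_b)) {
    span_b <- if (registry_kind == "parallel") span_a - registry_index
              else sort(registry_index - span_a)
    span_b <- c(max(span_b[1], min(resno)), min(span_b[2], max(resno)))
  }
  span_b <- sort(as.integer(span_b))
  ok <- function(s) s[1] >= min(resno) && s[2] <= max(resno) && s[1] < s[2]
  if (!ok(span_a) || !ok(span_b))
    stop("strand spans must lie within residues ", min(resno), "-", max(resno))
  if (noise_rms < 0) stop("'noise_rms' must be >= 0")
  structure(list(registry_kind = registry_kind,
                 registry_index = as.integer(registry_index),
                 span_a = span_a, span_b = span_b,
                 noise_rms = noise_rms, sequence = sequence,
                 first_residue_number = as.integer(first_residue_number),
                 resno = resno),
            class = "dimer_fixture_spec")
}

# --- ideal periodic beta-strand ------------------------------------------

# Refine (phi, psi) near the ideal antiparallel-strand values (-139, 135)
# so that the two-residue screw transform of the built chain is a pure
# translation (zero net twist): the strand is then exactly periodic and a
# single rigid placement of the partner chain satisfies the whole
# hydrogen-bond ladder. Cached per session.
.strand_cache <- new.env(parent = emptyenv())

.ideal_strand_angles <- function(target = c(-139, 135)) {
  key <- paste(target, collapse = "_")
  if (!is.null(.strand_cache[[key]])) return(.strand_cache[[key]])
  twist2 <- function(par) {
    bb <- build_backbone(rep(par[1], 7), rep(par[2], 7), with_cb = FALSE)
    P <- rbind(bb$N[3, ], bb$CA[3, ], bb$C[3, ], bb$N[4, ], bb$CA[4, ], bb$C[4, ])
    Q <- rbind(bb$N[5, ], bb$CA[5, ], bb$C[5, ], bb$N[6, ], bb$CA[6, ], bb$C[6, ])
    k <- .kabsch(P, Q)
    ang <- acos(max(-1, min(1, (sum(diag(k$R)) - 1) / 2)))
    ang^2 + 1e-6 * sum((par - target)^2)
  }
  fit <- stats::optim(target, twist2, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  .strand_cache[[key]] <- fit$par
  fit$par
}

# Build an n-residue periodic strand aligned with +x, with inferred
# amide hydrogens. Coordinates in Angstrom.
.ideal_strand <- function(n) {
  ang <- .ideal_strand_angles()
  bb <- build_backbone(rep(ang[1], n), rep(ang[2], n), with_cb = TRUE)
  # align the 2-residue repeat translation with +x
  k <- .kabsch(rbind(bb$N[1, ], bb$CA[1, ], bb$C[1, ]),
               rbind(bb$N[3, ], bb$CA[3, ], bb$C[3, ]))
  axis <- .unit(k$t)
  v <- pracma_cross(axis, c(1, 0, 0))
  s <- sqrt(sum(v^2))
  cth <- sum(axis * c(1, 0, 0))
  R <- if (s < 1e-12) diag(3) else .rotmat(.unit(v) * atan2(s, cth))
  bb <- .transform_backbone(bb, R, c(0, 0, 0))
  ctr <- colMeans(bb$CA)
  bb <- .transform_backbone(bb, diag(3), -ctr)
  bb$H <- .strand_hydrogens(bb)
  bb
}

# DSSP convention: H sits 1.0 A from N along the unit vector from the
# previous residue's O to its C. First residue: no H (NA row).
.strand_hydrogens <- function(bb) {
  n <- bb$n
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n)
    H[i, ] <- bb$N[i, ] + .unit(bb$C[i - 1, ] - bb$O[i - 1, ]) * .bb_geom$b_NH
  H
}

# --- registry-targeted rigid placement -----------------------------------

# Bridge pairs (i in span_a, j in span_b) realizing the registry.
.registry_pairs <- function(spec) {
  ia <- seq.int(spec$span_a[1], spec$span_a[2])
  j <- if (spec$registry_kind == "parallel") ia - spec$registry_index
       else spec$registry_index - ia
  keep <- j >= spec$span_b[1] & j <= spec$span_b[2]
  cbind(i = ia[keep], j = j[keep])
}

# Target hydrogen bonds (donor chain/res -> acceptor chain/res) whose
# realization makes DSSP bridges reproduce the registry exactly.
.registry_target_bonds <- function(spec) {
  pr <- .registry_pairs(spec)
  if (nrow(pr) < 2)
    stop("registry index ", spec$registry_index,
         " unreachable for spans ", paste(spec$span_a, collapse = "-"),
         " / ", paste(spec$span_b, collapse = "-"))
  rmin <- min(spec$resno); rmax <- max(spec$resno)
  # a chain-start residue has no amide H and cannot donate
  feasible <- function(donor) donor > rmin
  build_set <- function(start) {
    bonds <- NULL
    for (k in seq(start, nrow(pr), by = 2)) {
      i <- pr[k, "i"]; j <- pr[k, "j"]
      if (spec$registry_kind == "antiparallel") {
        if (feasible(i)) bonds <- rbind(bonds, c("A", i, "B", j))
        if (feasible(j)) bonds <- rbind(bonds, c("B", j, "A", i))
      } else {
        if (feasible(j) && i - 1 >= rmin)
          bonds <- rbind(bonds, c("B", j, "A", i - 1))
        if (i + 1 <= rmax && feasible(i + 1))
          bonds <- rbind(bonds, c("A", i + 1, "B", j))
      }
    }
    bonds
  }
  # the bridge parity (which pairs are narrow) is free: take the choice
  # that realizes more hydrogen bonds
  b1 <- build_set(1)
  b2 <- if (nrow(pr) > 1) build_set(2) else NULL
  bonds <- if (is.null(b2) || NROW(b1) >= NROW(b2)) b1 else b2
  if (is.null(bonds) || nrow(bonds) < 3)
    stop("registry index ", spec$registry_index,
         " unreachable: too few target hydrogen bonds for spans ",
         paste(spec$span_a, collapse = "-"), " / ",
         paste(spec$span_b, collapse = "-"))
  data.frame(donor_chain = bonds[, 1], donor_res = as.integer(bonds[, 2]),
             acc_chain = bonds[, 3], acc_res = as.integer(bonds[, 4]),
             stringsAsFactors = FALSE)
}

# Geometry objective for a rigid placement of chain B: drive each target
# N(H)...O=C bond to ideal distances and keep the chains from clashing.
.placement_objective <- function(par, bbA, bbB, bonds, resno) {
  R <- .rotmat(par[1:3]); t <- par[4:6]
  B <- .transform_backbone(bbB, R, t)
  chains <- list(A = bbA, B = B)
  obj <- 0
  for (b in seq_len(nrow(bonds))) {
    dc <- chains[[bonds$donor_chain[b]]]; ac <- chains[[bonds$acc_chain[b]]]
    di <- match(bonds$donor_res[b], resno); ai <- match(bonds$acc_res[b], resno)
    Np <- dc$N[di, ]; Hp <- dc$H[di, ]
    Op <- ac$O[ai, ]; Cp <- ac$C[ai, ]
    if (anyNA(Hp)) { obj <- obj + 100; next }
    rON <- sqrt(sum((Op - Np)^2)); rOH <- sqrt(sum((Op - Hp)^2))
    obj <- obj + (rON - 2.9)^2 + (rOH - 1.9)^2
  }
  dmat <- as.matrix(stats::dist(rbind(bbA$CA, B$CA)))
  n <- nrow(bbA$CA)
  dAB <- dmat[seq_len(n), n + seq_len(n)]
  obj + 10 * sum(pmax(0, 4.0 - dAB)^2)
}

.place_partner_strand <- function(bbA, bbB, bonds, resno, parallel) {
  i0 <- bonds$donor_res[1]; j0 <- bonds$acc_res[1]
  # anchor guess: bring the first bonded pair's CA atoms within sheet
  # distance, trying both faces and both flip axes
  rots <- if (parallel) list(c(0, 0, 0), c(pi, 0, 0))
          else list(c(0, pi, 0), c(0, 0, pi))
  best <- NULL
  ri <- match(if (bonds$donor_chain[1] == "A") i0 else j0, resno)
  rj <- match(if (bonds$donor_chain[1] == "A") j0 else i0, resno)
  for (r in rots) for (off in list(c(0, 4.9, 0), c(0, -4.9, 0),
                                   c(0, 0, 4.9), c(0, 0, -4.9))) {
    R <- .rotmat(r)
    caB <- as.numeric(R %*% bbB$CA[rj, ])
    t0 <- bbA$CA[ri, ] + off - caB
    par <- c(r, t0)
    fit <- stats::optim(par, .placement_objective, bbA = bbA, bbB = bbB,
                        bonds = bonds, resno = resno,
                        method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-6))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  for (k in 1:2)
    best <- stats::optim(best$par, .placement_objective, bbA = bbA,
                         bbB = bbB, bonds = bonds, resno = resno,
                         method = "Nelder-Mead",
                         control = list(maxit = 3000, reltol = 1e-12))
  best
}

#' Build a dimer conformation (or ensemble) with a known registry
#'
#' Constructs two ideal beta-strands (backbone N, CA, C, O, CB plus the
#' DSSP-convention amide H) and places the second chain by rigid-body
#' optimization so that the Kabsch-Sander hydrogen bonds realize exactly
#' the requested registry at zero noise. Gaussian coordinate jitter of
#' the stated RMS is then added independently per frame.
#'
#' @param spec a [dimer_fixture_spec()].
#' @param seed RNG seed for the jitter.
#' @param n_models number of frames to generate.
#' @return A [dimer_ensemble()] (coordinates in nm) whose `info` records
#'   the spec, seed and placement residual.
#' @export
build_dimer_conformation <- function(spec, seed = 1L, n_models = 1L) {
  stopifnot(inherits(spec, "dimer_fixture_spec"))
  bonds <- .registry_target_bonds(spec)
  nres <- length(spec$resno)
  bbA <- .ideal_strand(nres)
  bbB <- .ideal_strand(nres)
  key <- paste("place", spec$registry_kind, spec$registry_index,
               paste(spec$span_a, collapse = "."),
               paste(spec$span_b, collapse = "."), nres, sep = "_")
  fit <- .strand_cache[[key]]
  if (is.null(fit)) {
    fit <- .place_partner_strand(bbA, bbB, bonds, spec$resno,
                                 parallel = spec$registry_kind == "parallel")
    .strand_cache[[key]] <- fit
  }
  if (fit$value > 1.0)
    stop("registry index ", spec$registry_index,
         " unreachable: hydrogen-bond geometry could not be realized ",
         sprintf("(residual %.2f)", fit$value))
  bbB <- .transform_backbone(bbB, .rotmat(fit$par[1:3]), fit$par[4:6])

  res3 <- unname(.aa1to3[strsplit(spec$sequence, "")[[1]]])
  one_chain <- function(bb, chain) {
    els <- c("N", "CA", "C", "O", "CB")
    at <- do.call(rbind, lapply(seq_len(nres), function(i)
      data.frame(chain = chain, resno = spec$resno[i], resid = res3[i],
                 elety = els, stringsAsFactors = FALSE)))
    xyz <- do.call(rbind, lapply(seq_len(nres), function(i)
      rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ], bb$CB[i, ])))
    list(atoms = at, xyz = xyz)
  }
  A <- one_chain(bbA, "A"); B <- one_chain(bbB, "B")
  atoms <- rbind(A$atoms, B$atoms)
  base <- rbind(A$xyz, B$xyz)              # Angstrom
  set.seed(as.integer(seed))
  xyz <- t(vapply(seq_len(n_models), function(f) {
    jit <- if (spec$noise_rms > 0)
      matrix(stats::rnorm(length(base), 0, spec$noise_rms / sqrt(3)),
             ncol = 3) else 0
    as.numeric(t((base + jit) / 10))       # -> nm
  }, numeric(3 * nrow(atoms))))
  dimer_ensemble(atoms, xyz,
                 info = list(generator = "build_dimer_conformation",
                             spec = unclass(spec), seed = as.integer(seed),
                             placement_residual = fit$value))
}

# --- angular, distance, Gaussian and solvation generators ----------------

#' Specify a mixture of angular states for dihedral-landscape fixtures
#'
#' @param states list of lists, each with `phi`, `psi` (mean backbone
#'   dihedrals, degrees), `sd` (wrapped-normal spread, degrees) and
#'   `weight`; weights are normalized to sum to 1.
#' @param n_pairs number of (phi, psi) residue pairs per frame sharing
#'   the state means.
#' @return object of class `"landscape_spec"`.
#' @export
landscape_spec <- function(states, n_pairs = 1L) {
  w <- vapply(states, `[[`, 0, "weight")
  if (any(w < 0) || sum(w) <= 0) stop("state weights must be >= 0, sum > 0")
  if (any(vapply(states, `[[`, 0, "sd") <= 0)) stop("state sd must be > 0")
  for (k in seq_along(states)) states[[k]]$weight <- w[k] / sum(w)
  structure(list(states = states, n_pairs = as.integer(n_pairs)),
            class = "landscape_spec")
}

#' Sample a dihedral time series from an angular state mixture
#'
#' Frames are drawn i.i.d.: a state is picked with its weight, then each
#' of the `n_pairs` (phi, psi) pairs is drawn from a wrapped normal
#' around the state means. Angles are reported in degrees in
#' (-180, 180].
#'
#' @param spec a [landscape_spec()].
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return matrix `n_frames` x `2 * n_pairs` (columns phi1, psi1,
#'   phi2, ...) with attributes `state` (true state index per frame) and
#'   `params` (the generating spec and seed).
#' @export
sample_dihedral_ensemble <- function(spec, n_frames, seed = 1L) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(as.integer(seed))
  w <- vapply(spec$states, `[[`, 0, "weight")
  st <- sample.int(length(w), n_frames, replace = TRUE, prob = w)
  wrap <- function(x) { y <- (x + 180) %% 360 - 180; y[y <= -180] <- 180; y }
  m <- matrix(NA_real_, n_frames, 2 * spec$n_pairs)
  for (k in seq_along(spec$states)) {
    idx <- which(st == k); if (!length(idx)) next
    s <- spec$states[[k]]
    mu <- rep(c(s$phi, s$psi), spec$n_pairs)
    m[idx, ] <- wrap(matrix(rep(mu, each = length(idx)), nrow = length(idx)) +
                       stats::rnorm(length(idx) * 2 * spec$n_pairs, 0, s$sd))
  }
  colnames(m) <- paste0(rep(c("phi", "psi"), spec$n_pairs),
                        rep(seq_len(spec$n_pairs), each = 2))
  attr(m, "state") <- st
  attr(m, "params") <- list(spec = unclass(spec), seed = as.integer(seed))
  m
}

#' Draw i.i.d. Boltzmann distances from a 1D potential
#'
#' Samples `r` from the density proportional to `exp(-V(r)/kB T)` on
#' `r_range` by inverse-CDF interpolation on a fine grid (exactness over
#' speed).
#'
#' @param pmf_shape a [model_potential()] bounded below on the range.
#' @param temperature K.
#' @param n number of samples.
#' @param seed RNG seed.
#' @param r_range support, nm.
#' @param grid_n CDF grid resolution.
#' @return numeric vector of distances (nm) with attribute `params`.
#' @export
sample_distance_ensemble <- function(pmf_shape, temperature, n, seed = 1L,
                                     r_range = c(0.05, 2), grid_n = 10000L) {
  stopifnot(inherits(pmf_shape, "model_potential"), temperature > 0)
  r <- seq(r_range[1], r_range[2], length.out = grid_n)
  v <- potential_energy(pmf_shape, r)
  if (any(!is.finite(v))) stop("potential must be finite on r_range")
  dens <- exp(-(v - min(v)) / (phys_const$kB * temperature))
  cdf <- cumsum(dens); cdf <- cdf / cdf[grid_n]
  set.seed(as.integer(seed))
  u <- stats::runif(n)
  out <- stats::approx(cdf, r, xout = u, rule = 2, ties = "ordered")$y
  attr(out, "params") <- list(kind = pmf_shape$kind,
                              temperature = temperature, n = n,
                              seed = as.integer(seed), r_range = r_range)
  out
}

#' Sample a Gaussian coordinate trajectory with a known covariance spectrum
#'
#' Generates zero-mean Gaussian frames whose mass-weighted covariance has
#' the requested eigenvalues: mode `a` is one Cartesian coordinate of a
#' particle of mass `m_a` with variance `lambda_a / m_a`, so the
#' mass-weighted covariance eigenvalue converges to `lambda_a`
#' (amu nm^2). Ground truth for the quasiharmonic entropy machinery.
#'
#' @param spectrum data.frame or matrix with columns `mass` (amu) and
#'   `lambda` (amu nm^2), one row per mode.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return list with `xyz` (`n_frames` x n_modes matrix, nm), `masses`
#'   (per coordinate, amu) and `params`.
#' @export
sample_gaussian_coordinates <- function(spectrum, n_frames, seed = 1L) {
  spectrum <- as.data.frame(spectrum)
  stopifnot(all(c("mass", "lambda") %in% names(spectrum)),
            all(spectrum$lambda > 0), all(spectrum$mass > 0))
  set.seed(as.integer(seed))
  d <- nrow(spectrum)
  sd <- sqrt(spectrum$lambda / spectrum$mass)
  xyz <- matrix(stats::rnorm(n_frames * d), n_frames, d) %*% diag(sd, d)
  list(xyz = xyz, masses = spectrum$mass,
       params = list(spectrum = spectrum, n_frames = n_frames,
                     seed = as.integer(seed)))
}

#' Specify and place radial water shells around a point solute
#'
#' Waters are placed by Poisson sampling: a uniform background at the
#' stated bulk density plus spherical shells whose density is a stated
#' multiple of bulk. Ground truth for the radial-distribution machinery.
#'
#' @param box cubic box edge, nm.
#' @param bulk_density bulk water-oxygen number density, nm^-3 (TIP3P
#'   water at ambient conditions is ~33).
#' @param shells optional data.frame with columns `r0`, `width` (nm) and
#'   `rel_density` (multiple of bulk; the shell replaces background in
#'   its radial band). Shells must not overlap and must fit in the box.
#' @return object of class `"solvation_spec"`.
#' @export
solvation_spec <- function(box = 4, bulk_density = 33, shells = NULL) {
  if (!is.null(shells)) {
    shells <- as.data.frame(shells)
    stopifnot(all(c("r0", "width", "rel_density") %in% names(shells)))
    shells <- shells[order(shells$r0), , drop = FALSE]
    lo <- shells$r0 - shells$width / 2; hi <- shells$r0 + shells$width / 2
    if (any(lo < 0) || any(hi > box / 2)) stop("shells must fit in the box")
    if (nrow(shells) > 1 && any(lo[-1] < hi[-nrow(shells)]))
      stop("overlapping shells")
    if (any(shells$rel_density < 0)) stop("densities must be >= 0")
  }
  structure(list(box = box, bulk_density = bulk_density, shells = shells),
            class = "solvation_spec")
}

#' @rdname solvation_spec
#' @param spec a `solvation_spec`.
#' @param seed RNG seed.
#' @return `place_water_shells` returns a list with `solute` (1 x 3
#'   matrix: box center), `waters` (n x 3 matrix of oxygen positions,
#'   nm), `box` and `params`.
#' @export
place_water_shells <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "solvation_spec"))
  set.seed(as.integer(seed))
  L <- spec$box; ctr <- rep(L / 2, 3)
  n_bg <- stats::rpois(1, spec$bulk_density * L^3)
  pts <- matrix(stats::runif(3 * n_bg, 0, L), ncol = 3)
  if (!is.null(spec$shells)) {
    r <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
    keep <- rep(TRUE, nrow(pts))
    shell_pts <- NULL
    for (s in seq_len(nrow(spec$shells))) {
      lo <- spec$shells$r0[s] - spec$shells$width[s] / 2
      hi <- spec$shells$r0[s] + spec$shells$width[s] / 2
      keep <- keep & !(r >= lo & r < hi)   # shell replaces background
      vol <- 4 / 3 * pi * (hi^3 - lo^3)
      n_sh <- stats::rpois(1, spec$bulk_density *
                                spec$shells$rel_density[s] * vol)
      if (n_sh > 0) {
        u <- stats::runif(n_sh, lo^3, hi^3)^(1 / 3)
        z <- stats::runif(n_sh, -1, 1); phi <- stats::runif(n_sh, 0, 2 * pi)
        sq <- sqrt(1 - z^2)
        shell_pts <- rbind(shell_pts,
                           sweep(cbind(u * sq * cos(phi),
                                       u * sq * sin(phi), u * z),
                                 2, ctr, `+`))
      }
    }
    pts <- rbind(pts[keep, , drop = FALSE], shell_pts)
  }
  list(solute = matrix(ctr, 1, 3), waters = pts, box = L,
       params = list(spec = unclass(spec), seed = as.integer(seed)))
}
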