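# Dihedral PCA free-energy landscapes and quasiharmonic configurational
# entropy.

#' Backbone dihedral time series of an ensemble
#'
#' Computes phi/psi per residue per chain for every frame (degrees in
#' (-180, 180]). Terminal angles that need a neighbouring residue are
#' dropped.
#'
#' @param ens a [dimer_ensemble()].
#' @return matrix frames x angles, columns named
#'   `phi_<chain><resno>` / `psi_<chain><resno>`.
#' @export
backbone_dihedrals <- function(ens) {
  stopifnot(inherits(ens, "dimer_ensemble"))
  rt <- .residue_table(ens$atoms)
  n <- nrow(rt)
  specs <- list()
  for (i in seq_len(n)) {
    prev <- .res_shift(rt, i, -1L); nxt <- .res_shift(rt, i, 1L)
    if (!is.na(prev) && !anyNA(c(rt$C[prev], rt$N[i], rt$CA[i], rt$C[i])))
      specs[[length(specs) + 1]] <-
        list(name = sprintf("phi_%s%d", rt$chain[i], rt$resno[i]),
             idx = c(rt$C[prev], rt$N[i], rt$CA[i], rt$C[i]))
    if (!is.na(nxt) && !anyNA(c(rt$N[i], rt$CA[i], rt$C[i], rt$N[nxt])))
      specs[[length(specs) + 1]] <-
        list(name = sprintf("psi_%s%d", rt$chain[i], rt$resno[i]),
             idx = c(rt$N[i], rt$CA[i], rt$C[i], rt$N[nxt]))
  }
  out <- matrix(NA_real_, n_frames(ens), length(specs))
  colnames(out) <- vapply(specs, `[[`, "", "name")
  for (f in seq_len(n_frames(ens))) {
    xyz <- frame_coords(ens, f)
    out[f, ] <- vapply(specs, function(s)
      .dihedral(xyz[s$idx[1], ], xyz[s$idx[2], ], xyz[s$idx[3], ],
                xyz[s$idx[4], ]), 0)
  }
  out
}

#' Dihedral principal component analysis (dPCA)
#'
#' Maps every angle theta to the circular embedding
#' (cos theta, sin theta) and performs ordinary PCA on the resulting
#' 2M-dimensional data, avoiding the periodicity artefacts of PCA on
#' raw angles.
#'
#' @param angles matrix frames x angles, degrees (e.g. from
#'   [backbone_dihedrals()] or [sample_dihedral_ensemble()]).
#' @param n_components number of components to return scores for.
#' @return object of class `"dpca"`: list with `scores` (frames x
#'   n_components), `loadings`, `eigenvalues` (all component variances),
#'   `total_variance`.
#' @export
dpca_project <- function(angles, n_components = 2L) {
  angles <- as.matrix(angles)
  if (nrow(angles) < 2) stop("need at least 2 frames")
  if (anyNA(angles)) stop("angles must not contain missing values")
  rad <- angles * pi / 180
  emb <- cbind(cos(rad), sin(rad))
  nm <- if (is.null(colnames(angles))) paste0("a", seq_len(ncol(angles)))
        else colnames(angles)
  colnames(emb) <- c(paste0("cos_", nm), paste0("sin_", nm))
  p <- stats::prcomp(emb, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  if (all(ev < 1e-12))
    warning("constant trajectory: all component variances are zero")
  k <- min(n_components, ncol(p$x))
  structure(list(scores = p$x[, seq_len(k), drop = FALSE],
                 loadings = p$rotation[, seq_len(k), drop = FALSE],
                 eigenvalues = ev,
                 total_variance = sum(apply(emb, 2, stats::var))),
            class = "dpca")
}

#' Free-energy surface from projected scores
#'
#' Bins the first two score columns on a regular grid and converts
#' populations to relative free energies
#' `V = -kB T ln(N / Nmax)` (kJ/mol): the most populated bin is exactly
#' 0 and empty bins carry `NA` (not 0).
#'
#' @param scores matrix with >= 2 columns (only the first two are used)
#'   or a [dpca_project()] result.
#' @param temperature K.
#' @param grid integer length-2, bins per axis.
#' @param pad fractional padding of the score range.
#' @return object of class `"free_energy_surface"`: list with `x`, `y`
#'   (bin centers), `V` (matrix, kJ/mol, NA = unvisited), `counts`,
#'   `temperature`, and `assignment` (bin index per frame).
#' @export
free_energy_surface <- function(scores, temperature = 315,
                                grid = c(64L, 64L), pad = 0.05) {
  if (inherits(scores, "dpca")) scores <- scores$scores
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) stop("need at least two score columns")
  if (nrow(scores) < 1) stop("need at least one frame")
  rngx <- range(scores[, 1]); rngy <- range(scores[, 2])
  ex <- diff(rngx) * pad + 1e-9; ey <- diff(rngy) * pad + 1e-9
  bx <- seq(rngx[1] - ex, rngx[2] + ex, length.out = grid[1] + 1)
  by <- seq(rngy[1] - ey, rngy[2] + ey, length.out = grid[2] + 1)
  ix <- pmin(pmax(findInterval(scores[, 1], bx, all.inside = TRUE), 1), grid[1])
  iy <- pmin(pmax(findInterval(scores[, 2], by, all.inside = TRUE), 1), grid[2])
  counts <- matrix(0L, grid[1], grid[2])
  for (f in seq_len(nrow(scores)))
    counts[ix[f], iy[f]] <- counts[ix[f], iy[f]] + 1L
  V <- -phys_const$kB * temperature * log(counts / max(counts))
  V[counts == 0L] <- NA_real_
  structure(list(x = (bx[-1] + bx[-length(bx)]) / 2,
                 y = (by[-1] + by[-length(by)]) / 2,
                 V = V, counts = counts, temperature = temperature,
                 assignment = cbind(ix = ix, iy = iy)),
            class = "free_energy_surface")
}

#' Extract basins from a free-energy surface
#'
#' Watershed decomposition with persistence merging: visited bins are
#' processed in order of increasing free energy; a bin that touches no
#' existing basin seeds a new one, and at saddle bins the adjoining
#' basins are merged whenever the shallower one's depth below the saddle
#' is less than `min_depth` (statistically indistinguishable minima;
#' the default 1 kJ/mol matches the resolution at which distinct states
#' are usually reported on these landscapes). Basin populations are the
#' summed bin counts. If the originating ensemble is supplied, the
#' frames of each basin are clustered by pairwise backbone RMSD (leader
#' algorithm) and the medoid of the largest cluster is reported as the
#' representative conformation.
#'
#' @param fes a [free_energy_surface()].
#' @param ens optional [dimer_ensemble()] whose frames produced the
#'   scores, for representatives.
#' @param rmsd_cutoff leader-clustering cutoff, nm.
#' @param min_depth persistence threshold for keeping a separate basin,
#'   kJ/mol.
#' @param depth_window report all minima within this many kJ/mol of the
#'   global minimum in the `low_lying` count.
#' @return data.frame (class `"basin_table"`): basin id, grid location
#'   of the minimum, its free energy, population; representative frame
#'   index as attribute `representatives` when `ens` is given, plus
#'   attribute `low_lying`.
#' @export
extract_basins <- function(fes, ens = NULL, rmsd_cutoff = 0.2,
                           min_depth = 1, depth_window = 1) {
  stopifnot(inherits(fes, "free_energy_surface"))
  V <- fes$V
  nx <- nrow(V); ny <- ncol(V)
  visited <- which(is.finite(V))
  ord <- visited[order(V[visited])]
  label <- integer(nx * ny)              # 0 = unprocessed
  parent <- integer(0)                   # union-find over basin ids
  minbin <- integer(0)                   # linear index of each basin's min
  find <- function(b) { while (parent[b] != b) b <- parent[b]; b }
  for (l in ord) {
    i <- ((l - 1L) %% nx) + 1L; j <- ((l - 1L) %/% nx) + 1L
    nb <- integer(0)
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if ((di == 0 && dj == 0) || ii < 1 || ii > nx || jj < 1 || jj > ny)
        next
      lb <- label[(jj - 1L) * nx + ii]
      if (lb > 0L) nb <- c(nb, find(lb))
    }
    nb <- unique(nb)
    if (length(nb) == 0L) {              # new local minimum
      parent <- c(parent, length(parent) + 1L)
      minbin <- c(minbin, l)
      label[l] <- length(parent)
    } else if (length(nb) == 1L) {
      label[l] <- nb
    } else {                             # saddle: merge shallow basins
      deepest <- nb[which.min(V[minbin[nb]])]
      for (b in setdiff(nb, deepest))
        if (V[l] - V[minbin[b]] < min_depth) parent[b] <- deepest
      label[l] <- deepest
    }
  }
  roots <- vapply(label[visited], find, 1L)
  basin_ids <- sort(unique(roots))
  pop_total <- sum(fes$counts)
  tab <- do.call(rbind, lapply(basin_ids, function(b) {
    l <- minbin[b]
    i <- ((l - 1L) %% nx) + 1L; j <- ((l - 1L) %/% nx) + 1L
    members <- visited[roots == b]
    data.frame(x = fes$x[i], y = fes$y[j], V_min = V[i, j],
               population = sum(fes$counts[members]) / pop_total)
  }))
  ord2 <- order(tab$V_min)
  tab <- tab[ord2, , drop = FALSE]
  sorted_ids <- basin_ids[ord2]
  tab <- cbind(basin = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  attr(tab, "low_lying") <- sum(tab$V_min <= min(tab$V_min) + depth_window)
  if (!is.null(ens)) {
    stopifnot(inherits(ens, "dimer_ensemble"))
    frame_lab <- vapply(seq_len(nrow(fes$assignment)), function(f)
      find(label[(fes$assignment[f, 2] - 1L) * nx + fes$assignment[f, 1]]),
      1L)
    reps <- vapply(sorted_ids, function(b) {
      frames <- which(frame_lab == b)
      if (!length(frames)) return(NA_integer_)
      .leader_representative(ens, frames, rmsd_cutoff)
    }, 1L)
    attr(tab, "representatives") <- reps
  }
  class(tab) <- c("basin_table", "data.frame")
  tab
}

# Leader clustering on pairwise backbone RMSD (nm); returns the medoid
# frame of the largest cluster.
.leader_representative <- function(ens, frames, cutoff) {
  bb <- which(ens$atoms$elety %in% c("N", "CA", "C", "O"))
  xyz_cols <- as.numeric(t(outer(bb, 1:3, function(a, k) 3 * (a - 1) + k)))
  sub <- ens$xyz[frames, xyz_cols, drop = FALSE] * 10   # bio3d works in A
  if (length(frames) == 1) return(frames[1])
  fitted <- bio3d::fit.xyz(fixed = sub[1, ], mobile = sub,
                           fixed.inds = seq_len(ncol(sub)),
                           mobile.inds = seq_len(ncol(sub)))
  leaders <- integer(0); membership <- integer(length(frames))
  for (f in seq_along(frames)) {
    placed <- FALSE
    for (li in seq_along(leaders)) {
      r <- bio3d::rmsd(fitted[leaders[li], ], fitted[f, ]) / 10  # -> nm
      if (r < cutoff) { membership[f] <- li; placed <- TRUE; break }
    }
    if (!placed) { leaders <- c(leaders, f); membership[f] <- length(leaders) }
  }
  big <- which.max(tabulate(membership))
  mem <- which(membership == big)
  if (length(mem) == 1) return(frames[mem])
  dsum <- vapply(mem, function(a)
    sum(vapply(mem, function(b)
      bio3d::rmsd(fitted[a, ], fitted[b, ]), 0)), 0)
  frames[mem[which.min(dsum)]]
}

#' Quasiharmonic configurational entropy
#'
#' Builds the mass-weighted covariance matrix of the coordinate
#' fluctuations, takes its eigenvalues `lambda_a` (amu nm^2) as the
#' squared amplitudes of collective modes, assigns each mode the
#' frequency `omega_a = sqrt(kB T / lambda_a)` (ps^-1) and sums the
#' quantum harmonic-oscillator entropy
#' `S = kB * sum_a [ x_a/(exp(x_a)-1) - ln(1 - exp(-x_a)) ]` with
#' `x_a = hbar omega_a / (kB T)`. Modes with `lambda` below
#' `lambda_floor` (the six near-zero rigid-body modes after
#' superposition, and numerically frozen modes) are excluded; a frozen
#' mode's contribution tends to 0 in any case.
#'
#' @param xyz matrix frames x coordinates (nm). For 3D structures the
#'   columns are x1,y1,z1,x2,... and `masses` has one entry per atom;
#'   for generic mode ensembles `masses` may have one entry per column.
#' @param masses amu.
#' @param temperature K.
#' @param superpose least-squares superpose frames onto the first frame
#'   before analysis (requires 3D input); removes rigid-body motion.
#' @param lambda_floor amu nm^2.
#' @return list with `S` (kJ mol^-1 K^-1), `minus_TS` (kJ/mol),
#'   `lambda`, `omega`, `n_modes`.
#' @export
quasiharmonic_entropy <- function(xyz, masses, temperature = 315,
                                  superpose = FALSE, lambda_floor = 1e-8) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 2) stop("need at least 2 frames")
  d <- ncol(xyz)
  if (length(masses) == d / 3) masses <- rep(masses, each = 3)
  if (length(masses) != d)
    stop("'masses' must have one entry per atom or per coordinate")
  if (superpose) {
    if (d %% 3 != 0) stop("superposition requires 3D coordinates")
    xyz <- bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz,
                          fixed.inds = seq_len(d),
                          mobile.inds = seq_len(d))
  }
  mw <- sweep(xyz, 2, sqrt(masses), `*`)
  cv <- stats::cov(mw)
  lambda <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
  lambda <- lambda[lambda > lambda_floor]
  kB <- phys_const$kB; hbar <- phys_const$hbar
  omega <- sqrt(kB * temperature / lambda)
  x <- hbar * omega / (kB * temperature)
  S <- kB * sum(x / (exp(x) - 1) - log1p(-exp(-x)))
  list(S = S, minus_TS = -temperature * S, lambda = lambda, omega = omega,
       n_modes = length(lambda))
}

#' Cumulative-window entropy time series
#'
#' Recomputes the quasiharmonic entropy on growing windows `[1, t]` of
#' the trajectory — the standard REMD convergence diagnostic (the series
#' plateaus when sampling stops discovering new configuration space).
#'
#' @inheritParams quasiharmonic_entropy
#' @param times optional frame timestamps (ps); default frame indices.
#' @param n_points number of window endpoints.
#' @param plateau_slope threshold on |d(-TS)/d(window fraction)|
#'   (kJ/mol per unit fraction) under which the tail is declared
#'   converged.
#' @return data.frame (time, n_frames, S, minus_TS) with attribute
#'   `plateau` (logical) and `final_slope`.
#' @export
entropy_timeseries <- function(xyz, masses, temperature = 315,
                               times = NULL, n_points = 20L,
                               superpose = FALSE, plateau_slope = 1) {
  xyz <- as.matrix(xyz)
  nf <- nrow(xyz)
  if (is.null(times)) times <- seq_len(nf)
  ends <- unique(pmax(2L, round(seq(nf / n_points, nf, length.out = n_points))))
  out <- do.call(rbind, lapply(ends, function(t) {
    qh <- quasiharmonic_entropy(xyz[seq_len(t), , drop = FALSE], masses,
                                temperature, superpose)
    data.frame(time = times[t], n_frames = t, S = qh$S,
               minus_TS = qh$minus_TS)
  }))
  if (nrow(out) >= 3) {
    k <- nrow(out)
    frac <- out$n_frames / nf
    slope <- (out$minus_TS[k] - out$minus_TS[k - 2]) /
      (frac[k] - frac[k - 2])
    attr(out, "final_slope") <- slope
    attr(out, "plateau") <- abs(slope) < plateau_slope
  }
  out
}
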