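# Ensemble observables: potential of mean force over the inter-chain
# distance, side-chain contact maps, solvation RDFs, replica dwell-time
# diagnostics, and block-averaged errors.

#' Block-averaged standard error of a correlated series
#'
#' Splits the series into `n_blocks` contiguous blocks of equal length
#' (the remainder at the end is dropped) and reports the standard error
#' of the block means, `sd(block means)/sqrt(n_blocks)` — the standard
#' way to estimate errors on time averages of correlated simulation
#' data (here 5 blocks, matching a five-segment split of the analysis
#' window).
#'
#' @param series numeric vector.
#' @param n_blocks number of blocks (>= 2).
#' @return standard error (scalar).
#' @export
block_average_error <- function(series, n_blocks = 5L) {
  if (n_blocks < 2) stop("'n_blocks' must be >= 2")
  n <- length(series)
  if (n < n_blocks) stop("series shorter than the number of blocks")
  L <- n %/% n_blocks
  means <- vapply(seq_len(n_blocks), function(b)
    mean(series[((b - 1) * L + 1):(b * L)]), 0)
  stats::sd(means) / sqrt(n_blocks)
}

#' Potential of mean force from a distance sample
#'
#' Histogram Boltzmann inversion: a 1D grid over the inter-chain
#' distance counts the sampled conformations per bin (`N_i`) and the
#' relative free energy is `V_i = -kB T ln(N_i / N_max)`, so the most
#' populated bin is exactly 0 and empty bins carry `NA`.
#'
#' @param distances numeric vector, nm.
#' @param temperature K.
#' @param bin_width nm.
#' @param range optional length-2 range, nm.
#' @param n_blocks if > 0, per-bin standard errors by block averaging of
#'   block-wise PMFs.
#' @return object of class `"profile1d"`: data.frame (r, value, count,
#'   stderr) with attributes `kind = "pmf"`, `bin_width`, `temperature`.
#' @export
pmf_from_distances <- function(distances, temperature = 315,
                               bin_width = 0.05, range = NULL,
                               n_blocks = 0L) {
  if (length(distances) < 1) stop("need at least one sample")
  if (temperature <= 0) stop("'temperature' must be > 0")
  if (is.null(range)) range <- base::range(distances)
  breaks <- seq(floor(range[1] / bin_width) * bin_width,
                ceiling(range[2] / bin_width) * bin_width + bin_width / 2,
                by = bin_width)
  if (length(breaks) < 2) breaks <- c(breaks, breaks + bin_width)
  counts <- tabulate(findInterval(distances, breaks, all.inside = TRUE),
                     nbins = length(breaks) - 1)
  V <- -phys_const$kB * temperature * log(counts / max(counts))
  V[counts == 0] <- NA_real_
  se <- rep(NA_real_, length(counts))
  if (n_blocks >= 2 && length(distances) >= n_blocks) {
    L <- length(distances) %/% n_blocks
    bv <- vapply(seq_len(n_blocks), function(b) {
      d <- distances[((b - 1) * L + 1):(b * L)]
      cb <- tabulate(findInterval(d, breaks, all.inside = TRUE),
                     nbins = length(breaks) - 1)
      v <- -phys_const$kB * temperature * log(cb / max(cb))
      v[cb == 0] <- NA_real_
      v
    }, numeric(length(counts)))
    se <- apply(bv, 1, function(x)
      if (sum(is.finite(x)) >= 2) stats::sd(x, na.rm = TRUE) /
        sqrt(sum(is.finite(x))) else NA_real_)
  }
  out <- data.frame(r = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    value = V, count = counts, stderr = se)
  attr(out, "kind") <- "pmf"
  attr(out, "bin_width") <- bin_width
  attr(out, "temperature") <- temperature
  class(out) <- c("profile1d", "data.frame")
  out
}

#' Barrier height between the two deepest PMF minima
#'
#' Utility for double-well profiles: finds the two lowest local minima
#' of the profile and returns the highest point of the path between
#' them, relative to the shallower minimum.
#'
#' @param pmf a [pmf_from_distances()] result.
#' @return list with `barrier` (kJ/mol), `minima` (r values) and
#'   `top_r`.
#' @export
pmf_barrier <- function(pmf) {
  v <- pmf$value; r <- pmf$r
  ok <- which(is.finite(v))
  v2 <- v[ok]; r2 <- r[ok]
  n <- length(v2)
  if (n < 3) stop("profile too short for a barrier")
  locmin <- which(vapply(seq_len(n), function(i) {
    lo <- if (i > 1) v2[i - 1] else Inf
    hi <- if (i < n) v2[i + 1] else Inf
    v2[i] <= lo && v2[i] <= hi
  }, TRUE))
  if (length(locmin) < 2) stop("fewer than two local minima")
  two <- locmin[order(v2[locmin])][1:2]
  a <- min(two); b <- max(two)
  top <- which.max(v2[a:b]) + a - 1
  list(barrier = v2[top] - max(v2[a], v2[b]),
       minima = r2[two], top_r = r2[top])
}

#' Inter-chain distance between the central hydrophobic clusters
#'
#' Euclidean distance between the mass-weighted centroids of the heavy
#' atoms of the CHC residues (17-21, LVFFA) of the two chains, per
#' frame.
#'
#' @param ens a [dimer_ensemble()] with two chains containing residues
#'   17-21.
#' @param chc_range residue-number range of the cluster.
#' @return numeric vector, nm, one value per frame.
#' @export
interchain_chc_distance <- function(ens, chc_range = c(17L, 21L)) {
  stopifnot(inherits(ens, "dimer_ensemble"))
  at <- ens$atoms
  chains <- sort(unique(at$chain))
  if (length(chains) != 2) stop("need exactly two chains")
  sel <- lapply(chains, function(chn)
    which(at$chain == chn & at$resno >= chc_range[1] &
            at$resno <= chc_range[2] & at$elety != "H"))
  if (any(vapply(sel, length, 1L) == 0))
    stop("CHC residues ", chc_range[1], "-", chc_range[2],
         " missing in one chain")
  w <- lapply(sel, function(s) {
    m <- .atom_masses[at$elety[s]]
    m[is.na(m)] <- 12.011
    m
  })
  vapply(seq_len(n_frames(ens)), function(f) {
    xyz <- frame_coords(ens, f)
    c1 <- colSums(xyz[sel[[1]], , drop = FALSE] * w[[1]]) / sum(w[[1]])
    c2 <- colSums(xyz[sel[[2]], , drop = FALSE] * w[[2]]) / sum(w[[2]])
    sqrt(sum((c1 - c2)^2))
  }, 0)
}

#' Side-chain contact probability map
#'
#' `P(i, j)` is the fraction of frames in which the minimum distance
#' between side-chain heavy atoms of residue `i` (first chain) and
#' residue `j` (second chain) is below the cutoff. For a homodimer the
#' map is symmetrized by averaging `(i, j)` with `(j, i)`. Residues
#' without side-chain heavy atoms (glycine) yield zero rows/columns and
#' are flagged.
#'
#' @param ens a [dimer_ensemble()] with two chains.
#' @param cutoff nm (0.45 nm is the usual side-chain contact
#'   convention).
#' @param symmetrize average with the transposed map (homodimer).
#' @return object of class `"contact_map"`: list with `P` (matrix,
#'   rownames/colnames = residue numbers), `cutoff`, `flagged`
#'   (residues with no side-chain atoms).
#' @export
contact_map <- function(ens, cutoff = 0.45, symmetrize = TRUE) {
  stopifnot(inherits(ens, "dimer_ensemble"))
  at <- ens$atoms
  chains <- sort(unique(at$chain))
  if (length(chains) != 2) stop("need exactly two chains")
  bb <- c("N", "CA", "C", "O", "H")
  res <- sort(unique(at$resno))
  sel <- function(chn, rn) which(at$chain == chn & at$resno == rn &
                                   !(at$elety %in% bb))
  selA <- lapply(res, sel, chn = chains[1])
  selB <- lapply(res, sel, chn = chains[2])
  flagged <- res[vapply(selA, length, 1L) == 0 |
                   vapply(selB, length, 1L) == 0]
  nf <- n_frames(ens)
  P <- matrix(0, length(res), length(res), dimnames = list(res, res))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ens, f)
    for (a in seq_along(res)) for (b in seq_along(res)) {
      if (!length(selA[[a]]) || !length(selB[[b]])) next
      dmin <- min(vapply(selA[[a]], function(p)
        min(sqrt(colSums((t(xyz[selB[[b]], , drop = FALSE]) -
                            xyz[p, ])^2))), 0))
      if (dmin < cutoff) P[a, b] <- P[a, b] + 1
    }
  }
  P <- P / nf
  if (symmetrize) P <- (P + t(P)) / 2
  structure(list(P = P, cutoff = cutoff, flagged = flagged,
                 n_frames = nf),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d x %d residues, cutoff %.2f nm, max P = %.2f\n",
              nrow(x$P), ncol(x$P), x$cutoff, max(x$P)))
  invisible(x)
}

#' Solute-water radial distribution function
#'
#' `g(r)` = pair density of solute-atom / water-oxygen distances,
#' normalized by the ideal-gas expectation at the global water density
#' in the periodic box (minimum-image convention): uniform placement
#' gives `g(r) ~ 1` at every distance.
#'
#' @param solute n_s x 3 matrix of solute atom positions, nm.
#' @param waters n_w x 3 matrix of water-oxygen positions, nm.
#' @param box cubic box edge, nm.
#' @param bin_width nm.
#' @param r_max maximum distance; must not exceed half the box edge.
#' @return object of class `"profile1d"`: data.frame (r, value, count)
#'   with `kind = "rdf"`.
#' @export
rdf <- function(solute, waters, box, bin_width = 0.01, r_max = NULL) {
  solute <- rbind(solute); waters <- rbind(waters)
  if (is.null(r_max)) r_max <- box / 2
  if (r_max > box / 2 + 1e-9)
    stop("r_max beyond half the box edge: minimum-image truncation")
  breaks <- seq(0, r_max, by = bin_width)
  counts <- numeric(length(breaks) - 1)
  for (s in seq_len(nrow(solute))) {
    d <- sweep(waters, 2, solute[s, ])
    d <- d - box * round(d / box)            # minimum image
    r <- sqrt(rowSums(d^2))
    r <- r[r < r_max & r > 0]
    counts <- counts + tabulate(findInterval(r, breaks, all.inside = TRUE),
                                nbins = length(counts))
  }
  rho <- nrow(waters) / box^3
  lo <- breaks[-length(breaks)]; hi <- breaks[-1]
  expected <- nrow(solute) * rho * 4 / 3 * pi * (hi^3 - lo^3)
  out <- data.frame(r = (lo + hi) / 2, value = counts / expected,
                    count = counts)
  attr(out, "kind") <- "rdf"
  attr(out, "bin_width") <- bin_width
  class(out) <- c("profile1d", "data.frame")
  out
}

#' Replica dwell-time fractions over the temperature ladder
#'
#' Fraction of logged sweeps a given replica spends at each ladder
#' temperature — the replica-walk mixing diagnostic (a well-mixed run
#' approaches equal time at every rung).
#'
#' @param ensemble a [run_toy_remd()] result.
#' @param replica_id replica (walker) index.
#' @return object of class `"profile1d"`: data.frame (temp_index,
#'   temperature, value) with fractions summing to 1.
#' @export
dwell_fractions <- function(ensemble, replica_id = 1L) {
  stopifnot(inherits(ensemble, "replica_ensemble"))
  st <- ensemble$steps[ensemble$steps$replica == replica_id, , drop = FALSE]
  if (!nrow(st)) stop("no logged steps for replica ", replica_id)
  n_temp <- length(ensemble$ladder$temperatures)
  frac <- tabulate(st$temp_index, nbins = n_temp) / nrow(st)
  out <- data.frame(temp_index = seq_len(n_temp),
                    temperature = ensemble$ladder$temperatures,
                    value = frac)
  attr(out, "kind") <- "dwell"
  class(out) <- c("profile1d", "data.frame")
  out
}
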