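# Backbone hydrogen bonds (Kabsch-Sander electrostatic model) and
# DSSP-style secondary structure, reported in the four classes used for
# ensemble summaries: beta-sheet, helix, bend/turn, coil.

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic model for a backbone N-H...O=C hydrogen bond:
#' `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol, with
#' distances in Angstrom. A hydrogen bond is assigned when
#' `E < -0.5` kcal/mol.
#'
#' @param N,H donor backbone nitrogen and amide hydrogen coordinates
#'   (numeric(3), Angstrom). If the structure lacks amide hydrogens,
#'   infer them first (see [infer_amide_h()]).
#' @param C,O acceptor carbonyl carbon and oxygen coordinates.
#' @return energy in kcal/mol.
#' @examples
#' # ideal linear geometry (rON 2.9, rOH 1.9, rCN 3.9, rCH 3.0 A):
#' # about -3 kcal/mol
#' kabsch_sander_energy(N = c(0, 0, 0), H = c(1, 0, 0),
#'                      C = c(3.605, 1.487, 0), O = c(2.9, 0, 0))
#' @export
kabsch_sander_energy <- function(N, H, C, O) {
  if (anyNA(H)) stop("missing amide H: infer it with infer_amide_h()")
  d <- function(a, b) sqrt(sum((a - b)^2))
  rON <- d(O, N); rCH <- d(C, H); rOH <- d(O, H); rCN <- d(C, N)
  if (min(rON, rCH, rOH, rCN) <= 0.01)
    stop("atoms closer than 0.01 Angstrom; degenerate geometry")
  0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

#' Infer amide hydrogen positions (DSSP convention)
#'
#' Places H 1.0 Angstrom from the backbone N along the unit vector from
#' the preceding residue's carbonyl O to its C (i.e. anti to the
#' preceding carbonyl). The first residue of a chain (or a residue after
#' a numbering break) gets no hydrogen and cannot donate.
#'
#' @param rt residue table (internal).
#' @param coords n_atoms x 3 coordinate matrix, Angstrom.
#' @return matrix n_residues x 3 of H positions (NA rows where
#'   undefined or where an explicit H atom already exists, in which case
#'   that H is returned instead).
#' @keywords internal
.amide_hydrogens <- function(rt, coords) {
  n <- nrow(rt)
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (!is.na(rt$H[i])) { H[i, ] <- coords[rt$H[i], ]; next }
    if (i == 1) next
    prev <- i - 1
    if (rt$chain[prev] != rt$chain[i] || rt$resno[prev] != rt$resno[i] - 1)
      next
    if (is.na(rt$C[prev]) || is.na(rt$O[prev]) || is.na(rt$N[i])) next
    Cp <- coords[rt$C[prev], ]; Op <- coords[rt$O[prev], ]
    H[i, ] <- coords[rt$N[i], ] + .unit(Cp - Op) * 1.0
  }
  H
}

#' @rdname kabsch_sander_energy
#' @param ens a [dimer_ensemble()].
#' @param frame frame index.
#' @details `infer_amide_h()` returns the per-residue amide H positions
#'   (Angstrom) for one frame of an ensemble, using explicit H atoms
#'   where present and the geometric construction otherwise.
#' @export
infer_amide_h <- function(ens, frame = 1L) {
  rt <- .residue_table(ens$atoms)
  coords <- frame_coords(ens, frame) * 10
  H <- .amide_hydrogens(rt, coords)
  rownames(H) <- paste(rt$chain, rt$resno)
  H
}

#' Backbone hydrogen-bond graph of one conformation
#'
#' Evaluates the Kabsch-Sander energy for every donor/acceptor residue
#' pair whose CA atoms lie within `ca_cutoff` and keeps, per donor, the
#' `max_per_donor` lowest-energy bonds below the `-0.5` kcal/mol
#' threshold (the DSSP bookkeeping).
#'
#' @param ens a [dimer_ensemble()].
#' @param frame frame index.
#' @param cutoff H-bond energy threshold, kcal/mol.
#' @param max_per_donor bonds kept per donor residue.
#' @param ca_cutoff donor-acceptor CA distance screen, Angstrom.
#' @return data.frame (class `"hbond_graph"`): donor_chain, donor_res,
#'   acc_chain, acc_res, energy (kcal/mol).
#' @export
hbond_graph <- function(ens, frame = 1L, cutoff = -0.5, max_per_donor = 2L,
                        ca_cutoff = 9) {
  stopifnot(inherits(ens, "dimer_ensemble"))
  rt <- .residue_table(ens$atoms)
  coords <- frame_coords(ens, frame) * 10    # nm -> Angstrom
  H <- .amide_hydrogens(rt, coords)
  n <- nrow(rt)
  ca <- t(vapply(seq_len(n), function(i)
    if (is.na(rt$CA[i])) rep(NA_real_, 3) else coords[rt$CA[i], ],
    numeric(3)))
  out <- list()
  for (d in seq_len(n)) {
    if (anyNA(H[d, ]) || is.na(rt$N[d])) next
    best <- NULL
    for (a in seq_len(n)) {
      if (a == d) next
      if (is.na(rt$C[a]) || is.na(rt$O[a])) next
      if (anyNA(ca[d, ]) || anyNA(ca[a, ])) next
      if (sqrt(sum((ca[d, ] - ca[a, ])^2)) > ca_cutoff) next
      e <- kabsch_sander_energy(coords[rt$N[d], ], H[d, ],
                                coords[rt$C[a], ], coords[rt$O[a], ])
      if (e < cutoff)
        best <- rbind(best, data.frame(
          donor_chain = rt$chain[d], donor_res = rt$resno[d],
          acc_chain = rt$chain[a], acc_res = rt$resno[a], energy = e,
          stringsAsFactors = FALSE))
    }
    if (!is.null(best)) {
      best <- best[order(best$energy), , drop = FALSE]
      out[[length(out) + 1]] <- utils::head(best, max_per_donor)
    }
  }
  g <- if (length(out)) do.call(rbind, out) else
    data.frame(donor_chain = character(), donor_res = integer(),
               acc_chain = character(), acc_res = integer(),
               energy = numeric(), stringsAsFactors = FALSE)
  class(g) <- c("hbond_graph", "data.frame")
  g
}

# CO(x) -> NH(y) lookup table helper: DSSP's Hbond(x, y).
.hb_lookup <- function(g) {
  new.env(parent = emptyenv()) -> e
  if (nrow(g))
    for (k in seq_len(nrow(g)))
      assign(paste(g$acc_chain[k], g$acc_res[k], g$donor_chain[k],
                   g$donor_res[k]),
             g$energy[k], envir = e)
  e
}

.has_co_nh <- function(env, xc, xr, yc, yr)
  !is.null(env[[paste(xc, xr, yc, yr)]])

# residue index arithmetic requiring chain contiguity
.res_shift <- function(rt, i, k) {
  n <- nrow(rt)
  j <- i + k
  if (is.na(i) || j < 1 || j > n) return(NA_integer_)
  if (rt$chain[j] != rt$chain[i] || rt$resno[j] != rt$resno[i] + k)
    return(NA_integer_)
  j
}

# DSSP bridge detection from an H-bond graph: one row per bridge pair
# (residue-table indices i < j) with its type.
.frame_bridges <- function(rt, g) {
  n <- nrow(rt)
  env <- .hb_lookup(g)
  ch <- rt$chain; rn <- rt$resno
  hbij <- function(i, j) {     # CO(i) -> NH(j), residue-table indices
    if (is.na(i) || is.na(j)) return(FALSE)
    .has_co_nh(env, ch[i], rn[i], ch[j], rn[j])
  }
  sh <- function(i, k) .res_shift(rt, i, k)
  br_i <- integer(0); br_j <- integer(0); br_type <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (ch[i] == ch[j] && abs(rn[i] - rn[j]) < 3) next
    # DSSP evaluates bridges only at residues with both chain neighbours
    if (is.na(sh(i, -1)) || is.na(sh(i, 1)) ||
        is.na(sh(j, -1)) || is.na(sh(j, 1))) next
    par <- (hbij(sh(i, -1), j) && hbij(j, sh(i, 1))) ||
           (hbij(sh(j, -1), i) && hbij(i, sh(j, 1)))
    anti <- (hbij(i, j) && hbij(j, i)) ||
            (hbij(sh(i, -1), sh(j, 1)) && hbij(sh(j, -1), sh(i, 1)))
    if (par || anti) {
      br_i <- c(br_i, i); br_j <- c(br_j, j)
      br_type <- c(br_type, if (anti) "antiparallel" else "parallel")
    }
  }
  data.frame(i = br_i, j = br_j, type = br_type, stringsAsFactors = FALSE)
}

# DSSP letters for one frame from its H-bond graph.
.dssp_frame <- function(rt, coords, g) {
  n <- nrow(rt)
  env <- .hb_lookup(g)
  ch <- rt$chain; rn <- rt$resno
  shift <- function(i, k) .res_shift(rt, i, k)
  hbij <- function(i, j) {     # CO(i) -> NH(j), residue-table indices
    if (is.na(i) || is.na(j)) return(FALSE)
    .has_co_nh(env, ch[i], rn[i], ch[j], rn[j])
  }
  turn <- matrix(FALSE, n, 3, dimnames = list(NULL, c("3", "4", "5")))
  for (i in seq_len(n)) for (k in 3:5)
    if (hbij(i, shift(i, k))) turn[i, k - 2] <- TRUE

  letters <- rep("", n)
  mark <- function(idx, letter) {
    idx <- idx[!is.na(idx) & idx >= 1 & idx <= n]
    idx <- idx[letters[idx] == ""]
    letters[idx] <<- letter
    invisible(NULL)
  }
  # alpha helices: 4-turns at i-1 and i -> i..i+3 helical
  for (i in 2:n)
    if (turn[i, "4"] && !is.na(shift(i, -1)) && turn[shift(i, -1), "4"])
      mark(vapply(0:3, function(k) shift(i, k), 1L), "H")
  # bridges
  br <- .frame_bridges(rt, g)
  br_i <- br$i; br_j <- br$j; br_type <- br$type
  if (length(br_i)) {
    # ladder membership: a bridge adjacent (along both strands) to
    # another bridge of the same type belongs to an extended ladder (E);
    # isolated bridges are single bridges (B)
    ext <- rep(FALSE, length(br_i))
    for (a in seq_along(br_i)) for (b in seq_along(br_i)) {
      if (a == b || br_type[a] != br_type[b]) next
      di <- br_i[b] - br_i[a]
      dj <- br_j[b] - br_j[a]
      if (abs(di) == 1 &&
          dj == (if (br_type[a] == "parallel") di else -di))
        ext[a] <- TRUE
    }
    for (a in seq_along(br_i))
      mark(c(br_i[a], br_j[a]), if (ext[a]) "E" else "B")
  }
  # 3-10 and pi helices
  for (i in 2:n)
    if (turn[i, "3"] && !is.na(shift(i, -1)) && turn[shift(i, -1), "3"])
      mark(vapply(0:2, function(k) shift(i, k), 1L), "G")
  for (i in 2:n)
    if (turn[i, "5"] && !is.na(shift(i, -1)) && turn[shift(i, -1), "5"])
      mark(vapply(0:4, function(k) shift(i, k), 1L), "I")
  # turns
  for (i in seq_len(n)) for (k in 3:5)
    if (turn[i, k - 2])
      mark(vapply(seq_len(k - 1), function(m) shift(i, m), 1L), "T")
  # bends: CA kink > 70 degrees
  for (i in seq_len(n)) {
    im <- shift(i, -2); ip <- shift(i, 2)
    if (is.na(im) || is.na(ip)) next
    if (is.na(rt$CA[im]) || is.na(rt$CA[i]) || is.na(rt$CA[ip])) next
    u <- coords[rt$CA[i], ] - coords[rt$CA[im], ]
    v <- coords[rt$CA[ip], ] - coords[rt$CA[i], ]
    angle <- acos(max(-1, min(1, sum(u * v) /
                                sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    if (angle > 70) mark(i, "S")
  }
  letters[letters == ""] <- "C"
  letters
}

.letter_to_class <- c(H = "helix", G = "helix", I = "helix",
                      E = "beta", B = "beta",
                      T = "bend_turn", S = "bend_turn", C = "coil")

#' DSSP-style secondary-structure assignment
#'
#' Assigns per-residue secondary structure from the backbone
#' hydrogen-bond graph: beta via ladder/bridge rules, helix via runs of
#' i -> i+4 (and i+3 / i+5) hydrogen bonds, bend/turn via isolated turns
#' or CA kinks, everything else coil. Raw DSSP letters (H/G/I/E/B/T/S/C)
#' are retained alongside the four-class reduction.
#'
#' @param ens a [dimer_ensemble()].
#' @param frames frame indices (default all).
#' @inheritParams hbond_graph
#' @return object of class `"ss_assignment"`: list with `residues`
#'   (chain, resno, resid), `letters` and `classes` (frames x residues
#'   matrices) and `frames`.
#' @export
assign_secondary_structure <- function(ens, frames = NULL, cutoff = -0.5,
                                       max_per_donor = 2L, ca_cutoff = 9) {
  stopifnot(inherits(ens, "dimer_ensemble"))
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  rt <- .residue_table(ens$atoms)
  letters <- matrix(NA_character_, length(frames), nrow(rt))
  for (f in seq_along(frames)) {
    coords <- frame_coords(ens, frames[f]) * 10
    g <- hbond_graph(ens, frames[f], cutoff, max_per_donor, ca_cutoff)
    letters[f, ] <- .dssp_frame(rt, coords, g)
  }
  classes <- matrix(.letter_to_class[letters], nrow(letters), ncol(letters))
  colnames(letters) <- colnames(classes) <- paste(rt$chain, rt$resno)
  structure(list(residues = rt[, c("chain", "resno", "resid")],
                 letters = letters, classes = classes, frames = frames),
            class = "ss_assignment")
}

#' @export
print.ss_assignment <- function(x, ...) {
  cat(sprintf("ss_assignment: %d frame(s) x %d residues\n",
              nrow(x$letters), ncol(x$letters)))
  tab <- table(factor(x$classes,
                      levels = c("beta", "helix", "bend_turn", "coil")))
  print(round(tab / sum(tab), 3))
  invisible(x)
}

#' Per-residue secondary-structure fractions over an ensemble
#'
#' @param ss an [assign_secondary_structure()] result.
#' @return data.frame: chain, resno, resid, and the fraction of frames
#'   in each of the four classes.
#' @export
ss_fractions <- function(ss) {
  stopifnot(inherits(ss, "ss_assignment"))
  out <- ss$residues
  for (cl in c("beta", "helix", "bend_turn", "coil"))
    out[[cl]] <- colMeans(ss$classes == cl)
  out
}

#' Beta-sheet length observable
#'
#' The number of residues forming hydrogen-bonded beta stretches,
#' counted per frame over both chains (so a fully paired two-strand
#' dimer of 5+5 residues scores 10) and averaged over the ensemble.
#'
#' @param ss an [assign_secondary_structure()] result.
#' @param average `"cumulative"` (running mean over frames, the
#'   convergence diagnostic) or `"overall"`.
#' @return list with `per_frame`, `mean`, and `series` (the running or
#'   windowed average per frame index).
#' @export
beta_sheet_length <- function(ss, average = c("cumulative", "overall")) {
  stopifnot(inherits(ss, "ss_assignment"))
  average <- match.arg(average)
  per_frame <- rowSums(ss$classes == "beta")
  series <- if (average == "cumulative")
    cumsum(per_frame) / seq_along(per_frame)
  else rep(mean(per_frame), length(per_frame))
  list(per_frame = per_frame, mean = mean(per_frame), series = series)
}
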