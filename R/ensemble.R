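#' Conformational ensemble container
#'
#' A light-weight container for a multi-model peptide structure:
#' an atom table plus one row of coordinates per frame (bio3d-style
#' flattened xyz). Coordinates are stored in nm internally; PDB files
#' are read and written in Angstrom.
#'
#' @param atoms data.frame with columns `chain` (character), `resno`
#'   (integer), `resid` (3-letter code) and `elety` (atom name).
#' @param xyz numeric matrix, `n_frames` x `3 * n_atoms`, nm, ordered
#'   x1,y1,z1,x2,...
#' @param info optional named list of provenance (generator parameters,
#'   seed, ...).
#' @return An object of class `"dimer_ensemble"`.
#' @export
dimer_ensemble <- function(atoms, xyz, info = list()) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "resid", "elety") %in% names(atoms)))
  xyz <- rbind(xyz)
  if (ncol(xyz) != 3 * nrow(atoms))
    stop("xyz has ", ncol(xyz), " columns; expected ", 3 * nrow(atoms))
  structure(list(atoms = atoms, xyz = xyz, info = info),
            class = "dimer_ensemble")
}

#' @rdname dimer_ensemble
#' @param ens a `dimer_ensemble`.
#' @export
n_frames <- function(ens) nrow(ens$xyz)

#' Coordinates of one frame as an n_atoms x 3 matrix (nm)
#' @param ens a [dimer_ensemble()].
#' @param frame frame index (1-based).
#' @export
frame_coords <- function(ens, frame = 1L) {
  matrix(ens$xyz[frame, ], ncol = 3, byrow = TRUE)
}

#' @export
print.dimer_ensemble <- function(x, ...) {
  cat(sprintf("dimer_ensemble: %d frame(s), %d atoms, chains %s, residues %d-%d\n",
              n_frames(x), nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ","),
              min(x$atoms$resno), max(x$atoms$resno)))
  invisible(x)
}

#' Extract backbone atom indices per residue
#'
#' @return data.frame with one row per residue: chain, resno, resid and
#'   atom-table row indices for N, CA, C, O, CB and H (NA when absent).
#' @keywords internal
.residue_table <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno)
  res <- !duplicated(key)
  out <- data.frame(chain = atoms$chain[res], resno = atoms$resno[res],
                    resid = atoms$resid[res], stringsAsFactors = FALSE)
  for (el in c("N", "CA", "C", "O", "CB", "H")) {
    idx <- match(paste(out$chain, out$resno, el),
                 paste(atoms$chain, atoms$resno, atoms$elety))
    out[[el]] <- idx
  }
  out[order(out$chain, out$resno), , drop = FALSE]
}
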