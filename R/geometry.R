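# Internal-coordinate chain building and rigid-body helpers.
# Lengths in Angstrom here (PDB convention); converted at module boundaries.

#' @noRd
.unit <- function(v) v / sqrt(sum(v^2))

#' Place an atom from three reference atoms and internal coordinates
#'
#' Standard NeRF construction: the new atom D is placed at distance
#' `bond` from C, with angle B-C-D equal to `angle` and torsion
#' A-B-C-D equal to `torsion`.
#'
#' @param a,b,c numeric(3) coordinates of the three reference atoms.
#' @param bond bond length C-D (Angstrom).
#' @param angle bond angle B-C-D (degrees).
#' @param torsion dihedral A-B-C-D (degrees).
#' @return numeric(3) coordinates of the placed atom.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- .unit(c - b)
  n  <- .unit(pracma_cross(b - a, bc))
  m  <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' @noRd
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Ideal backbone geometry (Engh-Huber-like averages), Angstrom / degrees.
.bb_geom <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231, b_NH = 1.00,
  b_CACB = 1.530,
  a_CNCA = 121.7, a_NCAC = 111.2, a_CACN = 116.2, a_CACO = 120.8,
  a_NCACB = 110.4
)

#' Build backbone coordinates from phi/psi/omega torsions
#'
#' Constructs N, CA, C, O (and CB) atoms for a chain of `n` residues with
#' the given backbone torsions using ideal bond lengths and angles. The
#' amide hydrogen is not built here; see [infer_amide_h()].
#'
#' @param phi,psi numeric vectors of length `n` (degrees). `phi[1]` is
#'   unused (no preceding C) and may be `NA`.
#' @param omega peptide-bond torsion, scalar or length `n` (degrees).
#' @param with_cb logical; also place a C-beta atom per residue.
#' @return list with `n` and matrices `N`, `CA`, `C`, `O` (and `CB`),
#'   each `n` x 3, in Angstrom.
#' @keywords internal
build_backbone <- function(phi, psi, omega = 180, with_cb = TRUE) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  omega <- rep(omega, length.out = n)
  g <- .bb_geom
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  # seed first residue in a canonical pose
  N[1, ]  <- c(0, 0, 0)
  CA[1, ] <- c(g$b_NCA, 0, 0)
  C[1, ]  <- place_atom(c(0, 1, 0), N[1, ], CA[1, ], g$b_CAC, g$a_NCAC, -60)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ]  <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                            g$b_CN, g$a_CACN, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_NCA, g$a_CNCA, omega[i - 1])
      C[i, ]  <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                            g$b_CAC, g$a_NCAC, phi[i])
    }
    if (with_cb)
      CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ],
                            g$b_CACB, g$a_NCACB, 122.6)
  }
  # carbonyl O: trans to the next N across the C(i) plane, i.e. torsion
  # N(i)-CA(i)-C(i)-O(i) = psi(i) - 180 (psi defined to N(i+1))
  for (i in seq_len(n)) {
    ps <- if (i < n) psi[i] else 135  # tail O orientation is arbitrary
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_CO, g$a_CACO, ps - 180)
  }
  out <- list(n = n, N = N, CA = CA, C = C, O = O)
  if (with_cb) out$CB <- CB
  out
}

#' Dihedral angle defined by four points, degrees in (-180, 180]
#' @noRd
.dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, .unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Kabsch superposition: rigid transform mapping P onto Q
#' @return list(R, t) with Q ~ P %*% t(R) + t (rows are points)
#' @noRd
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cq - as.numeric(R %*% cp))
}

#' Rotation matrix from axis-angle parameters
#' @noRd
.rotmat <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  k <- r / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to every atom matrix of a backbone list
#' @noRd
.transform_backbone <- function(bb, R, t) {
  for (nm in intersect(names(bb), c("N", "CA", "C", "O", "CB", "H")))
    bb[[nm]] <- sweep(bb[[nm]] %*% t(R), 2, t, `+`)
  bb
}
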