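# Rigid-body superposition, the length-independent DTW loop distance, and
# CDR3 torso metrics (pseudo bond/dihedral angles, loop anchor transform,
# backbone phi/psi).

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  v / n
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

#' Kabsch superposition
#'
#' Finds the proper rotation and translation minimizing the least-squares
#' deviation between two point sets in correspondence, mapping `moving`
#' onto `reference` (y = R x + t).
#'
#' @param moving,reference N x 3 coordinate matrices, N >= 3.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   and `rmsd` (Angstrom, post-superposition).
#' @export
kabsch <- function(moving, reference) {
  moving <- as.matrix(moving); reference <- as.matrix(reference)
  stopifnot(ncol(moving) == 3, ncol(reference) == 3,
            nrow(moving) == nrow(reference))
  n <- nrow(moving)
  if (n < 3) stop("kabsch requires at least 3 points")
  mu_x <- colMeans(moving); mu_y <- colMeans(reference)
  X <- sweep(moving, 2, mu_x); Y <- sweep(reference, 2, mu_y)
  H <- t(X) %*% Y
  s <- svd(H)
  # rank < 2 (collinear points) leaves the rotation under-determined
  if (s$d[2] < 1e-9 * max(s$d[1], 1e-12)) {
    stop("kabsch: degenerate (collinear) point configuration")
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  translation <- as.numeric(mu_y - R %*% mu_x)
  fitted <- X %*% t(R)
  list(rotation = R, translation = translation,
       rmsd = sqrt(mean(rowSums((fitted - Y)^2))))
}

#' Superpose one loop onto another by its anchor residues
#'
#' Kabsch-fits the 40 backbone atoms (N, CA, C, O of the 10 anchor
#' residues) of `loop_b` onto those of `loop_a` and applies the transform
#' to every atom of `loop_b`.
#'
#' @param loop_a Reference `cdr_loop`.
#' @param loop_b Loop to transform.
#' @return `loop_b` expressed in `loop_a`'s frame; the anchor-fit RMSD is
#'   attached as attribute `"anchor_rmsd"`.
#' @export
anchor_superpose <- function(loop_a, loop_b) {
  fit <- kabsch(loop_backbone(loop_b, "anchors"),
                loop_backbone(loop_a, "anchors"))
  out <- apply_rigid(loop_b, fit$rotation, fit$translation)
  attr(out, "anchor_rmsd") <- fit$rmsd
  out
}

# Local DTW cost between residue i of a and residue j of b: RMS of the four
# backbone atom distances.
dtw_cost_matrix <- function(xa, xb) {
  n <- dim(xa)[1]; m <- dim(xb)[1]
  cost <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    di <- xa[i, , ]
    for (j in seq_len(m)) {
      cost[i, j] <- sqrt(mean(rowSums((di - xb[j, , ])^2)))
    }
  }
  cost
}

#' Length-independent DTW distance between two CDR loops
#'
#' Anchor-superposes `loop_b` onto `loop_a`, then aligns the two residue
#' series by dynamic time warping. The local cost of matching two residues
#' is the root-mean-square of their four backbone atom distances; the path
#' runs boundary to boundary with diagonal, horizontal and vertical steps,
#' and the score is the total path cost divided by the path length — an
#' RMSD-like value in Angstrom that is comparable across loop lengths.
#'
#' @param loop_a,loop_b `cdr_loop` objects (lengths may differ).
#' @param superpose Anchor-superpose first (default TRUE; set FALSE if the
#'   loops are already in a common frame).
#' @return Non-negative score in Angstrom; 0 for identical loops.
#' @export
dtw_distance <- function(loop_a, loop_b, superpose = TRUE) {
  if (dim(loop_a$cdr$xyz)[1] < 1 || dim(loop_b$cdr$xyz)[1] < 1) {
    stop("empty CDR")
  }
  if (superpose) loop_b <- anchor_superpose(loop_a, loop_b)
  cost <- dtw_cost_matrix(loop_a$cdr$xyz, loop_b$cdr$xyz)
  n <- nrow(cost); m <- ncol(cost)
  acc <- matrix(Inf, n, m)
  acc[1, 1] <- cost[1, 1]
  for (j in seq_len(m)[-1]) acc[1, j] <- acc[1, j - 1] + cost[1, j]
  for (i in seq_len(n)[-1]) {
    acc[i, 1] <- acc[i - 1, 1] + cost[i, 1]
    for (j in seq_len(m)[-1]) {
      acc[i, j] <- cost[i, j] + min(acc[i - 1, j - 1], acc[i - 1, j],
                                    acc[i, j - 1])
    }
  }
  # backtrack to count the path length (ties: diagonal, then vertical,
  # then horizontal)
  i <- n; j <- m; len <- 1L
  while (i > 1 || j > 1) {
    if (i == 1) {
      j <- j - 1
    } else if (j == 1) {
      i <- i - 1
    } else {
      prev <- c(acc[i - 1, j - 1], acc[i - 1, j], acc[i, j - 1])
      k <- which.min(prev)
      if (k == 1) { i <- i - 1; j <- j - 1 }
      else if (k == 2) i <- i - 1
      else j <- j - 1
    }
    len <- len + 1L
  }
  acc[n, m] / len
}

#' Backbone RMSD between two equal-length CDR loops
#'
#' @param loop_a,loop_b `cdr_loop` objects with equal CDR lengths.
#' @param fit_on `"loop"`: Kabsch-fit on the CDR backbone atoms themselves;
#'   `"anchors"`: fit on the 40 anchor backbone atoms, then measure over
#'   the CDR.
#' @return RMSD in Angstrom over the CDR backbone atoms.
#' @export
backbone_rmsd <- function(loop_a, loop_b, fit_on = c("loop", "anchors")) {
  fit_on <- match.arg(fit_on)
  xa <- loop_backbone(loop_a, "cdr")
  xb <- loop_backbone(loop_b, "cdr")
  if (nrow(xa) != nrow(xb)) stop("CDR length mismatch")
  if (fit_on == "loop") {
    kabsch(xb, xa)$rmsd
  } else {
    fit <- kabsch(loop_backbone(loop_b, "anchors"),
                  loop_backbone(loop_a, "anchors"))
    fitted <- sweep(xb %*% t(fit$rotation), 2, fit$translation, "+")
    sqrt(mean(rowSums((fitted - xa)^2)))
  }
}

#' Pseudo bond angle at a CA position
#'
#' Interior angle (degrees) at `ca_mid` formed by the three consecutive
#' C-alpha atoms; used at IMGT position 116 of CDR3 (tau_116).
#'
#' @param ca_prev,ca_mid,ca_next 3D points.
#' @return Angle in degrees, range (0, 180].
#' @export
pseudo_bond_angle <- function(ca_prev, ca_mid, ca_next) {
  u <- vunit(ca_prev - ca_mid)
  v <- vunit(ca_next - ca_mid)
  deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Pseudo dihedral angle over four CA positions
#'
#' Signed torsion (IUPAC convention, cis = 0) across four consecutive
#' C-alpha atoms; used at IMGT position 116 of CDR3 (alpha_116).
#'
#' @param p1,p2,p3,p4 3D points.
#' @return Torsion in degrees, range (-180, 180].
#' @export
pseudo_dihedral <- function(p1, p2, p3, p4) {
  torsion_angle(p1, p2, p3, p4)
}

# Four-point torsion, IUPAC sign, degrees in (-180, 180].
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-12 || vnorm(n2) < 1e-12) {
    stop("degenerate geometry: collinear points in torsion")
  }
  m <- vcross(n1, vunit(b2))
  ang <- deg(atan2(-sum(m * n2), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi torsions of a residue series
#'
#' Standard torsions: phi(i) = C(i-1)-N-CA-C, psi(i) = N-CA-C-N(i+1).
#' The first phi and last psi are undefined (NA), as are torsions across a
#' chain break (consecutive C–N distance at or above `bond_max`).
#'
#' @param xyz n x 4 x 3 backbone coordinate array (atoms N, CA, C, O) or a
#'   segment/`cdr_loop` span with an `xyz` element.
#' @param bond_max Chain-break cutoff for the peptide C–N bond (Angstrom).
#' @return n x 2 matrix with columns `phi`, `psi` in degrees.
#' @export
phi_psi <- function(xyz, bond_max = 1.37) {
  if (is.list(xyz)) xyz <- xyz$xyz
  n <- dim(xyz)[1]
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("phi", "psi")))
  if (n < 2) return(out)
  linked <- vapply(seq_len(n - 1), function(i) {
    vnorm(xyz[i + 1, "N", ] - xyz[i, "C", ]) < bond_max
  }, logical(1))
  for (i in seq_len(n)) {
    if (i > 1 && linked[i - 1]) {
      out[i, "phi"] <- torsion_angle(xyz[i - 1, "C", ], xyz[i, "N", ],
                                     xyz[i, "CA", ], xyz[i, "C", ])
    }
    if (i < n && linked[i]) {
      out[i, "psi"] <- torsion_angle(xyz[i, "N", ], xyz[i, "CA", ],
                                     xyz[i, "C", ], xyz[i + 1, "N", ])
    }
  }
  out
}

# Right-handed local frame at a residue: origin CA, z toward the carbonyl
# C, y perpendicular to z within the N-CA-C plane (toward N), x = y x z.
residue_frame <- function(res_xyz) {
  ca <- res_xyz["CA", ]
  z <- vunit(res_xyz["C", ] - ca)
  nv <- res_xyz["N", ] - ca
  y <- vunit(nv - sum(nv * z) * z)
  x <- vcross(y, z)
  list(origin = ca, axes = cbind(x = x, y = y, z = z))
}

# z-y-z intrinsic Euler angles (degrees) of a rotation matrix.
euler_zyz <- function(R) {
  beta <- acos(max(-1, min(1, R[3, 3])))
  if (sin(beta) > 1e-6) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else if (R[3, 3] > 0) {       # beta ~ 0
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- 0
  } else {                        # beta ~ pi
    alpha <- atan2(-R[2, 1], -R[1, 1])
    gamma <- 0
  }
  deg(c(alpha, beta, gamma))
}

rot_zyz <- function(phi, psi, theta) {
  a <- rad(phi); b <- rad(psi); g <- rad(theta)
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  Rz(a) %*% Ry(b) %*% Rz(g)
}

#' Loop anchor transform (LAT) of a CDR3 loop
#'
#' Builds the local residue frame at IMGT positions 105 and 117 (origin at
#' CA, z toward the carbonyl carbon, y perpendicular to z within the
#' N-CA-C plane, x completing a right-handed frame) and returns the
#' six-degree-of-freedom Euler transformation carrying frame(105) to
#' frame(117): the translation (X, Y, Z) expressed in frame(105)
#' coordinates and the z-y-z intrinsic Euler rotation (phi, psi, theta).
#' The values are invariant to any global rigid motion of the loop.
#'
#' @param loop A `cdr_loop` of type a3/b3/L3/H3 whose CDR contains
#'   positions 105 and 117.
#' @return Named numeric vector `X, Y, Z` (Angstrom), `phi, psi, theta`
#'   (degrees).
#' @export
lat <- function(loop) {
  pos <- loop$cdr$pos
  i105 <- match("105", pos); i117 <- match("117", pos)
  if (is.na(i105) || is.na(i117)) {
    stop("lat requires residues at IMGT positions 105 and 117")
  }
  f1 <- residue_frame(loop$cdr$xyz[i105, , ])
  f2 <- residue_frame(loop$cdr$xyz[i117, , ])
  R <- t(f1$axes) %*% f2$axes              # frame 2 expressed in frame 1
  tr <- as.numeric(t(f1$axes) %*% (f2$origin - f1$origin))
  ang <- euler_zyz(R)
  c(X = tr[1], Y = tr[2], Z = tr[3],
    phi = ang[1], psi = ang[2], theta = ang[3])
}

#' Classify a CDR3 torso as kinked or extended
#'
#' The sign of the pseudo dihedral angle alpha_116 separates the two base
#' geometries: positive alpha_116 marks the kinked region, non-positive
#' values (including the 0 boundary) are extended.
#'
#' @param tau116 Pseudo bond angle at position 116, degrees (recorded but
#'   not used by the boundary rule).
#' @param alpha116 Pseudo dihedral angle at position 116, degrees.
#' @return `"kinked"` or `"extended"`.
#' @export
torso_class <- function(tau116, alpha116) {
  stopifnot(is.finite(alpha116))
  if (alpha116 > 0) "kinked" else "extended"
}

#' Torso geometry of one CDR3 loop
#'
#' Computes tau_116 (pseudo bond angle over CA of 115/116/117), alpha_116
#' (pseudo dihedral over CA of 115/116/117/118 — the last point lies in
#' the C-terminal anchor), the loop anchor transform, the phi/psi torsions
#' of the first three (T1–T3) and last four (T4–T7) CDR3 residues, and the
#' kinked/extended torso class.
#'
#' @param loop A CDR3 `cdr_loop` (type a3, b3, L3 or H3).
#' @return List with `tau116`, `alpha116`, `lat`, `torso_phi_psi`
#'   (7 x 2 matrix, rows T1–T7) and `torso_class`.
#' @export
torso_geometry <- function(loop) {
  if (!substr(loop$cdr_type, 2, 2) == "3") {
    stop("torso geometry is defined for CDR3 loops")
  }
  span <- loop_span(loop)
  ca_at <- function(label) {
    i <- match(label, span$pos)
    if (is.na(i)) stop(sprintf("position %s missing from loop span", label))
    span$xyz[i, "CA", ]
  }
  tau <- pseudo_bond_angle(ca_at("115"), ca_at("116"), ca_at("117"))
  alpha <- pseudo_dihedral(ca_at("115"), ca_at("116"), ca_at("117"),
                           ca_at("118"))
  pp_all <- phi_psi(span$xyz)
  n_anch <- length(loop$anchors_n$pos)
  n_cdr <- length(loop$cdr$pos)
  idx <- n_anch + c(1:3, (n_cdr - 3):n_cdr)
  torso_pp <- pp_all[idx, , drop = FALSE]
  rownames(torso_pp) <- paste0("T", 1:7)
  list(tau116 = tau, alpha116 = alpha, lat = lat(loop),
       torso_phi_psi = torso_pp,
       torso_class = torso_class(tau, alpha))
}

#' Torso geometry report for a set of CDR3 loops
#'
#' @param loops List of CDR3 `cdr_loop` objects.
#' @return A tibble with one row per loop: provenance, tau116, alpha116,
#'   the six LAT components, the torso class and the T1–T7 phi/psi values.
#' @export
torso_report <- function(loops) {
  rows <- lapply(loops, function(l) {
    g <- torso_geometry(l)
    pp <- as.vector(t(g$torso_phi_psi))
    names(pp) <- paste0(rep(paste0("T", 1:7), each = 2), "_", c("phi", "psi"))
    tibble::tibble(
      source = l$source, cdr = l$cdr_type,
      tau116 = g$tau116, alpha116 = g$alpha116,
      lat_X = g$lat[["X"]], lat_Y = g$lat[["Y"]], lat_Z = g$lat[["Z"]],
      lat_phi = g$lat[["phi"]], lat_psi = g$lat[["psi"]],
      lat_theta = g$lat[["theta"]],
      torso_class = g$torso_class,
      !!!as.list(pp))
  })
  do.call(rbind, rows)
}
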