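#' Total-least-squares plane through a set of points
#'
#' Fits the plane minimising the sum of squared perpendicular distances, the
#' appropriate plane for sp2 (pi-system) groups such as carboxylates, peptide
#' amides and purine rings. The normal is the eigenvector of the smallest
#' eigenvalue of the point covariance; its sign is fixed deterministically
#' (largest-magnitude component positive).
#'
#' @param points Numeric matrix (n x 3), n >= 3, in Angstrom.
#' @param group_kind Label for the group (`"carboxylate"`, `"peptide_amide"`,
#'   `"guanine_ring"` or `"custom"`).
#' @return A `planar_group`: list with `normal` (unit 3-vector), `centroid`,
#'   `rms_residual` (Angstrom), `group_kind` and `points`.
#' @examples
#' fit_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))$normal
#' @export
fit_plane <- function(points, group_kind = "custom") {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  if (nrow(points) < 3L) stop("plane fitting needs at least 3 points")
  if (!all(is.finite(points))) stop("non-finite coordinates")
  ctr <- colMeans(points)
  cen <- sweep(points, 2L, ctr)
  sv <- svd(cen)
  ## collinear or coincident points: only one non-negligible direction
  scale_ref <- max(sv$d[1L], 1e-12)
  if (sv$d[2L] / scale_ref < 1e-9) {
    stop("degenerate geometry: points are collinear or coincident")
  }
  normal <- sv$v[, 3L]
  k <- which.max(abs(normal))
  if (normal[k] < 0) normal <- -normal
  resid <- cen %*% normal
  structure(list(
    normal = as.numeric(normal),
    centroid = as.numeric(ctr),
    rms_residual = sqrt(mean(resid^2)),
    group_kind = group_kind,
    points = points
  ), class = "planar_group")
}

#' Distance of a point from a fitted plane
#'
#' The out-of-pi-plane distance of a hydrogen-bond partner: the absolute
#' perpendicular distance from the least-squares plane of the sp2 group.
#'
#' @param plane A `planar_group` from [fit_plane()].
#' @param point Numeric 3-vector (Angstrom).
#' @return Non-negative distance in Angstrom.
#' @export
out_of_plane_distance <- function(plane, point) {
  stopifnot(inherits(plane, "planar_group"), length(point) == 3L)
  abs(sum((as.numeric(point) - plane$centroid) * plane$normal))
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares rotation + translation mapping `mov` onto `ref` over paired
#' atoms, with reflections excluded (det(R) = +1).
#'
#' @param ref,mov Numeric n x 3 matrices with matching row order, n >= 3.
#' @return A `superposition`: list with `rotation` (3 x 3, applied on the
#'   right to row-vectors of `mov`), `translation`, `rmsd` (Angstrom),
#'   `n_atoms` and `stable` (FALSE when the point set is near-collinear, in
#'   which case the in-plane rotation is ill-determined).
#' @examples
#' ref <- matrix(rnorm(12), 4, 3)
#' sp <- superpose_kabsch(ref, ref)
#' sp$rmsd
#' @export
superpose_kabsch <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (!all(dim(ref) == dim(mov))) stop("ref and mov must have matching dimensions")
  if (ncol(ref) != 3L) stop("coordinate matrices must be n x 3")
  if (nrow(ref) < 3L) stop("superposition needs at least 3 paired points")
  cr <- colMeans(ref); cm <- colMeans(mov)
  P <- sweep(mov, 2L, cm); Q <- sweep(ref, 2L, cr)
  sv <- svd(crossprod(P, Q))          # t(P) %*% Q
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  stable <- sv$d[2L] / max(sv$d[1L], 1e-12) > 1e-8
  if (!stable) warning("near-collinear point set: superposition is unstable")
  moved <- P %*% R
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(
    rotation = R,
    translation = as.numeric(cr - cm %*% R),
    rmsd = rmsd,
    n_atoms = nrow(ref),
    stable = stable
  ), class = "superposition")
}

#' Apply a superposition to coordinates
#'
#' @param sp A `superposition` from [superpose_kabsch()].
#' @param coords Numeric n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  coords <- as.matrix(coords)
  sweep(coords %*% sp$rotation, 2L, sp$translation, "+")
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

#' Rotation of a carboxylate about its O-O axis between two ligand poses
#'
#' Measures how far the carboxylate of a bound C3 acid has rotated about the
#' axis through its two carboxylate oxygens between two superposed ligand
#' poses (e.g. the glycerate of GPPG versus PEP in a homologous site). The
#' axis is the O-to-O direction averaged over the two poses after sign
#' alignment; the angle is between the projections, onto the plane normal to
#' that axis, of the vectors from the axis to a reference atom.
#'
#' @param lig_a,lig_b Atom tables (as returned by [select_atoms()]) of the
#'   two poses, already in a common frame.
#' @param oxygen_names Length-2 character vector naming the carboxylate
#'   oxygens present in both poses.
#' @param reference_atom Atom whose swing defines the angle (default `"C2"`,
#'   the carbon bonded to the carboxylate carbon).
#' @return A `rotation_result`: list with `axis` (unit 3-vector),
#'   `angle_deg` in [0, 180] and `reference_atom`.
#' @export
carboxylate_rotation <- function(lig_a, lig_b, oxygen_names = c("O1", "O2"),
                                 reference_atom = "C2") {
  getp <- function(lig, nm) {
    i <- which(lig$name == nm)
    if (!length(i)) stop("atom '", nm, "' not found in ligand")
    c(lig$x[i[1L]], lig$y[i[1L]], lig$z[i[1L]])
  }
  o1a <- getp(lig_a, oxygen_names[1L]); o2a <- getp(lig_a, oxygen_names[2L])
  o1b <- getp(lig_b, oxygen_names[1L]); o2b <- getp(lig_b, oxygen_names[2L])
  ua <- .unit(o2a - o1a); ub <- .unit(o2b - o1b)
  if (sum(ua * ub) < 0) ub <- -ub
  axis <- .unit(ua + ub)
  proj_off_axis <- function(mid, p) {
    v <- p - mid
    w <- v - sum(v * axis) * axis
    if (sqrt(sum(w^2)) < 1e-6) {
      stop("degenerate reference: atom lies on the rotation axis")
    }
    w
  }
  wa <- proj_off_axis((o1a + o2a) / 2, getp(lig_a, reference_atom))
  wb <- proj_off_axis((o1b + o2b) / 2, getp(lig_b, reference_atom))
  cosang <- sum(.unit(wa) * .unit(wb))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  structure(list(axis = axis, angle_deg = ang, reference_atom = reference_atom),
            class = "rotation_result")
}

#' Displacement of a named atom between two ligand poses
#'
#' Euclidean distance between the positions of one atom (e.g. the phosphorus
#' of the substrate phosphate) in two poses sharing a frame.
#'
#' @param lig_a,lig_b Atom tables of the two poses.
#' @param atom_selector Atom name present in both.
#' @return Distance in Angstrom.
#' @export
group_displacement <- function(lig_a, lig_b, atom_selector) {
  getp <- function(lig) {
    i <- which(lig$name == atom_selector)
    if (!length(i)) stop("atom '", atom_selector, "' not found in ligand")
    c(lig$x[i[1L]], lig$y[i[1L]], lig$z[i[1L]])
  }
  sqrt(sum((getp(lig_a) - getp(lig_b))^2))
}

## Rodrigues rotation of row-vector coordinates about a unit axis (radians)
.rotate_about_axis <- function(coords, axis, theta, origin = c(0, 0, 0)) {
  axis <- .unit(axis)
  K <- matrix(c(0, axis[3L], -axis[2L],
                -axis[3L], 0, axis[1L],
                axis[2L], -axis[1L], 0), 3L, 3L)  # cross-product matrix
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  sweep(sweep(coords, 2L, origin) %*% t(R), 2L, origin, "+")
}
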