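#' Interatomic distance
#'
#' Euclidean distance in Angstrom between two referenced atoms of a
#' conformation.
#'
#' @param conf a [conformation()].
#' @param a,b atom references (see [parse_atom_ref()]).
#' @return distance in Angstrom.
#' @export
conf_distance <- function(conf, a, b) {
  pa <- atom_coords(conf, a)
  pb <- atom_coords(conf, b)
  sqrt(sum((pa - pb)^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Signed torsion (degrees) from four points, IUPAC convention: cis = 0,
## sign by right-hand rule looking from b to c.
torsion_points <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-9 || sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18)
    stop("degenerate geometry: collinear atoms or zero-length bond in torsion",
         call. = FALSE)
  m1 <- cross3(b2 / nb2, n1)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  normalize_angle(ang * 180 / pi)
}

#' Dihedral angle
#'
#' Signed torsion angle a-b-c-d in degrees on (-180, 180], IUPAC sign
#' convention (cis = 0 degrees).
#'
#' @param conf a [conformation()].
#' @param a,b,c,d atom references.
#' @return angle in degrees.
#' @export
conf_dihedral <- function(conf, a, b, c, d) {
  torsion_points(atom_coords(conf, a), atom_coords(conf, b),
                 atom_coords(conf, c), atom_coords(conf, d))
}

#' Angular windows on the circle
#'
#' An angular window is a union of closed intervals on (-180, 180] degrees;
#' intervals with `lo > hi` wrap through the +/-180 branch cut. The syn
#' window of the glycosidic torsion is `[-25, 115]`; the anti / high-anti
#' region used by the classifier is its exact complement, so that the two
#' windows partition angle space (printed endpoints belong to syn).
#'
#' @param intervals numeric matrix (or 2-vector) of `lo`, `hi` columns in
#'   degrees.
#' @param complement if `TRUE` the window is the complement of the given
#'   intervals (used for the anti window so the partition is exact).
#' @return object of class `angular_window`.
#' @export
angular_window <- function(intervals, complement = FALSE) {
  if (is.null(dim(intervals))) intervals <- matrix(intervals, ncol = 2)
  stopifnot(ncol(intervals) == 2)
  structure(list(intervals = intervals, complement = complement),
            class = "angular_window")
}

#' @rdname angular_window
#' @export
syn_window <- function() angular_window(c(-25, 115))

#' @rdname angular_window
#' @export
anti_window <- function() angular_window(c(-25, 115), complement = TRUE)

#' Test membership of an angle in an angular window
#'
#' Angles are normalized to (-180, 180] first, so membership is unchanged by
#' adding multiples of 360 degrees.
#'
#' @param angle angle(s) in degrees.
#' @param w an [angular_window()].
#' @return logical vector.
#' @export
in_window <- function(angle, w) {
  stopifnot(inherits(w, "angular_window"))
  a <- normalize_angle(angle)
  inside <- rep(FALSE, length(a))
  for (k in seq_len(nrow(w$intervals))) {
    lo <- w$intervals[k, 1]; hi <- w$intervals[k, 2]
    inside <- inside | if (lo <= hi) (a >= lo & a <= hi)
                       else (a >= lo | a <= hi)   # wraps through 180
  }
  if (w$complement) !inside else inside
}

## Optimal rotation (Kabsch, SVD with reflection guard) mapping centered P
## onto centered Q; both n x 3.
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  s$v %*% D %*% t(s$u)
}

#' Superposition RMSD
#'
#' Least-squares RMSD over a heavy-atom selection after optimal rigid
#' superposition (rotation + translation, reflections excluded) of the
#' mobile structure onto the reference.
#'
#' @param mobile,reference [conformation()] objects with the selection
#'   present in both (same atoms, matched by residue index and atom name).
#' @param resid residue indices defining the selection (all heavy atoms of
#'   those residues). Alternatively supply `refs`, a character vector of
#'   explicit atom references.
#' @param refs optional explicit atom references overriding `resid`.
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(mobile, reference, resid = NULL, refs = NULL) {
  if (is.null(refs)) {
    stopifnot(!is.null(resid))
    sel <- heavy_selection(reference, resid)
    keys <- paste(reference$resid[sel], reference$name[sel])
    Q <- cbind(reference$x[sel], reference$y[sel], reference$z[sel])
    mkeys <- paste(mobile$resid, mobile$name)
    idx <- match(keys, mkeys)
    if (anyNA(idx))
      stop("selection mismatch: atoms absent from mobile structure: ",
           paste(utils::head(keys[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    P <- cbind(mobile$x[idx], mobile$y[idx], mobile$z[idx])
  } else {
    P <- t(vapply(refs, function(r) atom_coords(mobile, r), numeric(3)))
    Q <- t(vapply(refs, function(r) atom_coords(reference, r), numeric(3)))
  }
  if (nrow(P) < 3)
    stop("under-determined superposition: fewer than 3 atoms selected",
         call. = FALSE)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  R <- kabsch_rotation(Pc, Qc)
  diff <- Pc %*% t(R) - Qc
  sqrt(sum(diff^2) / nrow(P))
}

#' Sugar pseudorotation phase
#'
#' Altona-Sundaralingam pseudorotation phase P of a ribose ring, from the
#' five endocyclic torsions nu0..nu4, with the pucker class: north
#' (C3'-endo) for P in \[0, 36) degrees, south (C2'-endo) for P in
#' \[144, 180).
#'
#' @param conf a [conformation()]; alternatively pass `nu` directly.
#' @param resid residue index whose sugar is analyzed.
#' @param nu optional numeric vector `c(nu0, ..., nu4)` in degrees,
#'   bypassing the coordinate computation.
#' @return list with `P` (degrees in \[0, 360)), `tau_m` (amplitude,
#'   degrees) and `pucker` (`"north"`, `"south"` or `"other"`).
#' @export
pseudorotation_phase <- function(conf = NULL, resid = NULL, nu = NULL) {
  if (is.null(nu)) {
    at <- function(n) paste0(resid, ":", n)
    nu <- c(
      conf_dihedral(conf, at("C4'"), at("O4'"), at("C1'"), at("C2'")),
      conf_dihedral(conf, at("O4'"), at("C1'"), at("C2'"), at("C3'")),
      conf_dihedral(conf, at("C1'"), at("C2'"), at("C3'"), at("C4'")),
      conf_dihedral(conf, at("C2'"), at("C3'"), at("C4'"), at("O4'")),
      conf_dihedral(conf, at("C3'"), at("C4'"), at("O4'"), at("C1'")))
  }
  stopifnot(length(nu) == 5)
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * (sin(pi / 5) + sin(2 * pi / 5))
  if (max(abs(nu)) < 1e-8)
    stop("degenerate geometry: zero pucker amplitude, phase undefined",
         call. = FALSE)
  P <- atan2(num, den) * 180 / pi
  if (P < 0) P <- P + 360
  tau_m <- nu[3] / cos(P * pi / 180)
  if (!is.finite(tau_m) || abs(cos(P * pi / 180)) < 1e-8)
    tau_m <- num / (2 * (sin(pi / 5) + sin(2 * pi / 5)) * sin(P * pi / 180))
  pucker <- if (P >= 0 && P < 36) "north"
            else if (P >= 144 && P < 180) "south"
            else "other"
  list(P = P, tau_m = abs(tau_m), pucker = pucker)
}
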