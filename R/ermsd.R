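## Six-membered-ring atoms used to build base frames. For purines these are
## the atoms of the pyrimidine-type six-ring (N1, C2, N3, C4, C5, C6); for
## pyrimidines the full ring. Modified residues are rejected rather than
## guessed.
base_ring_atoms <- function(resname) {
  if (!resname %in% c("A", "G", "C", "U"))
    stop("unsupported residue type '", resname,
         "': ring atoms unknown for modified residues", call. = FALSE)
  c("N1", "C2", "N3", "C4", "C5", "C6")
}

#' Local reference frame of a nucleobase
#'
#' Origin at the centroid of the six-membered ring; z along the best-fit
#' ring normal (right-handed around the N1 -> C2 -> ... -> C6 atom cycle),
#' x toward the C2 atom projected into the ring plane, y completing a
#' right-handed set. The convention is fixed and applied identically to
#' both structures entering the eRMSD, which is all the metric requires.
#'
#' @param conf a [conformation()].
#' @param resid residue index.
#' @return list with `origin` (3-vector, Angstrom) and `axes` (3x3
#'   orthonormal matrix, rows x, y, z).
#' @export
base_frame <- function(conf, resid) {
  rn <- conf$resname[match(resid, conf$resid)]
  if (is.na(rn)) stop("atom lookup failed: no residue ", resid, call. = FALSE)
  ring <- base_ring_atoms(rn)
  pts <- t(vapply(ring, function(a) atom_coords(conf, paste0(resid, ":", a)),
                  numeric(3)))
  origin <- colMeans(pts)
  cen <- sweep(pts, 2, origin)
  ## robust planar normal: sum of consecutive cross products around the ring
  z <- c(0, 0, 0)
  for (i in 1:6) z <- z + cross3(cen[i, ], cen[if (i == 6) 1 else i + 1, ])
  z <- z / sqrt(sum(z^2))
  x <- cen[2, ] - sum(cen[2, ] * z) * z     # toward C2, in-plane
  x <- x / sqrt(sum(x^2))
  y <- cross3(z, x)
  list(origin = origin, axes = rbind(x = x, y = y, z = z))
}

## G-vector of a scaled inter-base vector rt (length-3); gamma = pi/cutoff.
## Returns 0 beyond the cutoff. |G| <= 2/gamma.
g_vector <- function(rt, cutoff) {
  rho <- sqrt(sum(rt^2))
  if (rho >= cutoff) return(c(0, 0, 0, 0))
  gamma <- pi / cutoff
  c(sin(gamma * rho) * rt / rho, 1 + cos(gamma * rho)) / gamma
}

## All pairwise G-vectors of a conformation: rows = ordered pairs (i, j),
## i != j, in fixed order.
g_vectors <- function(conf, resids, cutoff, a, b) {
  frames <- lapply(resids, function(r) base_frame(conf, r))
  n <- length(resids)
  G <- matrix(0, n * (n - 1), 4)
  k <- 0L
  for (i in seq_len(n)) {
    Ai <- frames[[i]]$axes
    oi <- frames[[i]]$origin
    for (j in seq_len(n)) {
      if (i == j) next
      k <- k + 1L
      r_local <- as.numeric(Ai %*% (frames[[j]]$origin - oi))
      G[k, ] <- g_vector(r_local / c(a, a, b), cutoff)
    }
  }
  G
}

#' Base-centric eRMSD between two structures
#'
#' For every ordered residue pair the inter-base vector (expressed in the
#' first base's local frame) is scaled by the ellipsoid (a, a, b) =
#' (5, 5, 3) Angstrom, mapped through the smooth 4-component G function
#' (zero beyond the scaled cutoff 2.4), and the eRMSD is the root mean
#' square of the G-vector differences over the number of residues:
#' sqrt( sum_pairs |G(conf) - G(ref)|^2 / N_res ).
#'
#' @param conf,reference [conformation()] objects with identical residue
#'   sequences.
#' @param cutoff scaled-distance cutoff (default 2.4).
#' @param a,b ellipsoidal scaling lengths in Angstrom (defaults 5 and 3).
#' @return non-negative eRMSD (dimensionless).
#' @export
ermsd <- function(conf, reference, cutoff = 2.4, a = 5, b = 3) {
  r1 <- unique(conf$resid)
  r2 <- unique(reference$resid)
  s1 <- conf$resname[match(r1, conf$resid)]
  s2 <- reference$resname[match(r2, reference$resid)]
  if (length(r1) != length(r2) || any(s1 != s2))
    stop("comparison error: residue sequences differ between structures",
         call. = FALSE)
  G1 <- g_vectors(conf, r1, cutoff, a, b)
  G2 <- g_vectors(reference, r2, cutoff, a, b)
  sqrt(sum((G1 - G2)^2) / length(r1))
}

#' Two-state folded indicator
#'
#' A conformer counts as folded when its eRMSD from the native reference is
#' below the threshold separating folded from un(mis)folded ensembles
#' (default 0.7).
#'
#' @inheritParams ermsd
#' @param threshold eRMSD threshold (default 0.7).
#' @return logical.
#' @export
is_folded <- function(conf, reference, threshold = 0.7, cutoff = 2.4) {
  ermsd(conf, reference, cutoff = cutoff) < threshold
}
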