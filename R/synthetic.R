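## ---------------------------------------------------------------------
## Nucleotide templates
##
## Idealized planar bases (regular-hexagon six-rings, fused regular-pentagon
## five-ring for purines) with a pentagonal ribose and a short phosphate
## tail, built in a local frame with the base in the z = 0 plane. The
## glycosidic torsion chi is imposed at construction. These templates are
## geometric fixtures for the classifier and metrics, not refined
## nucleotide geometries.
## ---------------------------------------------------------------------

base_template <- function(resname) {
  hex <- rbind(N1 = c(0, 0, 0), C2 = c(1.39, 0, 0),
               N3 = c(2.085, 1.204, 0), C4 = c(1.39, 2.407, 0),
               C5 = c(0, 2.407, 0), C6 = c(-0.695, 1.204, 0))
  if (resname %in% c("A", "G")) {
    five <- rbind(N9 = c(1.820, 3.729, 0), C8 = c(0.695, 4.545, 0),
                  N7 = c(-0.430, 3.729, 0))
    exo <- if (resname == "G")
      rbind(O6 = c(-1.925, 1.204, 0), N2 = c(2.060, -1.161, 0))
    else rbind(N6 = c(-2.035, 1.204, 0))
    rbind(hex, five, exo)
  } else if (resname == "U") {
    rbind(hex, O2 = c(2.005, -1.065, 0), O4 = c(2.005, 3.472, 0))
  } else {
    rbind(hex, O2 = c(2.005, -1.065, 0), N4 = c(2.060, 3.567, 0))
  }
}

## Regular pentagon from one edge (A -> B are ring-adjacent via the closing
## edge) in the plane with normal n; returns the three remaining vertices in
## ring order between A and B.
pentagon_complete <- function(A, B, n) {
  n <- n / sqrt(sum(n^2))
  M <- (A + B) / 2
  s <- sqrt(sum((B - A)^2))
  apo <- (s / 2) / tan(pi / 5)
  m <- cross3(n, B - A)
  m <- m / sqrt(sum(m^2))
  center <- M + apo * m
  rot <- function(p, deg) center +
    as.numeric(rotation_matrix(n, deg * pi / 180) %*% (p - center))
  ## walking A -> v1 -> v2 -> v3 -> B must close the ring: B = rot(A, -72)
  if (sum((rot(A, -72) - B)^2) > 1e-12) n <- -n
  rot <- function(p, deg) center +
    as.numeric(rotation_matrix(n, deg * pi / 180) %*% (p - center))
  list(v = rbind(rot(A, 72), rot(A, 144), rot(A, 216)), center = center,
       normal = n)
}

## Full heavy-atom nucleotide template with prescribed glycosidic chi (deg).
nt_template <- function(resname, chi = -160) {
  base <- base_template(resname)
  purine <- resname %in% c("A", "G")
  gN <- if (purine) "N9" else "N1"
  refC <- if (purine) "C4" else "C2"
  ring_center <- if (purine) colMeans(base[c("C4", "C5", "N7", "C8", "N9"), ])
                 else colMeans(base[c("N1", "C2", "N3", "C4", "C5", "C6"), ])
  gNp <- base[gN, ]
  u <- gNp - ring_center
  u <- u / sqrt(sum(u^2))
  C1p <- gNp + 1.48 * u

  ## O4' at torsion chi about the C1'-N glycosidic bond, measured against
  ## the reference base atom (O4'-C1'-N-C4 for purines, ...-N1-C2 for
  ## pyrimidines); the rotation sense is fixed numerically.
  v <- gNp - C1p
  uv <- v / sqrt(sum(v^2))
  w4 <- base[refC, ] - gNp
  w4 <- w4 - sum(w4 * uv) * uv
  w4 <- w4 / sqrt(sum(w4^2))
  e2 <- cross3(uv, w4)
  place_O4p <- function(theta, s) {
    wp <- cos(theta * pi / 180) * w4 + s * sin(theta * pi / 180) * e2
    C1p + 1.41 * (-0.334 * uv + 0.943 * wp)
  }
  O4p <- place_O4p(chi, 1)
  got <- torsion_points(O4p, C1p, gNp, base[refC, ])
  if (abs(normalize_angle(got - chi)) > 1e-6) O4p <- place_O4p(chi, -1)

  pent <- pentagon_complete(C1p, O4p, cross3(O4p - C1p, uv))
  C2p <- pent$v[1, ]; C3p <- pent$v[2, ]; C4p <- pent$v[3, ]
  pc <- pent$center; pn <- pent$normal
  out_dir <- function(p) (p - pc) / sqrt(sum((p - pc)^2))
  unitize <- function(p) p / sqrt(sum(p^2))
  O2p <- C2p + 1.41 * unitize(out_dir(C2p) + 0.6 * pn)
  O3p <- C3p + 1.41 * unitize(out_dir(C3p) - 0.6 * pn)
  dA <- out_dir(C4p)
  C5p <- C4p + 1.51 * unitize(dA + 0.7 * pn)
  O5p <- C5p + 1.42 * unitize(dA + 1.4 * pn)
  P <- O5p + 1.60 * unitize(dA + 1.0 * pn)
  side <- unitize(cross3(pn, dA))
  OP1 <- P + 1.48 * side
  OP2 <- P + 1.48 * unitize(-side + 0.8 * pn)

  sugar <- rbind("C1'" = C1p, "C2'" = C2p, "C3'" = C3p, "C4'" = C4p,
                 "O4'" = O4p, "O2'" = O2p, "O3'" = O3p, "C5'" = C5p,
                 "O5'" = O5p, P = P, OP1 = OP1, OP2 = OP2)
  xyz <- rbind(sugar, base)
  data.frame(name = rownames(xyz), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

## ---------------------------------------------------------------------
## Rigid placement helpers
## ---------------------------------------------------------------------

## Rotation taking unit(a) onto unit(b).
align_rotation <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  ax <- cross3(a, b)
  s <- sqrt(sum(ax^2)); d <- sum(a * b)
  if (s < 1e-12) {
    if (d > 0) return(diag(3))
    return(rotation_matrix(perp_vector(a), pi))
  }
  rotation_matrix(ax / s, atan2(s, d))
}

apply_rigid <- function(xyz, R, t) sweep(as.matrix(xyz) %*% t(R), 2, -t)

## Place a template so atom `nameA` -> posA and `nameB` -> posB (their
## separations must match); the free rotation about the A-B axis is chosen
## to maximize clearance from `avoid` (matrix of points).
two_point_place <- function(tmpl, nameA, posA, nameB, posB, avoid) {
  xyz <- as.matrix(tmpl[, c("x", "y", "z")])
  rownames(xyz) <- tmpl$name
  a0 <- xyz[nameA, ]; b0 <- xyz[nameB, ]
  R1 <- align_rotation(b0 - a0, posB - posA)
  xyz1 <- sweep(xyz %*% t(R1), 2, as.numeric(posA - R1 %*% a0), "+")
  axis <- (posB - posA) / sqrt(sum((posB - posA)^2))
  best <- NULL; best_clear <- -Inf
  for (deg in seq(0, 355, by = 5)) {
    R2 <- rotation_matrix(axis, deg * pi / 180)
    cand <- sweep(sweep(xyz1, 2, posA) %*% t(R2), 2, posA, "+")
    dmin <- min(sqrt(pmax(outer(rowSums(cand^2), rowSums(avoid^2), "+") -
                          2 * cand %*% t(avoid), 0)))
    if (dmin > best_clear) { best_clear <- dmin; best <- cand }
  }
  tmpl$x <- best[, 1]; tmpl$y <- best[, 2]; tmpl$z <- best[, 3]
  tmpl
}

## Place a template so atom `nameA` -> posA, pointing the template centroid
## along `away`, clearance-optimized about that axis.
one_point_place <- function(tmpl, nameA, posA, away, avoid) {
  xyz <- as.matrix(tmpl[, c("x", "y", "z")])
  rownames(xyz) <- tmpl$name
  a0 <- xyz[nameA, ]
  c0 <- colMeans(xyz)
  R1 <- align_rotation(c0 - a0, away)
  xyz1 <- sweep(xyz %*% t(R1), 2, as.numeric(posA - R1 %*% a0), "+")
  axis <- away / sqrt(sum(away^2))
  best <- NULL; best_clear <- -Inf
  for (deg in seq(0, 355, by = 5)) {
    R2 <- rotation_matrix(axis, deg * pi / 180)
    cand <- sweep(sweep(xyz1, 2, posA) %*% t(R2), 2, posA, "+")
    dmin <- min(sqrt(pmax(outer(rowSums(cand^2), rowSums(avoid^2), "+") -
                          2 * cand %*% t(avoid), 0)))
    if (dmin > best_clear) { best_clear <- dmin; best <- cand }
  }
  tmpl$x <- best[, 1]; tmpl$y <- best[, 2]; tmpl$z <- best[, 3]
  tmpl
}

residue_rows <- function(conf, resid) which(conf$resid == resid)

## Rigid-move one residue: x -> R (x - center) + center + t.
move_residue <- function(conf, resid, R = diag(3), t = c(0, 0, 0),
                         center = NULL) {
  i <- residue_rows(conf, resid)
  xyz <- cbind(conf$x[i], conf$y[i], conf$z[i])
  if (is.null(center)) center <- colMeans(xyz)
  xyz <- sweep(sweep(xyz, 2, center) %*% t(R), 2, center + t, "+")
  conf$x[i] <- xyz[, 1]; conf$y[i] <- xyz[, 2]; conf$z[i] <- xyz[, 3]
  conf
}

## Rotate the base of `resid` about its glycosidic bond until chi hits
## `target` (degrees).
rotate_chi <- function(conf, resid, target) {
  rn <- conf$resname[match(resid, conf$resid)]
  gN <- if (rn %in% c("A", "G")) "N9" else "N1"
  refC <- if (rn %in% c("A", "G")) "C4" else "C2"
  at <- function(n) paste0(resid, ":", n)
  cur <- conf_dihedral(conf, at("O4'"), at("C1'"), at(gN), at(refC))
  pN <- atom_coords(conf, at(gN))
  pC1 <- atom_coords(conf, at("C1'"))
  axis <- (pN - pC1) / sqrt(sum((pN - pC1)^2))
  base_idx <- which(conf$resid == resid & !grepl("'", conf$name, fixed = TRUE) &
                    !conf$name %in% c("P", "OP1", "OP2"))
  spin <- function(delta) {
    R <- rotation_matrix(axis, delta * pi / 180)
    xyz <- cbind(conf$x[base_idx], conf$y[base_idx], conf$z[base_idx])
    xyz <- sweep(sweep(xyz, 2, pN) %*% t(R), 2, pN, "+")
    out <- conf
    out$x[base_idx] <- xyz[, 1]; out$y[base_idx] <- xyz[, 2]
    out$z[base_idx] <- xyz[, 3]
    out
  }
  delta <- normalize_angle(target - cur)
  out <- spin(delta)
  got <- conf_dihedral(out, at("O4'"), at("C1'"), at(gN), at(refC))
  if (abs(normalize_angle(got - target)) > 1e-6) out <- spin(-delta)
  out
}

## ---------------------------------------------------------------------
## Reference scaffold
## ---------------------------------------------------------------------

.tf_cache <- new.env(parent = emptyenv())

#' Deterministic reference scaffold of the 14-mer UUCG hairpin
#'
#' Builds a stylized but geometrically consistent 14-residue hairpin
#' (sequence GGCAC-UUCG-GUGCC, loop residues 6-9) containing every atom the
#' analysis monitors. The loop is constructed so the native-state criteria
#' hold by a comfortable margin: G9 N1 - U6 O2 and the two sugar-base
#' contacts at 2.9 A, the 7BPh contact at 3.2 A, chi(G9) = +20 degrees
#' (syn); the stem is a twisted stack giving the eRMSD reference a dense
#' set of base-base contacts. It is a classifier/metric fixture emulating
#' the equilibrated starting structure, not a model of the experimental
#' coordinates; a user-supplied native structure can be passed anywhere a
#' reference is accepted.
#'
#' @return a [conformation()] of 14 residues; identical on every call.
#' @export
build_reference_scaffold <- function() {
  if (!is.null(.tf_cache$scaffold)) return(.tf_cache$scaffold)
  seqs <- c("G", "G", "C", "A", "C", "U", "U", "C", "G", "G", "U", "G",
            "C", "C")

  ## G9 first, base in the z = 0 plane, six-ring centroid at the origin.
  g9 <- nt_template("G", chi = 20)
  hexc <- colMeans(as.matrix(
    g9[g9$name %in% c("N1", "C2", "N3", "C4", "C5", "C6"), c("x", "y", "z")]))
  g9$x <- g9$x - hexc[1]; g9$y <- g9$y - hexc[2]; g9$z <- g9$z - hexc[3]
  gat <- function(n) as.numeric(g9[g9$name == n, c("x", "y", "z")])
  g_N1 <- gat("N1"); g_O6 <- gat("O6"); g_N7 <- gat("N7")
  g9_xyz <- as.matrix(g9[, c("x", "y", "z")])

  ## U6: O2 hydrogen-bonded to G9 N1, O2' to G9 O6 (both at 2.9 A).
  u_tmpl <- nt_template("U", chi = -160)
  D_u <- sqrt(sum((as.numeric(u_tmpl[u_tmpl$name == "O2", c("x", "y", "z")]) -
                   as.numeric(u_tmpl[u_tmpl$name == "O2'",
                                     c("x", "y", "z")]))^2))
  e1 <- g_N1 / sqrt(sum(g_N1^2))       # in-plane, outward at N1
  q1 <- g_N1 + 2.9 * e1
  d0 <- sqrt(sum((g_O6 - q1)^2))
  tt <- (d0^2 + D_u^2 - 2.9^2) / (2 * d0)
  rr2 <- D_u^2 - tt^2
  if (rr2 < 0) stop("scaffold construction failed: incompatible contacts")
  uu <- (g_O6 - q1) / d0
  ## the two-sphere intersection is a circle: take the point farthest from
  ## the G9 atoms so the U6 sugar does not collapse onto the G9 base
  vv0 <- perp_vector(uu)
  best_q2 <- NULL; best_d <- -Inf
  for (deg in seq(0, 355, by = 5)) {
    vv <- as.numeric(rotation_matrix(uu, deg * pi / 180) %*% vv0)
    cand <- q1 + tt * uu + sqrt(rr2) * vv
    dmin <- min(sqrt(colSums((t(g9_xyz) - cand)^2)))
    if (dmin > best_d) { best_d <- dmin; best_q2 <- cand }
  }
  q2 <- best_q2
  u6 <- two_point_place(u_tmpl, "O2", q1, "O2'", q2, avoid = g9_xyz)
  u6_xyz <- as.matrix(u6[, c("x", "y", "z")])

  ## U7: flipped out, its O2' reaching G9 N7 at 2.9 A.
  e7 <- g_N7 / sqrt(sum(g_N7^2))
  q7 <- g_N7 + 2.9 * e7
  bulk <- rbind(g9_xyz, u6_xyz)
  u7 <- one_point_place(nt_template("U", chi = -160), "O2'", q7,
                        away = q7 - colMeans(bulk), avoid = bulk)
  u7_xyz <- as.matrix(u7[, c("x", "y", "z")])

  ## C8: its N4 forming the 7BPh contact with U6 OP1 at 3.2 A.
  u6_OP1 <- as.numeric(u6[u6$name == "OP1", c("x", "y", "z")])
  u6_cen <- colMeans(u6_xyz)
  e8 <- (u6_OP1 - u6_cen) / sqrt(sum((u6_OP1 - u6_cen)^2))
  q8 <- u6_OP1 + 3.2 * e8
  bulk <- rbind(bulk, u7_xyz)
  c8 <- one_point_place(nt_template("C", chi = -160), "N4", q8,
                        away = q8 - colMeans(bulk), avoid = bulk)

  ## Stems: twisted stacks descending from U6 (strand A, residues 5..1
  ## below it) and from G9 (strand B, residues 10..14), laterally offset so
  ## the two strands face each other.
  u6_hexc <- colMeans(u6_xyz[u6$name %in% c("N1", "C2", "N3", "C4", "C5",
                                            "C6"), ])
  lateral <- u6_hexc - c(0, 0, u6_hexc[3])
  lateral <- if (sqrt(sum(lateral^2)) > 1e-6)
    lateral / sqrt(sum(lateral^2)) else c(1, 0, 0)
  nA <- c(0, 0, -1)
  place_stack <- function(resname, step, anchor, twist0) {
    tm <- nt_template(resname, chi = -160)
    xyz <- as.matrix(tm[, c("x", "y", "z")])
    hc <- colMeans(xyz[tm$name %in% c("N1", "C2", "N3", "C4", "C5", "C6"), ])
    xyz <- sweep(xyz, 2, hc)
    R <- rotation_matrix(c(0, 0, 1), (twist0 + 33 * step) * pi / 180)
    xyz <- xyz %*% t(R)
    target <- anchor + step * 3.3 * nA
    xyz <- sweep(xyz, 2, target, "+")
    tm$x <- xyz[, 1]; tm$y <- xyz[, 2]; tm$z <- xyz[, 3]
    tm
  }
  parts <- vector("list", 14)
  parts[[6]] <- u6; parts[[7]] <- u7; parts[[8]] <- c8; parts[[9]] <- g9
  for (r in 5:1)
    parts[[r]] <- place_stack(seqs[r], 6 - r, u6_hexc + 1.5 * lateral, 40)
  for (r in 10:14)
    parts[[r]] <- place_stack(seqs[r], r - 9, c(0, 0, 0) - 1.5 * lateral,
                              200)

  atoms <- do.call(rbind, lapply(1:14, function(r)
    cbind(resid = r, resname = seqs[r], parts[[r]])))
  sc <- conformation(atoms$resid, atoms$resname, atoms$name,
                     as.matrix(atoms[, c("x", "y", "z")]))
  .tf_cache$scaffold <- sc
  sc
}

## ---------------------------------------------------------------------
## Seeded generators
## ---------------------------------------------------------------------

jitter_conf <- function(conf, sd) {
  if (sd <= 0) return(conf)
  n <- nrow(conf)
  conf$x <- conf$x + stats::rnorm(n, 0, sd)
  conf$y <- conf$y + stats::rnorm(n, 0, sd)
  conf$z <- conf$z + stats::rnorm(n, 0, sd)
  conf
}

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

## Translate residue so the distance between two referenced atoms becomes
## `target` (moving along the current separation vector).
pull_residue <- function(conf, resid, ref_moving, ref_fixed, target) {
  pm <- atom_coords(conf, ref_moving)
  pf <- atom_coords(conf, ref_fixed)
  d <- sqrt(sum((pm - pf)^2))
  move_residue(conf, resid, t = (target - d) * (pm - pf) / d)
}

#' Generate a conformer belonging to a prescribed state
#'
#' Perturbs the reference scaffold by constrained, seeded randomization
#' (rigid-body moves of loop residues, glycosidic rotation of G9, Gaussian
#' jitter) so that the frame's features satisfy the target state's
#' published criteria and no higher-precedence rule. Every candidate is
#' verified through the classifier; after `max_retries` failed draws the
#' generator stops with an error rather than returning silently.
#'
#' @param state target state label (any of [tl_states()] except
#'   `unclassified`).
#' @param seed integer seed.
#' @param noise Gaussian jitter SD in Angstrom (default 0.05).
#' @param max_retries bounded rejection-sampling retries (default 200).
#' @param map,cfg atom map and classifier configuration.
#' @return a [conformation()] whose [classify_frame()] label equals
#'   `state`.
#' @export
generate_state_conformer <- function(state, seed = NULL, noise = 0.05,
                                     max_retries = 200,
                                     map = default_atom_map(),
                                     cfg = classifier_config()) {
  states <- setdiff(tl_states(), "unclassified")
  if (!state %in% states)
    stop("cannot target state '", state, "'", call. = FALSE)
  ref <- build_reference_scaffold()
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      conf <- jitter_conf(ref, noise)
      conf <- switch(state,
        native = conf,
        sugar_base_N7_lost =
          pull_residue(conf, 7, map$U7_O2p, map$G9_N7,
                       stats::runif(1, 4.2, 4.8)),
        bph7_lost =
          pull_residue(conf, 8, map$C8_N4, map$U6_proRP,
                       stats::runif(1, 4.2, 4.8)),
        both_sugar_base_lost = {
          ## swing the G9 base about its N1-O2 hydrogen-bond axis: keeps
          ## d_N1_O2 fixed while carrying O6 out of reach of U6 O2'
          ## pivot G9 rigidly about its N1 (keeping the N1-O2 H-bond) so
          ## that O6 points away from U6 O2'; N1-O6 is short (2.3 A), so
          ## the diametrically-opposed direction is needed to clear 3.5 A
          conf <- pull_residue(conf, 7, map$U7_O2p, map$G9_N7,
                               stats::runif(1, 4.2, 4.8))
          n1 <- atom_coords(conf, map$G9_N1)
          away <- n1 - atom_coords(conf, map$U6_O2p)
          away <- away / sqrt(sum(away^2)) + 0.25 * rand_unit()
          R <- align_rotation(atom_coords(conf, map$G9_O6) - n1, away)
          move_residue(conf, 9, R = R, center = n1)
        },
        C8_bulge_one_sugar_base_lost = {
          conf <- pull_residue(conf, 7, map$U7_O2p, map$G9_N7,
                               stats::runif(1, 4.2, 4.8))
          pull_residue(conf, 8, map$C8_N4, map$U6_proRP,
                       stats::runif(1, 6.0, 7.0))
        },
        G9_bulge_syn = ,
        G9_bulge_anti = {
          d1 <- atom_coords(conf, map$G9_N1) - atom_coords(conf, map$U6_O2)
          d2 <- atom_coords(conf, map$G9_O6) - atom_coords(conf, map$U6_O2p)
          dir <- d1 / sqrt(sum(d1^2)) + d2 / sqrt(sum(d2^2))
          dir <- dir / sqrt(sum(dir^2))
          conf <- move_residue(conf, 9, t = stats::runif(1, 3.5, 4.5) * dir)
          if (state == "G9_bulge_anti")
            conf <- rotate_chi(conf, 9, stats::runif(1, -150, -60))
          conf
        },
        G9_back_in_pocket_anti = {
          n1_old <- atom_coords(conf, map$G9_N1)
          conf <- rotate_chi(conf, 9, stats::runif(1, -150, -60))
          move_residue(conf, 9, t = n1_old - atom_coords(conf, map$G9_N1))
        },
        U6U7C8_bulge = {
          ## translate U6 so its O2 and pro-R_P leave their partners
          ## (> 5 A) while O2' stays in the 4-5 A band: the intact
          ## U7(O2')-G9(N7) contact then satisfies the rule's
          ## "at least one sugar-base distance < 4 A" clause without
          ## tripping the G9-bulge definition (which needs O2'-O6 > 5 A)
          v1 <- atom_coords(conf, map$U6_O2) - atom_coords(conf, map$G9_N1)
          v2 <- atom_coords(conf, map$U6_O2p) - atom_coords(conf, map$G9_O6)
          v3 <- atom_coords(conf, map$U6_proRP) - atom_coords(conf, map$C8_N4)
          u <- rand_unit()
          ## step length solved so O2'-O6 lands exactly in the 4-5 A band
          target <- stats::runif(1, 4.2, 4.7)
          pr <- sum(v2 * u)
          delta <- -pr + sqrt(pr^2 - sum(v2^2) + target^2)
          t <- delta * u
          ok <- sqrt(sum((v1 + t)^2)) > 5.2 && sqrt(sum((v3 + t)^2)) > 5.2
          if (ok) move_residue(conf, 6, t = t) else conf
        },
        loop_disrupted = {
          for (r in 6:9)
            conf <- move_residue(conf, r,
                                 R = rotation_matrix(rand_unit(),
                                   stats::runif(1, 30, 80) * pi / 180),
                                 t = stats::runif(1, 2.5, 4.5) * rand_unit())
          conf
        },
        stem_loop_disrupted = {
          for (r in 1:14)
            conf <- move_residue(conf, r,
                                 R = rotation_matrix(rand_unit(),
                                   stats::runif(1, 0, 60) * pi / 180),
                                 t = c((r - 7.5) * 1.8, 0, 0) +
                                   stats::runif(1, 0, 1) * rand_unit())
          conf
        })
      f <- extract_features(conf, map, ref)
      if (classify_frame(f, cfg) == state) return(conf)
    }
    stop("generation error: could not satisfy state '", state, "' after ",
         max_retries, " retries", call. = FALSE)
  })
}

#' Sample a state timeline from a Markov chain
#'
#' Seeded simulation of a discrete state chain started from its stationary
#' distribution, emulating the state traces of long trajectories.
#'
#' @param P row-stochastic transition matrix with state labels as
#'   `rownames` (or supply `states`).
#' @param n number of frames.
#' @param seed integer seed.
#' @param states state labels (default `rownames(P)`).
#' @return a `state_timeline` data frame (unit weights).
#' @export
generate_markov_timeline <- function(P, n, seed = NULL,
                                     states = rownames(P)) {
  P <- as.matrix(P)
  if (is.null(states)) states <- paste0("S", seq_len(nrow(P)))
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12))
    stop("validation error: transition matrix rows must be non-negative and sum to 1",
         call. = FALSE)
  pi0 <- stationary_distribution(P)
  with_seed(seed, {
    s <- integer(n)
    s[1] <- sample.int(nrow(P), 1, prob = pi0)
    if (n > 1) for (i in 2:n)
      s[i] <- sample.int(nrow(P), 1, prob = P[s[i - 1], ])
    out <- data.frame(frame = seq_len(n), time = seq_len(n) - 1,
                      state = states[s], weight = 1,
                      stringsAsFactors = FALSE)
    class(out) <- c("state_timeline", "data.frame")
    attr(out, "populations") <- timeline_populations(out)
    out
  })
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized
#' to sum to 1.
#'
#' @param P row-stochastic matrix.
#' @return numeric stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(as.matrix(P)))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

## Extended (unfolded) conformation: residues strung out along x with
## 13 A spacing so every inter-base vector lies beyond the eRMSD cutoff.
extended_conformation <- function(scaffold) {
  conf <- scaffold
  for (r in unique(conf$resid)) {
    i <- residue_rows(conf, r)
    xyz <- cbind(conf$x[i], conf$y[i], conf$z[i])
    xyz <- sweep(xyz, 2, colMeans(xyz))
    R <- rotation_matrix(rand_unit(), stats::runif(1, 0, 2 * pi))
    xyz <- xyz %*% t(R)
    xyz <- sweep(xyz, 2, c(13 * r, 0, 0), "+")
    conf$x[i] <- xyz[, 1]; conf$y[i] <- xyz[, 2]; conf$z[i] <- xyz[, 3]
  }
  conf
}

#' Generate a two-state (folded/unfolded) conformer ensemble
#'
#' Per frame, a Bernoulli(p_star) draw selects either a near-native
#' conformer (jittered scaffold, eRMSD below the folding threshold) or an
#' extended conformer (all base pairs beyond the eRMSD cutoff, eRMSD above
#' the threshold). Every generated frame is verified against
#' [is_folded()]; the ground-truth labels are returned.
#'
#' @param p_star true folded fraction in (0, 1).
#' @param n number of frames.
#' @param seed integer seed.
#' @param noise jitter SD in Angstrom (default 0.15).
#' @param threshold eRMSD folding threshold (default 0.7).
#' @param coordinates if `FALSE`, skip building coordinates and return only
#'   the indicator draw from the same Bernoulli process (for large-n
#'   statistical calibration where only the indicator enters).
#' @return list with `folded` (logical ground truth), `frames` (list of
#'   conformations, or `NULL`) and `reference` (the scaffold).
#' @export
generate_two_state_ensemble <- function(p_star, n, seed = NULL,
                                        noise = 0.15, threshold = 0.7,
                                        coordinates = TRUE) {
  stopifnot(p_star > 0, p_star < 1, n >= 1)
  ref <- build_reference_scaffold()
  with_seed(seed, {
    folded <- stats::runif(n) < p_star
    if (!coordinates)
      return(list(folded = folded, frames = NULL, reference = ref))
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      for (try in 1:50) {
        cand <- if (folded[i]) jitter_conf(ref, noise)
                else jitter_conf(extended_conformation(ref), noise)
        if (is_folded(cand, ref, threshold) == folded[i]) break
        cand <- NULL
      }
      if (is.null(cand))
        stop("generation error: could not realize folded = ", folded[i],
             call. = FALSE)
      frames[[i]] <- cand
    }
    list(folded = folded, frames = frames, reference = ref)
  })
}

#' Generate a noisy NMR observable table from an ensemble
#'
#' Builds an observable set with the standard class composition (63
#' backbone 3J, 33 sugar 3J, 253 NOE, 27 ambiguous NOE by default),
#' back-calculates every observable from the supplied ensemble, adds
#' Gaussian noise of SD `noise * sigma[class]`, and reports `sigma[class]`
#' as the experimental error. With `noise = 0` the table is exactly
#' self-consistent (total chi-square 0 on the same ensemble); with
#' `noise = 1` residuals are standard normal and the total chi-square is
#' calibrated to 1.
#'
#' @param frames list of [conformation()] frames.
#' @param weights per-frame weights (default 1).
#' @param sigma named per-class experimental errors (Hz for 3J classes,
#'   Angstrom for NOE classes).
#' @param noise noise amplitude as a multiple of `sigma` (default 1).
#' @param counts named observable counts per class.
#' @param seed integer seed.
#' @param karplus_sets Karplus coefficient table.
#' @return an observable table (see [read_observable_table()]).
#' @export
generate_nmr_dataset <- function(frames, weights = NULL,
                                 sigma = c(backbone_3J = 0.5,
                                           sugar_3J = 0.5,
                                           NOE = 0.3, ambNOE = 0.3),
                                 noise = 1,
                                 counts = c(backbone_3J = 63, sugar_3J = 33,
                                            NOE = 253, ambNOE = 27),
                                 seed = NULL,
                                 karplus_sets = default_karplus_sets()) {
  stopifnot(all(sigma > 0))
  if (is.null(weights)) weights <- rep(1, length(frames))
  ref <- frames[[1]]
  resids <- unique(ref$resid)
  with_seed(seed, {
    rows <- list()
    bb_quads <- list(c("P", "O5'", "C5'", "C4'"),
                     c("O5'", "C5'", "C4'", "C3'"),
                     c("C5'", "C4'", "C3'", "O3'"))
    su_quads <- list(c("O4'", "C1'", "C2'", "C3'"),
                     c("C1'", "C2'", "C3'", "C4'"),
                     c("C2'", "C3'", "C4'", "O4'"))
    mk_tors <- function(class, quads, kset, n_obs) {
      res <- sample(resids, n_obs, replace = TRUE)
      pick <- sample.int(length(quads), n_obs, replace = TRUE)
      data.frame(
        id = paste0(class, "_", seq_len(n_obs)), class = class,
        atoms = vapply(seq_len(n_obs), function(k)
          paste(paste0(res[k], ":", quads[[pick[k]]]), collapse = ";"),
          character(1)),
        exp_value = NA_real_, exp_error = sigma[[class]],
        karplus_set = kset, stringsAsFactors = FALSE)
    }
    rows$bb <- mk_tors("backbone_3J", bb_quads, "backbone_HCOP",
                       counts[["backbone_3J"]])
    rows$su <- mk_tors("sugar_3J", su_quads, "sugar_HCCH",
                       counts[["sugar_3J"]])

    ## candidate NOE pairs: all heavy-atom pairs of nearby residues
    ## (sequence separation <= 3) within 1.5-7 A in the first frame
    heavy <- which(!ref$name %in% c("P", "OP1", "OP2"))
    cand <- expand.grid(i1 = heavy, i2 = heavy)
    cand <- cand[cand$i1 < cand$i2 &
                 abs(ref$resid[cand$i1] - ref$resid[cand$i2]) <= 3, ]
    d <- sqrt((ref$x[cand$i1] - ref$x[cand$i2])^2 +
              (ref$y[cand$i1] - ref$y[cand$i2])^2 +
              (ref$z[cand$i1] - ref$z[cand$i2])^2)
    cand <- cand[d > 1.5 & d < 7, ]
    pair_tok <- paste0(ref$resid[cand$i1], ":", ref$name[cand$i1], ";",
                       ref$resid[cand$i2], ":", ref$name[cand$i2])
    need <- counts[["NOE"]] + 4 * counts[["ambNOE"]]
    if (length(pair_tok) < need)
      stop("generation error: not enough NOE candidate pairs", call. = FALSE)
    pair_tok <- sample(pair_tok, need)
    noe_tok <- pair_tok[seq_len(counts[["NOE"]])]
    rows$noe <- data.frame(
      id = paste0("NOE_", seq_along(noe_tok)), class = "NOE",
      atoms = noe_tok, exp_value = NA_real_, exp_error = sigma[["NOE"]],
      karplus_set = "", stringsAsFactors = FALSE)
    amb_pool <- pair_tok[-seq_len(counts[["NOE"]])]
    npair <- sample(2:4, counts[["ambNOE"]], replace = TRUE)
    stopifnot(sum(npair) <= length(amb_pool))
    idx <- c(0, cumsum(npair))
    rows$amb <- data.frame(
      id = paste0("ambNOE_", seq_len(counts[["ambNOE"]])), class = "ambNOE",
      atoms = vapply(seq_len(counts[["ambNOE"]]), function(k)
        paste(amb_pool[(idx[k] + 1):idx[k + 1]], collapse = ";"),
        character(1)),
      exp_value = NA_real_, exp_error = sigma[["ambNOE"]],
      karplus_set = "", stringsAsFactors = FALSE)

    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    truth <- vapply(seq_len(nrow(tab)), function(i) {
      v <- calc_observable(tab[i, ], frames, weights, karplus_sets)
      if (is.null(v)) NA_real_ else v
    }, numeric(1))
    if (anyNA(truth))
      stop("generation error: unresolvable atoms in generated observables",
           call. = FALSE)
    tab$exp_value <- truth +
      noise * tab$exp_error * stats::rnorm(nrow(tab))
    validate_observable_table(tab)
  })
}
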