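# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: plain arithmetic, brute-force search, or an
# unrelated algorithm.

# Euclidean norm oracle
norm_oracle <- function(p, q) {
  d <- p - q
  sqrt(d[1]^2 + d[2]^2 + d[3]^2)
}

# Decision-table oracle for the state classifier: evaluates every state's
# predicate independently (transcribed from the published criteria), then
# resolves by the documented precedence. Structured as predicate table +
# explicit resolution rather than an early-return chain.
oracle_classify <- function(f) {
  syn <- {
    a <- ((f$chi_G9 %% 360) + 360) %% 360
    a <- ifelse(a > 180, a - 360, a)
    a >= -25 & a <= 115
  }
  pred <- list(
    native = (f$d_N1_O2 < 3.5) && (f$d_O2p6_O6 < 3.5) &&
      (f$d_O2p7_N7 < 3.5) && (f$d_N4_proRP < 3.7) && syn,
    sugar_base_N7_lost = (f$d_N1_O2 < 3.5 || f$d_N2_O2 < 3.5) &&
      (f$d_O2p6_O6 < 3.5) && (f$d_O2p7_N7 > 3.5) &&
      (f$d_N4_proRP < 3.7) && syn,
    bph7_lost = (f$d_N1_O2 < 3.5 || f$d_N2_O2 < 3.5) &&
      (f$d_O2p6_O6 < 3.5) && (f$d_O2p7_N7 < 4.0) &&
      (f$d_N4_proRP > 3.7) && syn,
    both_sugar_base_lost = (f$d_N1_O2 < 3.5 || f$d_N2_O2 < 3.5) &&
      (f$d_O2p6_O6 > 3.5) && (f$d_O2p7_N7 > 3.5) &&
      (f$d_N4_proRP < 3.7) && syn,
    C8_bulge_one_sugar_base_lost = (f$d_N1_O2 < 3.5 || f$d_N2_O2 < 3.5) &&
      (f$d_O2p6_O6 > 3.5 || f$d_O2p7_N7 > 3.5) &&
      (f$d_N4_proRP > 5.0) && syn,
    G9_bulge_syn = (f$d_N1_O2 > 5.0) && (f$d_O2p6_O6 > 5.0) && syn &&
      (f$rmsd_loop < 3.0),
    G9_bulge_anti = (f$d_N1_O2 > 5.0) && (f$d_O2p6_O6 > 5.0) && !syn &&
      (f$rmsd_loop < 3.0),
    G9_back_in_pocket_anti = (f$d_N1_O2 < 5.2) &&
      (f$d_O2p6_O6 < 3.7 || f$d_N4_proRP < 4.2) && !syn &&
      (f$rmsd_loop < 3.0),
    U6U7C8_bulge = (f$d_N1_O2 > 5.0) &&
      (f$d_O2p6_O6 < 4.0 || f$d_O2p7_N7 < 4.0) &&
      (f$d_N4_proRP > 5.0) && syn,
    loop_disrupted = f$rmsd_loop > 3.0)
  if (f$rmsd_all > 4.6) return("stem_loop_disrupted")
  hits <- names(pred)[vapply(pred, isTRUE, logical(1))]
  if (length(hits) == 0) return("unclassified")
  hits[1]
}

# Grid-search superposition oracle: coarse rotation grid (ZYZ Euler
# angles) followed by Nelder-Mead polish of the rotation parameters;
# never touches an SVD.
oracle_superpose_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rotz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                               0, 0, 1), 3, 3)
  roty <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                               sin(a), 0, cos(a)), 3, 3)
  rmsd_at <- function(ang) {
    R <- rotz(ang[1]) %*% roty(ang[2]) %*% rotz(ang[3])
    sqrt(sum((Pc %*% t(R) - Qc)^2) / nrow(Pc))
  }
  grid <- expand.grid(a = seq(0, 2 * pi, by = pi / 9),
                      b = seq(0, pi, by = pi / 9),
                      c = seq(0, 2 * pi, by = pi / 9))
  vals <- apply(grid, 1, rmsd_at)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(start, rmsd_at, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 5000))
  opt$value
}

# Random small conformation (plain point cloud with valid atom bookkeeping)
random_conformation <- function(n_res = 2, atoms_per_res = 4, seed = 1) {
  set.seed(seed)
  resid <- rep(seq_len(n_res), each = atoms_per_res)
  name <- paste0("X", rep(seq_len(atoms_per_res), n_res))
  conformation(resid, rep("G", length(resid)), name,
               matrix(rnorm(length(resid) * 3, sd = 3), ncol = 3))
}

# Apply one rigid transform (rotation R then translation t) to all atoms
rigid_transform_conf <- function(conf, R, t) {
  xyz <- cbind(conf$x, conf$y, conf$z) %*% t(R)
  conf$x <- xyz[, 1] + t[1]
  conf$y <- xyz[, 2] + t[2]
  conf$z <- xyz[, 3] + t[3]
  conf
}

random_rotation <- function() {
  v <- rnorm(3); v <- v / sqrt(sum(v^2))
  tetrafold:::rotation_matrix(v, runif(1, 0, 2 * pi))
}

# Regular-hexagon "base ring" residue for toy eRMSD systems
hex_ring_conf <- function(offsets) {
  hex <- rbind(c(0, 0, 0), c(1.39, 0, 0), c(2.085, 1.204, 0),
               c(1.39, 2.407, 0), c(0, 2.407, 0), c(-0.695, 1.204, 0))
  nm <- c("N1", "C2", "N3", "C4", "C5", "C6")
  xyz <- do.call(rbind, lapply(seq_along(offsets), function(i)
    sweep(hex, 2, offsets[[i]], "+")))
  conformation(rep(seq_along(offsets), each = 6),
               rep("C", 6 * length(offsets)),
               rep(nm, length(offsets)), xyz)
}

# Feature list helper
feat <- function(d_N1_O2 = 2.9, d_N2_O2 = 4.5, d_O2p6_O6 = 3.0,
                 d_O2p7_N7 = 3.1, d_N4_proRP = 3.2, chi_G9 = 20,
                 rmsd_loop = 0.9, rmsd_all = 1.0) {
  list(d_N1_O2 = d_N1_O2, d_N2_O2 = d_N2_O2, d_O2p6_O6 = d_O2p6_O6,
       d_O2p7_N7 = d_O2p7_N7, d_N4_proRP = d_N4_proRP, chi_G9 = chi_G9,
       rmsd_loop = rmsd_loop, rmsd_all = rmsd_all)
}
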