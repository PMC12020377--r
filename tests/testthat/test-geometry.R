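test_that("distances match an independent norm oracle and basic cases", {
  conf <- conformation(c(1, 1), c("G", "G"), c("A1", "A2"),
                       rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(conf_distance(conf, "1:A1", "1:A2"), 5)
  expect_equal(conf_distance(conf, "1:A1", "1:A1"), 0)
  expect_equal(conf_distance(conf, "1:A2", "1:A1"), 5)  # symmetry
  expect_error(conf_distance(conf, "1:A1", "2:ZZ"), "2:ZZ")

  set.seed(42)
  for (i in 1:100) {
    p <- rnorm(3, sd = 5); q <- rnorm(3, sd = 5)
    cf <- conformation(c(1, 1), c("U", "U"), c("P1", "P2"), rbind(p, q))
    expect_equal(conf_distance(cf, "1:P1", "1:P2"), norm_oracle(p, q),
                 tolerance = 1e-12)
  }
})

test_that("dihedral follows the IUPAC convention with correct sign", {
  mk <- function(p1, p2, p3, p4)
    conformation(rep(1, 4), rep("G", 4), c("a", "b", "c", "d"),
                 rbind(p1, p2, p3, p4))
  cis <- mk(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, 1, 0))
  expect_equal(conf_dihedral(cis, "1:a", "1:b", "1:c", "1:d"), 0)
  trans <- mk(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, -1, 0))
  expect_equal(abs(conf_dihedral(trans, "1:a", "1:b", "1:c", "1:d")), 180)

  # constructive rotation oracle: rotate d about the b-c axis by +37 deg
  set.seed(7)
  for (i in 1:20) {
    theta <- runif(1, -170, 170)
    b <- c(1, 0, 0); cc <- c(-1, 0, 0)
    a <- b + c(rnorm(1), abs(rnorm(1)) + 0.5, rnorm(1))
    d0 <- cc + c(rnorm(1) * 0, abs(rnorm(1)) + 0.5, 0)  # cis position
    # align d0 into the a/b/c plane reference: start from torsion 0
    cf0 <- mk(a, b, cc, d0)
    base <- conf_dihedral(cf0, "1:a", "1:b", "1:c", "1:d")
    R <- tetrafold:::rotation_matrix(cc - b, theta * pi / 180)
    d1 <- as.numeric(R %*% (d0 - cc)) + cc
    cf1 <- mk(a, b, cc, d1)
    got <- conf_dihedral(cf1, "1:a", "1:b", "1:c", "1:d")
    expect_equal(tetrafold:::normalize_angle(got - base), theta,
                 tolerance = 1e-9)
  }

  # order-reversal identity on random geometries: the IUPAC torsion is
  # unchanged (value and sign) when the four atoms are read backwards
  set.seed(8)
  for (i in 1:50) {
    P <- matrix(rnorm(12, sd = 2), 4, 3)
    cf <- conformation(rep(1, 4), rep("A", 4), c("a", "b", "c", "d"), P)
    fw <- conf_dihedral(cf, "1:a", "1:b", "1:c", "1:d")
    bw <- conf_dihedral(cf, "1:d", "1:c", "1:b", "1:a")
    expect_equal(tetrafold:::normalize_angle(fw - bw), 0, tolerance = 1e-9)
  }

  degen <- mk(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(conf_dihedral(degen, "1:a", "1:b", "1:c", "1:d"),
               "degenerate")
})

test_that("angular windows are closed at printed endpoints and wrap", {
  syn <- syn_window(); anti <- anti_window()
  expect_true(in_window(30, syn))
  expect_false(in_window(150, syn))
  expect_true(in_window(150, anti))
  expect_true(in_window(-170, anti))
  expect_true(in_window(-25, syn))   # closed endpoint belongs to syn
  expect_true(in_window(115, syn))
  expect_false(in_window(-25, anti)) # exact complement
  # wrap-around invariance
  set.seed(3)
  for (a in runif(50, -180, 180)) {
    expect_identical(in_window(a, syn), in_window(a + 360, syn))
    expect_identical(in_window(a, anti), in_window(a - 720, anti))
  }
  # explicit wrapping interval through the branch cut
  w <- angular_window(c(160, -160))
  expect_true(in_window(175, w))
  expect_true(in_window(-175, w))
  expect_false(in_window(0, w))
  # syn/anti partition angle space
  for (a in seq(-180, 180, by = 7.3))
    expect_identical(in_window(a, syn), !in_window(a, anti))
})

test_that("superposition RMSD handles identity, rigid moves and a grid-search oracle", {
  set.seed(11)
  xyz <- matrix(rnorm(30, sd = 3), 10, 3)
  ref <- conformation(rep(1, 10), rep("G", 10), paste0("X", 1:10), xyz)
  expect_equal(superpose_rmsd(ref, ref, resid = 1), 0, tolerance = 1e-9)

  R <- random_rotation()
  moved <- rigid_transform_conf(ref, R, c(5, -3, 2))
  expect_equal(superpose_rmsd(moved, ref, resid = 1), 0, tolerance = 1e-6)

  # one atom displaced by 1 A: agree with grid-search oracle
  dis <- ref; dis$x[4] <- dis$x[4] + 1.0
  P <- cbind(dis$x, dis$y, dis$z); Q <- cbind(ref$x, ref$y, ref$z)
  expect_equal(superpose_rmsd(dis, ref, resid = 1),
               oracle_superpose_rmsd(P, Q), tolerance = 1e-3)

  # superposed <= raw RMSD, and invariance under common rigid transforms
  for (i in 1:10) {
    noisy <- ref
    noisy$x <- noisy$x + rnorm(10, sd = 0.5)
    noisy$y <- noisy$y + rnorm(10, sd = 0.5)
    noisy$z <- noisy$z + rnorm(10, sd = 0.5)
    raw <- sqrt(sum((cbind(noisy$x - ref$x, noisy$y - ref$y,
                           noisy$z - ref$z))^2) / 10)
    sup <- superpose_rmsd(noisy, ref, resid = 1)
    expect_lte(sup, raw + 1e-12)
    Rc <- random_rotation(); tc <- rnorm(3, sd = 4)
    expect_equal(superpose_rmsd(rigid_transform_conf(noisy, Rc, tc),
                                rigid_transform_conf(ref, Rc, tc),
                                resid = 1), sup, tolerance = 1e-6)
  }

  expect_error(superpose_rmsd(ref, ref, refs = c("1:X1", "1:X2")),
               "under-determined")
})

test_that("pseudorotation phase round-trips the inverse formula", {
  mk_nu <- function(P, tau) tau * cos((P + (0:4 - 2) * 144) * pi / 180)
  out <- pseudorotation_phase(nu = mk_nu(18, 40))
  expect_equal(out$P, 18, tolerance = 0.1)
  expect_equal(out$tau_m, 40, tolerance = 0.1)
  expect_identical(out$pucker, "north")

  south <- pseudorotation_phase(nu = mk_nu(162, 38))
  expect_equal(south$P, 162, tolerance = 0.1)
  expect_identical(south$pucker, "south")

  set.seed(5)
  for (i in 1:25) {
    P0 <- runif(1, 0, 360); tau <- runif(1, 25, 45)
    expect_equal(pseudorotation_phase(nu = mk_nu(P0, tau))$P, P0,
                 tolerance = 0.1)
  }
  expect_error(pseudorotation_phase(nu = rep(0, 5)), "degenerate")

  # from coordinates: the scaffold sugars are deliberately planar
  # pentagons (zero amplitude), the documented degenerate case; pushing
  # C2' out of plane gives a finite phase
  sc <- build_reference_scaffold()
  expect_error(pseudorotation_phase(sc, resid = 7), "degenerate")
  puck <- sc
  i <- which(puck$resid == 7 & puck$name == "C2'")
  puck$z[i] <- puck$z[i] + 0.45
  ph <- pseudorotation_phase(puck, resid = 7)
  expect_true(is.finite(ph$P) && ph$P >= 0 && ph$P < 360)
  expect_gt(ph$tau_m, 5)
})
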