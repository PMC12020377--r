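test_that("hand-picked feature vectors map to the published states", {
  expect_identical(classify_frame(feat()), "native")
  expect_identical(classify_frame(feat(d_O2p7_N7 = 4.2, d_N2_O2 = 3.0)),
                   "sugar_base_N7_lost")
  # stem+loop override beats every hydrogen-bond pattern
  expect_identical(classify_frame(feat(rmsd_all = 5.0)),
                   "stem_loop_disrupted")
  expect_identical(classify_frame(feat(d_N4_proRP = 4.0)), "bph7_lost")
  expect_identical(
    classify_frame(feat(d_N1_O2 = 6, d_O2p6_O6 = 6, rmsd_loop = 1.5)),
    "G9_bulge_syn")
  expect_identical(
    classify_frame(feat(d_N1_O2 = 6, d_O2p6_O6 = 6, chi_G9 = 160,
                        rmsd_loop = 1.5)),
    "G9_bulge_anti")
  expect_identical(
    classify_frame(feat(chi_G9 = -90, d_O2p7_N7 = 6)),
    "G9_back_in_pocket_anti")
  # the carve-out: a U6+U7+C8 bulge with high loop RMSD is never
  # relabeled loop_disrupted
  expect_identical(
    classify_frame(feat(d_N1_O2 = 6, d_O2p6_O6 = 6, d_O2p7_N7 = 3.2,
                        d_N4_proRP = 6, rmsd_loop = 3.6)),
    "U6U7C8_bulge")
  expect_identical(
    classify_frame(feat(d_N1_O2 = 4.5, d_N2_O2 = 4.5, d_O2p6_O6 = 4.5,
                        d_O2p7_N7 = 4.5, d_N4_proRP = 4.5, chi_G9 = 160,
                        rmsd_loop = 3.6)),
    "loop_disrupted")
  # uncovered region falls through to the explicit unclassified label
  expect_identical(
    classify_frame(feat(d_O2p7_N7 = 4.5, d_N4_proRP = 4.0)),
    "unclassified")
})

test_that("classifier equals the decision-table oracle on the threshold-straddling grid", {
  grid <- expand.grid(
    d_N1_O2 = c(3.3, 3.7, 4.8, 5.0, 5.2, 5.4),
    d_N2_O2 = c(3.3, 3.7),
    d_O2p6_O6 = c(3.3, 3.5, 3.7, 3.8, 3.9, 4.2, 4.8, 5.2),
    d_O2p7_N7 = c(3.3, 3.7, 3.8, 4.2),
    d_N4_proRP = c(3.5, 3.9, 4.0, 4.4, 4.8, 5.2),
    chi_G9 = c(20, 160),
    rmsd_loop = c(1, 3.5, 5),
    rmsd_all = c(1, 3.5, 5))
  expect_gte(nrow(grid), 2^10)
  cfg <- classifier_config()
  got <- character(nrow(grid))
  want <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    f <- as.list(grid[i, ])
    got[i] <- classify_frame(f, cfg)
    want[i] <- oracle_classify(f)
  }
  expect_identical(got, want)
  # every label emitted exactly once per vector (totality by construction)
  expect_true(all(got %in% tl_states()))
})

test_that("classifier is total and oracle-consistent on random feature vectors", {
  set.seed(123)
  n <- 1e5
  rf <- data.frame(
    d_N1_O2 = runif(n, 0.5, 8), d_N2_O2 = runif(n, 0.5, 8),
    d_O2p6_O6 = runif(n, 0.5, 8), d_O2p7_N7 = runif(n, 0.5, 8),
    d_N4_proRP = runif(n, 0.5, 8), chi_G9 = runif(n, -180, 180),
    rmsd_loop = runif(n, 0, 7), rmsd_all = runif(n, 0, 7))
  cfg <- classifier_config()
  labs <- character(n)
  for (i in seq_len(n)) labs[i] <- classify_frame(as.list(rf[i, ]), cfg)
  expect_true(all(labs %in% tl_states()))
  # override invariant
  expect_true(all(labs[rf$rmsd_all > 4.6] == "stem_loop_disrupted"))
  # spot-check oracle agreement on a subsample
  idx <- sample.int(n, 2000)
  for (i in idx)
    expect_identical(labs[i], oracle_classify(as.list(rf[i, ])))
})

test_that("monotone perturbation off native yields sugar_base_N7_lost", {
  set.seed(4)
  for (i in 1:50) {
    f <- feat(d_N1_O2 = runif(1, 2.5, 3.4), d_O2p6_O6 = runif(1, 2.5, 3.4),
              d_O2p7_N7 = runif(1, 2.5, 3.4),
              d_N4_proRP = runif(1, 2.7, 3.6),
              chi_G9 = runif(1, -20, 110))
    expect_identical(classify_frame(f), "native")
    f$d_O2p7_N7 <- runif(1, 3.55, 3.99)
    expect_identical(classify_frame(f), "sugar_base_N7_lost")
  }
})

test_that("trajectory classification aggregates weighted populations", {
  ref <- build_reference_scaffold()
  frames <- lapply(1:4, function(k) generate_state_conformer("native", seed = k))
  tl <- classify_trajectory(frames, reference = ref)
  expect_equal(unname(attr(tl, "populations")["native"]), 1.0)
  expect_equal(sum(attr(tl, "populations")), 1, tolerance = 1e-12)

  # weighted populations equal frame replication of integer weights
  frames2 <- c(frames,
               lapply(5:6, function(k)
                 generate_state_conformer("bph7_lost", seed = k)))
  w <- c(3, 1, 2, 1, 2, 3)
  tw <- classify_trajectory(frames2, reference = ref, weights = w)
  rep_frames <- frames2[rep(seq_along(frames2), w)]
  tr <- classify_trajectory(rep_frames, reference = ref)
  pw <- attr(tw, "populations"); pr <- attr(tr, "populations")
  expect_equal(pw[sort(names(pw))], pr[sort(names(pr))], tolerance = 1e-12)
})

test_that("per-state RMSD statistics use the population SD", {
  tl <- data.frame(state = c("a", "a", "b"), weight = 1,
                   rmsd_loop = c(1, 3, 1))
  st <- state_rmsd_stats(tl)
  a <- st[st$state == "a", ]
  expect_equal(a$mean, 2); expect_equal(a$sd, 1)  # population SD
  b <- st[st$state == "b", ]
  expect_equal(b$mean, 1); expect_equal(b$sd, 0)
  # random series vs direct two-pass oracle
  set.seed(9)
  x <- rnorm(40); tl2 <- data.frame(state = "s", weight = 1, rmsd_loop = x)
  st2 <- state_rmsd_stats(tl2)
  expect_equal(st2$mean, sum(x) / 40, tolerance = 1e-12)
  expect_equal(st2$sd, sqrt(sum((x - mean(x))^2) / 40), tolerance = 1e-12)
})
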