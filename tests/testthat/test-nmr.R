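test_that("Karplus evaluation matches direct arithmetic", {
  expect_equal(karplus_3j(0, A = 9.67, B = -2.03, C = 0.68),
               9.67 - 2.03 + 0.68)
  expect_equal(karplus_3j(90, A = 9.67, B = -2.03, C = 0.68), 0.68,
               tolerance = 1e-12)
  expect_equal(karplus_3j(50, A = 1, B = 0, C = 0, offset = 40), 0,
               tolerance = 1e-12)
  set.seed(12)
  for (i in 1:50) {
    th <- runif(1, -360, 360); A <- rnorm(1, 10); B <- rnorm(1); C <- rnorm(1)
    off <- runif(1, -180, 180)
    ct <- cos((th + off) / 180 * pi)
    expect_equal(karplus_3j(th, A, B, C, off), A * ct * ct + B * ct + C,
                 tolerance = 1e-12)
  }
})

test_that("NOE averaging uses r^-6 with power-mean bounds", {
  expect_equal(noe_effective(rep(3.1, 10)), 3.1, tolerance = 1e-12)
  expect_equal(noe_effective(c(2, 4)), ((2^-6 + 4^-6) / 2)^(-1 / 6),
               tolerance = 1e-12)
  expect_equal(noe_effective(c(2, 4)), 2.2392, tolerance = 1e-4)
  set.seed(13)
  for (i in 1:30) {
    r <- runif(20, 1.8, 7)
    reff <- noe_effective(r)
    expect_gte(reff, min(r))
    expect_lte(reff, mean(r))
    w <- runif(20, 0.1, 2)
    expect_equal(noe_effective(r, w),
                 (sum(w * r^-6) / sum(w))^(-1 / 6), tolerance = 1e-12)
  }
  expect_error(noe_effective(c(2, -1)), "domain")
})

test_that("ambiguous NOEs sum pair contributions before averaging", {
  # two identical pairs at constant r: closed form r * 2^(-1/6)
  r <- matrix(3, nrow = 5, ncol = 2)
  expect_equal(ambnoe_effective(r), 3 * 2^(-1 / 6), tolerance = 1e-12)
  # single-pair input reduces to the plain NOE average
  set.seed(14)
  x <- runif(8, 2, 6)
  expect_equal(ambnoe_effective(matrix(x, ncol = 1)), noe_effective(x),
               tolerance = 1e-12)
  # brute-force oracle on random input
  for (i in 1:20) {
    np <- sample(2:4, 1)
    D <- matrix(runif(6 * np, 2, 7), nrow = 6)
    w <- runif(6, 0.5, 2)
    acc <- 0
    for (fr in 1:6) {
      s <- 0
      for (p in 1:np) s <- s + D[fr, p]^-6
      acc <- acc + w[fr] * s
    }
    expect_equal(ambnoe_effective(D, w), (acc / sum(w))^(-1 / 6),
                 tolerance = 1e-12)
  }
})

test_that("total chi-square combines classes by observable counts", {
  # synthetic residual bookkeeping through a real ensemble
  ens <- generate_two_state_ensemble(0.7, 12, seed = 21)
  tab <- generate_nmr_dataset(ens$frames, noise = 0, seed = 22,
                              counts = c(backbone_3J = 6, sugar_3J = 4,
                                         NOE = 10, ambNOE = 3))
  rep0 <- chi2_total(tab, ens$frames)
  expect_equal(rep0$total_chi2, 0, tolerance = 1e-12)

  # single observable displaced by exactly one sigma
  tab1 <- tab
  tab1$exp_value[1] <- tab1$exp_value[1] + tab1$exp_error[1]
  rep1 <- chi2_total(tab1[1, ], ens$frames)
  expect_equal(rep1$total_chi2, 1, tolerance = 1e-10)

  # two classes with (n=3, chi2=2) and (n=1, chi2=6) -> weighted mean 3
  tab2 <- rbind(tab[tab$class == "backbone_3J", ][1:3, ],
                tab[tab$class == "NOE", ][1, ])
  tab2$exp_value[1:3] <- tab2$exp_value[1:3] + sqrt(2) * tab2$exp_error[1:3]
  tab2$exp_value[4] <- tab2$exp_value[4] + sqrt(6) * tab2$exp_error[4]
  rep2 <- chi2_total(tab2, ens$frames)
  expect_equal(rep2$total_chi2, 3, tolerance = 1e-8)

  # invariance under reordering of observables and frames, and under
  # frame replication
  perm <- sample(nrow(tab))
  expect_equal(chi2_total(tab[perm, ], ens$frames)$total_chi2,
               rep0$total_chi2, tolerance = 1e-12)
  expect_equal(chi2_total(tab1, rev(ens$frames))$total_chi2,
               chi2_total(tab1, ens$frames)$total_chi2, tolerance = 1e-12)
  expect_equal(chi2_total(tab1, ens$frames[rep(1:12, 3)])$total_chi2,
               chi2_total(tab1, ens$frames)$total_chi2, tolerance = 1e-10)

  # unresolvable atoms are skipped with a warning, not fatal
  tab3 <- tab
  tab3$atoms[2] <- "99:ZZ;1:C1';1:C2';1:C3'"
  expect_warning(rep3 <- chi2_total(tab3, ens$frames), "skipping")
  expect_identical(rep3$skipped, tab3$id[2])
})

test_that("observable table round-trips through TSV", {
  ens <- generate_two_state_ensemble(0.6, 5, seed = 30)
  tab <- generate_nmr_dataset(ens$frames, seed = 31,
                              counts = c(backbone_3J = 4, sugar_3J = 3,
                                         NOE = 6, ambNOE = 2))
  path <- tempfile(fileext = ".tsv")
  write_observable_table(tab, path)
  back <- read_observable_table(path)
  expect_equal(back$exp_value, tab$exp_value, tolerance = 1e-9)
  expect_identical(back$atoms, tab$atoms)
  expect_identical(back$class, tab$class)

  bad <- tab; bad$exp_error[1] <- 0
  expect_error(write_observable_table(bad, path), "exp_error")
  bad2 <- tab; bad2$class[1] <- "weird"
  expect_error(write_observable_table(bad2, path), "class")
})
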