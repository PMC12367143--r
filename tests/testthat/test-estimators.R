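test_that("Woolf-Hanes inverts noiseless MM data exactly", {
  s <- c(1, 2, 5, 10, 20)
  fit <- woolf_hanes_fit(data.frame(conc = s, v = 10 * s / (5 + s)))
  expect_true(fit$valid)
  expect_equal(fit$kcat, 10, tolerance = 1e-10)
  expect_equal(fit$Km, 5, tolerance = 1e-10)
  # the stated identities against the raw line coefficients
  expect_equal(fit$kcat, 1 / fit$slope, tolerance = 1e-12)
  expect_equal(fit$Km, fit$intercept / fit$slope, tolerance = 1e-12)
})

test_that("Woolf-Hanes is calibrated under 5% noise", {
  s <- c(1, 2, 5, 10, 20)
  v0 <- 10 * s / (5 + s)
  set.seed(1234)
  kcats <- kms <- covered <- numeric(100)
  for (i in 1:100) {
    fit <- woolf_hanes_fit(data.frame(conc = s,
                                      v = v0 * (1 + rnorm(5, 0, 0.05))))
    kcats[i] <- fit$kcat; kms[i] <- fit$Km
    covered[i] <- abs(fit$kcat - 10) <= 2 * fit$kcat_se
  }
  expect_lt(abs(median(kcats) / 10 - 1), 0.02)
  expect_lt(abs(median(kms) / 5 - 1), 0.05)
  # the Hanes transform leaves proportional velocity noise heteroscedastic,
  # so the unweighted-OLS delta-method se is anticonservative: Monte-Carlo
  # coverage of +/-2 se is ~0.64 under this noise model (2000-draw oracle),
  # not the nominal 0.95. Freeze that behaviour within binomial error.
  expect_gt(mean(covered), 0.64 - 3 * sqrt(0.64 * 0.36 / 100))
  expect_lt(mean(covered), 0.64 + 3 * sqrt(0.64 * 0.36 / 100))
})

test_that("degenerate Hanes inputs are flagged or rejected", {
  expect_error(woolf_hanes_fit(data.frame(conc = c(1, 2), v = c(1, 2))),
               "at least 3")
  # decreasing v with conc gives a non-positive intercept -> invalid
  bad <- woolf_hanes_fit(data.frame(conc = c(1, 5, 25), v = c(5, 3.2, 2)))
  expect_false(bad$valid)
  expect_match(bad$reason, "non-positive")
})

test_that("exponential fit recovers exact bounded growth", {
  tt <- seq(0, 0.5, length.out = 50)
  y <- 5 * (1 - exp(-14.9 * tt))
  fit <- fit_exponential(tt, y)
  expect_equal(fit$A, 5, tolerance = 1e-6)
  expect_equal(fit$B, 14.9, tolerance = 1e-6)
  expect_error(fit_exponential(tt, rep(0, 50)), "degenerate")
})

test_that("exponential fit matches the waiting-time rate of an SSA transfer", {
  # single-turnover subscheme with saturating binding: appearance of
  # charged tRNA is exponential at the transfer rate
  sub <- build_single_turnover_scheme()
  k <- 12
  rs <- rate_set(sub, k_f = c(trna_bind_ED = 50, tran = k, amp_rel = 100,
                              prod_rel = 10),
                 k_b = c(trna_bind_ED = 0.1, tran = 0, amp_rel = 0,
                         prod_rel = 0))
  cond <- assay_conditions(ATP = 0, AA = 0, tRNA = 5, enzyme_conc = 50,
                          copies_target = 2000, duration = 1,
                          n_samples = 200, start_state = "S5")
  Bs <- vapply(1:20, function(r) {
    traj <- simulate_ssa(sub, cond, rates = rs, seed = 400 + r)
    fit_exponential(traj$times, trajectory_product(traj))$B
  }, numeric(1))
  # binding at 2500/s barely shifts the rate; compare to the composite
  b_true <- 1 / (1 / (50 * 50) + 1 / k)
  expect_lt(abs(mean(Bs) - b_true), 3 * sd(Bs) / sqrt(20))
})

test_that("burst detection reads amplitudes off the late linear phase", {
  tt <- seq(0, 10, length.out = 400)
  withburst <- fake_product_traj(tt, 100 + 25 * tt, enzyme_copies = 100)
  b1 <- detect_burst(withburst)
  expect_equal(b1$amplitude, 100, tolerance = 1e-8)
  expect_true(b1$burst)
  expect_equal(b1$steady_rate, 0.25, tolerance = 1e-8)
  plain <- fake_product_traj(tt, 25 * tt, enzyme_copies = 100)
  b0 <- detect_burst(plain)
  expect_equal(b0$amplitude, 0, tolerance = 1e-8)
  expect_false(b0$burst)
  # a still-accelerating curve has no steady phase
  curved <- fake_product_traj(tt, tt^3, enzyme_copies = 100)
  expect_error(detect_burst(curved), "steady phase")
})
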