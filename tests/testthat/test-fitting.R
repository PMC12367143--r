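test_that("stage 1 recovers a known transfer rate", {
  tg <- fit_targets(k_tran = 15, tolerance = 0.15)
  s1 <- fit_stage_single_turnover("class1_monomer", tg, seed = 1)
  expect_true(s1$ok)
  expect_rel(s1$achieved$k_tran, 15, 0.10)
  expect_true(all(c("tran.kf", "tran.kb") %in% s1$fixed))
})

test_that("degenerate targets are rejected up front", {
  expect_error(fit_targets(k_tran = 0), "positive")
  expect_error(fit_targets(k_tran = 5, tolerance = 0), "tolerance")
  tg <- fit_targets(aa = list(kcat = 3))
  expect_error(fit_stage_single_turnover("class1_monomer", tg), "k_tran")
})

test_that("constraints are honoured bitwise through the stages", {
  con <- rate_constraint("trna_bind_ED", k_on = 0.7, k_off = 2.1)
  tg <- fit_targets(k_tran = 12)
  s1 <- fit_stage_single_turnover("class1_monomer", tg, constraints = con,
                                  seed = 2)
  rates <- aarskinetics:::.theta_to_rates(s1$theta, "class1_monomer")
  i <- match("trna_bind_ED", rates$step_id)
  expect_identical(rates$k_f[i], 0.7)
  # k_b rebuilt as k_on * (k_off/k_on): exact up to one float round trip
  expect_equal(rates$k_b[i], 2.1, tolerance = 1e-15)
})

test_that("parameters fixed at one stage are untouched afterwards", {
  tg <- fit_targets(pp = list(kcat = 60, Km_aa = 30, Km_atp = 300),
                    aa = list(kcat = 3, Km_trna = 1),
                    k_tran = 15, tolerance = 0.3)
  s1 <- fit_stage_single_turnover("class1_monomer", tg, seed = 3)
  s2 <- fit_stage_pp_exchange("class1_monomer", tg, stage1 = s1, seed = 4,
                              n_random = 10, polish_iters = 0,
                              refine_passes = 1)
  expect_identical(s1$theta[s1$fixed], s2$theta[s1$fixed])
  s3 <- fit_stage_aminoacylation("class1_monomer", tg, stage2 = s2,
                                 seed = 5, n_random = 10, polish_iters = 0,
                                 refine_passes = 1)
  expect_identical(s2$theta[s2$fixed], s3$theta[s2$fixed])
})

test_that("a vacuous tolerance accepts the first feasible rate set", {
  tg <- fit_targets(pp = list(kcat = 60, Km_aa = 30, Km_atp = 300),
                    k_tran = 15, tolerance = 1)
  s2 <- fit_stage_pp_exchange("class1_monomer", tg, seed = 6,
                              n_random = 5, polish_iters = 0,
                              refine_passes = 1)
  expect_true(s2$ok)
  rates <- aarskinetics:::.theta_to_rates(s2$theta, "class1_monomer")
  expect_true(all(rates$k_f >= 0 & is.finite(rates$k_f)))
})

test_that("full fits are deterministic in their seed and flag infeasibility", {
  tg <- fit_targets(aa = list(kcat = 3, Km_trna = 1), k_tran = 15,
                    tolerance = 0.3)
  f1 <- fit_enzyme("cysRS", tg, seed = 7, n_random = 6, polish_iters = 20,
                   refine_passes = 1)
  f2 <- fit_enzyme("cysRS", tg, seed = 7, n_random = 6, polish_iters = 20,
                   refine_passes = 1)
  expect_identical(f1$model$rates, f2$model$rates)
  bad <- fit_targets(aa = list(kcat = 1e4, Km_trna = 1e-6), k_tran = 15,
                     tolerance = 0.15)
  fb <- fit_enzyme("cysRS", bad, seed = 8, n_random = 4, polish_iters = 0,
                   refine_passes = 1)
  expect_false(fb$ok)
})

test_that("refitting a synthetic enzyme reproduces its observables", {
  gt <- make_synthetic_enzyme("class1_monomer", seed = 101)
  fit <- fit_enzyme("synthetic", gt$targets, seed = 9, n_random = 10,
                    polish_iters = 60, refine_passes = 1,
                    variant = "class1_monomer")
  tol <- 2 * gt$targets$tolerance
  expect_rel(fit$achieved[["aa_kcat"]], gt$observables$aa_kcat, tol)
  expect_rel(fit$achieved[["aa_Km_trna"]], gt$observables$aa_Km_trna, tol)
  expect_rel(fit$achieved[["k_tran"]], gt$observables$k_tran, tol)
})
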