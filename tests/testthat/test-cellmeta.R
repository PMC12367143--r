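trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

test_that("a single measurement gives a unit Gaussian consensus", {
  vd <- violin_density(5, sigma = 1)
  expect_equal(vd$peak, 5, tolerance = 1e-2)
  expect_equal(max(vd$density), stats::dnorm(0), tolerance = 1e-4)
  expect_equal(trapz(vd$grid, vd$density), 1, tolerance = 1e-3)
})

test_that("two-component mixtures peak where the analytic mixture does", {
  vd <- violin_density(c(4, 6), sigma = c(0.5, 0.5))
  f <- function(y) dnorm(y, 4, 0.5) + dnorm(y, 6, 0.5)
  yy <- seq(2, 8, length.out = 20000)
  expect_equal(min(abs(vd$peak - yy[which.max(f(yy))])), 0,
               tolerance = 2e-2)
  # symmetric: density at 4 equals density at 6
  d4 <- vd$density[which.min(abs(vd$grid - 4))]
  d6 <- vd$density[which.min(abs(vd$grid - 6))]
  expect_equal(d4, d6, tolerance = 1e-3)
})

test_that("consensus densities normalise for random measurement sets", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(1:12, 1)
    y <- runif(n, 1, 30)
    vd <- violin_density(y, sigma = runif(n, 0.2, 4))
    expect_equal(trapz(vd$grid, vd$density), 1, tolerance = 1e-3)
  }
  # defaulted 20% errors behave the same
  vd <- violin_density(c(3, 8, 9))
  expect_equal(trapz(vd$grid, vd$density), 1, tolerance = 1e-3)
})

test_that("turnover rates and unit conversions reproduce printed values", {
  expect_equal(conc_rate_to_per_cell(4.478, 1), 2696.6, tolerance = 2e-4)
  expect_equal(conc_rate_to_per_cell(4.508, 1), 2714.8, tolerance = 2e-4)
  expect_equal(conc_rate_to_per_cell(0, 1), 0)
  expect_equal(turnover_rate(2714.8, 1610), 1.68, tolerance = 1e-2)
  expect_equal(turnover_rate(2696.6, 606), 4.44, tolerance = 1e-2)
  expect_equal(turnover_rate(0, 10), 0)
  expect_error(turnover_rate(5, 0), "> 0")
})

test_that("transcriptome reconstruction hits the nucleotide target", {
  # hand-solvable: fractions 1/4 and 3/4 over equal lengths
  ts <- build_transcriptome(c(a = 100, b = 300), c(a = 1000, b = 1000),
                            total_nt = 4e6)
  expect_equal(unname(ts$copies), c(1000, 3000))
  expect_equal(sum(ts$fraction), 1)
  ts2 <- build_transcriptome(c(a = 200, b = 600), c(a = 1000, b = 1000),
                             total_nt = 4e6)
  expect_equal(ts2$copies, ts$copies)      # scale invariance
  expect_error(build_transcriptome(c(0, 0), c(10, 10), 100), "zero")
  set.seed(5)
  rpkm <- runif(40, 0, 50); len <- sample(300:3000, 40)
  ts3 <- build_transcriptome(rpkm, len, total_nt = 2e6)
  expect_lt(abs(ts3$achieved_nt - 2e6), max(len))
})

test_that("codon usage counts are copy-weighted and order-invariant", {
  ts <- build_transcriptome(c(x = 10, y = 10), c(x = 6, y = 9), 60)
  cu <- codon_usage(ts, c(x = "ATGAAA", y = "ATGCCCGGG"))
  expect_equal(unname(cu$counts["AAA"]), unname(ts$copies[["x"]]))
  expect_equal(unname(cu$counts["ATG"]),
               unname(ts$copies[["x"]] + ts$copies[["y"]]))
  expect_equal(sum(cu$fractions), 1)
  cu2 <- codon_usage(ts, c(y = "ATGCCCGGG", x = "ATGAAA"))
  expect_identical(cu$counts, cu2$counts)
  expect_error(codon_usage(ts, c(x = "ATGA", y = "ATGCCCGGG")), "multiple")
})

test_that("demand simulation conserves tRNA and respects capacity", {
  orc <- make_mm_oracle_fixture(10, 5)
  # zero demand: everything ends up charged
  r0 <- demand_charging_sim(orc, demand = 0, tRNA_total = 5,
                            enzyme_conc = 0.5, duration = 10, seed = 1,
                            copies_target = 100)
  expect_gt(r0$charged_fraction, 0.95)
  expect_true(r0$sustainable)
  # demand above kcat*E0 collapses the charged pool
  over <- demand_charging_sim(orc, demand = 5 * r0$capacity, tRNA_total = 5,
                              enzyme_conc = 0.5, duration = 10, seed = 2,
                              copies_target = 100)
  expect_false(over$sustainable)
  expect_lt(over$charged_fraction, 0.1)
})

test_that("steady free uncharged tRNA matches the MM balance point", {
  orc <- make_mm_oracle_fixture(10, 5)
  cond_copies <- 200
  r <- 0.4 * 10 * cond_copies    # demand at 40% of capacity, molecules/s
  rep <- demand_charging_sim(orc, demand = r, tRNA_total = 20,
                             enzyme_conc = 1, duration = 40, seed = 3,
                             copies_target = cond_copies)
  expect_true(rep$sustainable)
  tu_pred <- invert_mm_for_substrate(10, 5, r / cond_copies)
  expect_rel(rep$mean_free_uncharged_uM, tu_pred, 0.15)
})

test_that("tRNA moieties are conserved across all partitions in time", {
  orc <- make_mm_oracle_fixture(10, 5)
  cond <- assay_conditions(tRNA = 10, enzyme_conc = 1, copies_target = 100,
                          duration = 5, demand = 300)
  traj <- simulate_ssa(orc, cond, seed = 4)
  bound <- traj$states[, "S1"]
  total <- bound + traj$pools[, "R"] + traj$pools[, "Rs"]
  expect_true(all(total == total[1]))
})
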