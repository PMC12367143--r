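test_that("no enzyme means no reactions and zero product", {
  m <- hand_class1_model()
  cond <- assay_conditions(tRNA = 10, enzyme_conc = 0, duration = 1,
                          volume = 1e-15)
  traj <- simulate_ssa(m, cond, seed = 1)
  expect_equal(traj$enzyme_copies, 0)
  expect_true(all(trajectory_product(traj) == 0))
  expect_equal(as.numeric(initial_velocity(traj, "product")), 0)
})

test_that("a symmetric two-state switch occupies both states equally", {
  sc <- two_state_scheme()
  rs <- rate_set(sc, k_f = c(aa_bind_E = 5), k_b = c(aa_bind_E = 5))
  cond <- assay_conditions(AA = 1, ATP = 0, enzyme_conc = 0.01,
                          copies_target = 400, duration = 50,
                          n_samples = 1000)
  traj <- simulate_ssa(sc, cond, rates = rs, seed = 42)
  late <- traj$times > 2      # past relaxation (rate 10/s)
  occ <- mean(traj$states[late, "S1"]) / traj$enzyme_copies
  # binomial error of the time average, generously 5 sigma of a single draw
  expect_lt(abs(occ - 0.5), 5 * sqrt(0.25 / 400) / sqrt(length(late) / 50))
  expect_lt(abs(occ - 0.5), 0.02)
})

test_that("irreversible turnover with bath substrate is a Poisson flow", {
  # E + S -> E + P at rate k[S] per enzyme: binding is rate limiting
  m <- make_mm_oracle_fixture(kcat = 1000, Km = 1001, k_on = 1)
  conc <- 2  # uM bath
  cond <- assay_conditions(tRNA = conc, bath = c(R = TRUE),
                          enzyme_conc = 0.01, copies_target = 100,
                          duration = 5)
  rate_true <- 1000 * conc / (1001 + conc) * 100   # molecules/s, all copies
  counts <- vapply(1:10, function(r) {
    traj <- simulate_ssa(m, cond, seed = 100 + r)
    max(trajectory_product(traj))
  }, numeric(1))
  expect_lt(abs(mean(counts) - rate_true * 5),
            3 * sd(counts) / sqrt(length(counts)))
})

test_that("identical seeds give identical event sequences", {
  m <- hand_class1_model()
  cond <- assay_conditions(tRNA = 5, duration = 0.5)
  t1 <- simulate_ssa(m, cond, seed = 99)
  t2 <- simulate_ssa(m, cond, seed = 99)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$fire_f, t2$fire_f)
  expect_identical(t1$pools, t2$pools)
  t3 <- simulate_ssa(m, cond, seed = 100)
  expect_false(identical(t1$fire_f, t3$fire_f))
})

test_that("enzyme copies are conserved at every sample in every variant", {
  th <- hand_class1_theta()
  for (v in c("class1_monomer", "class1_tRNA_required", "class2_flipflop")) {
    rs <- aarskinetics:::.theta_to_rates(th, v)
    cond <- assay_conditions(tRNA = 5, duration = 0.5, copies_target = 150)
    traj <- simulate_ssa(build_scheme(v), cond, rates = rs, seed = 5)
    expect_true(all(rowSums(traj$states) == traj$enzyme_copies), label = v)
  }
  # and for the oracle mechanism with a discrete tRNA pool
  orc <- make_mm_oracle_fixture(10, 5)
  traj <- simulate_ssa(orc, assay_conditions(tRNA = 5, duration = 1), seed = 6)
  expect_true(all(rowSums(traj$states) == traj$enzyme_copies))
})

test_that("mean-field ODE conserves enzyme and holds baths fixed", {
  m <- hand_class1_model()
  cond <- assay_conditions(tRNA = 10, duration = 2)
  traj <- simulate_ode(m, cond)
  expect_equal(rowSums(traj$states) / traj$enzyme_copies,
               rep(1, length(traj$times)), tolerance = 1e-6)
  # bath species (columns A, T, P, M) never change
  expect_true(all(traj$pools[, c("A", "T", "P", "M")] == 0))
})

test_that("SSA ensemble mean matches the ODE at large copy number", {
  m <- hand_class1_model()
  cond <- assay_conditions(tRNA = 10, enzyme_conc = 0.01,
                          copies_target = 1000, duration = 2)
  ode <- simulate_ode(m, cond)
  p_ode <- trajectory_product(ode)
  p_ssa <- rowMeans(vapply(1:10, function(r)
    trajectory_product(simulate_ssa(m, cond, seed = 200 + r)),
    numeric(length(p_ode))))
  sel <- p_ode > 50           # skip the near-zero start-up samples
  expect_lt(max(abs(p_ssa[sel] - p_ode[sel]) / p_ode[sel]), 0.05)
})

test_that("initial velocity recovers exact slopes and flags silence", {
  tt <- seq(0, 10, length.out = 201)
  traj <- fake_product_traj(tt, 30 * tt, enzyme_copies = 10)
  v <- initial_velocity(traj, "product", window_frac = 1)
  expect_equal(as.numeric(v), 3, tolerance = 1e-10)
  expect_false(attr(v, "low_confidence"))
  silent <- fake_product_traj(tt, rep(0, length(tt)), enzyme_copies = 10)
  v0 <- initial_velocity(silent, "product")
  expect_equal(as.numeric(v0), 0)
  expect_true(attr(v0, "low_confidence"))
})

test_that("exchange velocity matches the ODE reverse-activation flux", {
  m <- hand_class1_model()
  pp <- build_pp_exchange_scheme()
  rates <- m$rates[match(pp$steps$id, m$rates$step_id), ]
  conc <- aarskinetics:::.assay_conc("pp_exchange")
  v_ode <- aarskinetics:::.steady_velocity(pp, rates, conc, "pp_exchange")
  cond <- assay_conditions(PPi = 2000, duration = 2, copies_target = 400)
  vs <- vapply(1:5, function(r) {
    traj <- simulate_ssa(pp, cond, rates = rates, seed = 300 + r)
    as.numeric(initial_velocity(traj, "pp_exchange"))
  }, numeric(1))
  expect_lt(abs(mean(vs) - v_ode), 4 * sd(vs) / sqrt(5) + 0.02 * v_ode)
})
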