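test_that("scheme variants have the expected state and parameter counts", {
  sc1 <- build_scheme("class1_monomer")
  expect_length(sc1$states, 16)
  expect_identical(names(sc1$states), paste0("S", 0:15))
  expect_equal(n_parameters(sc1), 48)
  expect_equal(n_parameters(build_pp_exchange_scheme()), 12)
  expect_equal(n_parameters(build_single_turnover_scheme()), 8)
  expect_length(build_pp_exchange_scheme()$states, 6)
  sc2 <- build_scheme("class2_flipflop")
  expect_length(sc2$states, 20)
  expect_equal(sc2$site_count, 2L)
})

test_that("tRNA-required variant forms no adenylate from tRNA-free states", {
  sc <- build_scheme("class1_tRNA_required", tRNA_required = TRUE)
  is_act_step <- function(sp, states) {
    vapply(seq_len(nrow(sp)), function(i) {
      d <- aarskinetics:::.multiset_diff(
        aarskinetics:::.comp_all(states[[sp$to[i]]]),
        aarskinetics:::.comp_all(states[[sp$from[i]]]))
      setequal(d$plus, c("D", "P")) && setequal(d$minus, c("A", "T"))
    }, logical(1))
  }
  act <- sc$steps[is_act_step(sc$steps, sc$states), ]
  from_has_trna <- vapply(act$from, function(lab)
    any(aarskinetics:::.comp_all(sc$states[[lab]]) %in% c("R", "Rs")),
    logical(1))
  expect_true(all(from_has_trna))
})

test_that("every state is reachable from S0 in every variant", {
  for (v in aarskinetics:::SCHEME_VARIANTS) {
    sc <- build_scheme(v)
    expect_setequal(reachable_states(sc, "S0"), names(sc$states))
  }
})

test_that("dual PPi-release and ATP-before-release paths are present", {
  sc <- build_scheme("class1_monomer")
  edges <- paste(sc$steps$from, sc$steps$to)
  expect_true(all(c("S10 S11", "S11 S13", "S10 S12", "S12 S13") %in% edges))
  expect_true(all(c("S14 S15") %in% edges))          # ATP binds product state
  expect_true("S15 S2" %in% edges)                   # release with ATP bound
})

test_that("invalid variant combinations are rejected", {
  expect_error(build_scheme("nonsense"))
  expect_error(build_scheme("class2_flipflop", tRNA_required = TRUE),
               "class I")
})

test_that("chemical moieties balance across every step (so along any cycle)", {
  moieties <- list(
    amino_acid = c(A = 1, D = 1, Rs = 1),
    trna       = c(R = 1, Rs = 1),
    adenosine  = c(T = 1, D = 1, M = 1),
    phosphate  = c(T = 3, D = 1, M = 1, P = 2)
  )
  count <- function(lig, w) sum(w[lig], na.rm = TRUE)
  for (v in aarskinetics:::SCHEME_VARIANTS) {
    sc <- build_scheme(v)
    for (i in seq_len(nrow(sc$steps))) {
      from <- aarskinetics:::.comp_all(sc$states[[sc$steps$from[i]]])
      to <- aarskinetics:::.comp_all(sc$states[[sc$steps$to[i]]])
      for (m in names(moieties)) {
        w <- moieties[[m]]
        lhs <- count(from, w) + count(sc$steps$consume[i], w)
        rhs <- count(to, w) + count(sc$steps$release[i], w)
        expect_equal(lhs, rhs,
                     label = sprintf("%s moiety at step %s (%s)", m,
                                     sc$steps$id[i], v))
      }
    }
  }
})

test_that("assay subschemes are induced subgraphs of the class I scheme", {
  full <- build_scheme("class1_monomer")
  for (sub in list(build_pp_exchange_scheme(),
                   build_single_turnover_scheme())) {
    for (i in seq_len(nrow(sub$steps))) {
      j <- match(sub$steps$id[i], full$steps$id)
      expect_false(is.na(j))
      expect_identical(sub$steps$from[i], full$steps$from[j])
      expect_identical(sub$steps$to[i], full$steps$to[j])
    }
    for (lab in names(sub$states))
      expect_identical(sub$states[[lab]], full$states[[lab]])
  }
  # the exchange subscheme is exactly the tRNA-free part
  pp <- build_pp_exchange_scheme()
  trna_free <- names(Filter(function(cp)
    !any(aarskinetics:::.comp_all(cp) %in% c("R", "Rs")), full$states))
  expect_setequal(names(pp$states), trna_free)
})

test_that("dissociation constants follow K_d = k_b/k_f", {
  sc <- build_pp_exchange_scheme()
  rs <- rate_set(sc, k_f = c(aa_bind_E = 0.024), k_b = c(aa_bind_E = 3.2))
  expect_equal(dissociation_constant(rs, "aa_bind_E"), 3.2 / 0.024,
               tolerance = 1e-12)
  expect_equal(round(dissociation_constant(rs, "aa_bind_E"), 1), 133.3)
  rs0 <- rate_set(sc, k_f = c(atp_bind_E = 2), k_b = c(atp_bind_E = 0))
  expect_equal(dissociation_constant(rs0, "atp_bind_E"), 0)
  set.seed(7)
  kf <- runif(6, 0.1, 10); kb <- runif(6, 0.1, 10)
  rs2 <- rate_set(sc, kf, kb)
  kd <- dissociation_constant(rs2, rs2$step_id)
  expect_equal(kd * rs2$k_f, rs2$k_b, tolerance = 1e-12)
  rsz <- rate_set(sc, k_f = c(aa_bind_E = 0), k_b = c(aa_bind_E = 1))
  expect_error(dissociation_constant(rsz, "aa_bind_E"), "zero")
})

test_that("step molecularity matches pool stoichiometry", {
  sc <- build_scheme("class1_monomer")
  mol <- step_molecularity(sc)
  expect_identical(mol$units[mol$id == "aa_bind_E"], "bi/uni")
  expect_identical(mol$units[mol$id == "ppi_rel"], "uni/bi")
  expect_identical(mol$units[mol$id == "act"], "uni/uni")
  el <- scheme_edge_list(sc)
  expect_identical(nrow(el), nrow(sc$steps))
  expect_true(all(c("from_state", "to_state", "step_id") %in% names(el)))
})
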