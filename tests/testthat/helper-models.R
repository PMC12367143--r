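# shared fixtures built in code

# a hand-parameterised class I model with release-limited turnover:
# fast activation, transfer ~15/s, slow product release
hand_class1_theta <- function() {
  th <- aarskinetics:::.default_theta("class1_monomer")
  th[c("aa.Kd", "atp.Kd", "act.kf", "act.kb", "ppi.kf",
       "trna.kon", "trna.Kd", "trna_D.kon", "trna_D.Kd",
       "tran.kf", "tranP.kf", "amp.kf", "rel.kf")] <-
    c(135, 1395, 425, 212.5, 100, 3, 1, 3, 1, 15, 15, 50, 4)
  th
}

hand_class1_model <- function() {
  enzyme_model("cysRS",
               aarskinetics:::.theta_to_rates(hand_class1_theta(),
                                              "class1_monomer"))
}

# minimal custom scheme: reversible ligand binding only (two enzyme states)
two_state_scheme <- function() {
  sc <- structure(list(
    variant = "pp_exchange",
    states = list(S0 = aarskinetics:::.comp(),
                  S1 = aarskinetics:::.comp("A")),
    steps = aarskinetics:::.step("aa_bind_E", "S0", "S1", consume = "A"),
    site_count = 1L, tRNA_required = FALSE), class = "aars_scheme")
  validate_scheme(sc)
  sc
}

# fabricate a trajectory object around an explicit product curve
fake_product_traj <- function(times, product, enzyme_copies = 100,
                              sites = 1) {
  scheme <- build_single_turnover_scheme()
  fire_f <- matrix(0, length(times), nrow(scheme$steps),
                   dimnames = list(NULL, scheme$steps$id))
  fire_f[, "tran"] <- product
  structure(list(times = times, states = NULL,
                 pools = matrix(0, length(times), 6,
                                dimnames = list(NULL, aarskinetics:::POOL_SPECIES)),
                 fire_f = fire_f,
                 fire_b = fire_f * 0,
                 drain = numeric(length(times)),
                 enzyme_copies = enzyme_copies, conv = 1, scheme = scheme,
                 conditions = assay_conditions(),
                 exhausted = FALSE, stochastic = FALSE),
            class = "aars_trajectory")
}

expect_rel <- function(object, expected, tol) {
  expect_true(abs(object / expected - 1) <= tol,
              label = sprintf("%.6g vs %.6g (rel err %.3g > %.3g)",
                              object, expected, abs(object / expected - 1),
                              tol))
}
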