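# Staged identification of kinetic parameters. The observables an enzyme
# model must reproduce (pyrophosphate-exchange kcat/Km, single-turnover
# transfer rate, aminoacylation kcat/Km, burst phenotype) each depend on a
# subscheme of the full reaction graph, so fitting proceeds in three stages
# of growing scope: single turnover (transfer subscheme), pyrophosphate
# exchange (tRNA-free subscheme), then the full aminoacylation cycle.
# Parameters fixed at one stage are never revisited.
#
# The search works on a reduced "tied" parameterisation: rates with and
# without tRNA bound are identical by default (adenylate formation in
# particular), binding steps for the same ligand share k_on/K_d, and
# parameters with little effect on kcat/Km are pinned to experimental
# dissociation constants (k_on = 1 uM^-1 s^-1 unless constrained).

# tied components -> the scheme steps they parameterise.
# Each component is (kon, Kd) for binding groups or (kf, kb) for others.
.tie_table <- function(variant) {
  t1 <- list(
    aa      = list(steps = c("aa_bind_E", "aa_bind_ET"), kind = "bind"),
    aa_R    = list(steps = c("aa_bind_ER", "aa_bind_ETR"), kind = "bind"),
    atp     = list(steps = c("atp_bind_E", "atp_bind_EA"), kind = "bind"),
    atp_R   = list(steps = c("atp_bind_ER", "atp_bind_EAR"), kind = "bind"),
    trna    = list(steps = c("trna_bind_E", "trna_bind_EA", "trna_bind_ET",
                             "trna_bind_EAT"), kind = "bind"),
    trna_D  = list(steps = "trna_bind_ED", kind = "bind"),
    act     = list(steps = c("act", "act_trna"), kind = "rate"),
    ppi     = list(steps = c("ppi_rel", "ppi_rel_pre", "ppi_rel_post"),
                   kind = "rate"),
    tran    = list(steps = "tran", kind = "rate"),
    tranP   = list(steps = "tran_ppi", kind = "rate"),
    amp     = list(steps = "amp_rel", kind = "rate")
  )
  if (variant %in% c("class1_monomer", "class1_tRNA_required")) {
    t1$atp_Rs <- list(steps = "atp_bind_ERs", kind = "bind")
    t1$rel <- list(steps = c("prod_rel", "prod_rel_atp"), kind = "rate")
  } else if (variant == "class2_flipflop") {
    # site-2 binding happens with charged tRNA still held in site 1, so it
    # shares the tRNA-bound binding components
    t1$aa_R $steps <- c(t1$aa_R$steps, "aa_bind_s2", "aa_bind_s2b")
    t1$atp_R$steps <- c(t1$atp_R$steps, "atp_bind_s2", "atp_bind_s2b")
    t1$act  $steps <- c(t1$act$steps, "act_s2")
    t1$ppi  $steps <- c(t1$ppi$steps, "ppi_rel_s2")
    t1$rel <- list(steps = c("prod_rel_flip", "prod_rel_flip_pp"),
                   kind = "rate")
  }
  if (variant == "class1_tRNA_required")
    t1$act$steps <- "act_trna"
  t1
}

# theta: named vector over component parameters <comp>.kon/.Kd or
# <comp>.kf/.kb
.default_theta <- function(variant) {
  th <- c(aa.kon = 1, aa.Kd = 100, aa_R.kon = 1, aa_R.Kd = 100,
          atp.kon = 1, atp.Kd = 300, atp_R.kon = 1, atp_R.Kd = 300,
          trna.kon = 1, trna.Kd = 1, trna_D.kon = 1, trna_D.Kd = 1,
          act.kf = 200, act.kb = 100,
          ppi.kf = 100, ppi.kb = 0.05,
          tran.kf = 20, tran.kb = 0.01,
          tranP.kf = 20, tranP.kb = 0.01,
          amp.kf = 100, amp.kb = 1e-4,
          rel.kf = 10, rel.kb = 1e-4)
  if (variant %in% c("class1_monomer", "class1_tRNA_required"))
    th <- c(th, atp_Rs.kon = 1, atp_Rs.Kd = 300)
  th
}

.theta_to_rates <- function(theta, variant) {
  scheme <- build_scheme(variant)
  ties <- .tie_table(variant)
  kf <- kb <- numeric(0)
  for (comp in names(ties)) {
    steps <- intersect(ties[[comp]]$steps, scheme$steps$id)
    if (!length(steps)) next
    if (ties[[comp]]$kind == "bind") {
      kon <- theta[[paste0(comp, ".kon")]]
      kd <- theta[[paste0(comp, ".Kd")]]
      kf[steps] <- kon; kb[steps] <- kon * kd
    } else {
      kf[steps] <- theta[[paste0(comp, ".kf")]]
      kb[steps] <- theta[[paste0(comp, ".kb")]]
    }
  }
  rate_set(scheme, kf, kb)
}

#' Fitting targets for an enzyme model
#'
#' @param pp named list/vector with any of `kcat`, `Km_aa`, `Km_atp`
#'   (pyrophosphate exchange).
#' @param aa named list/vector with any of `kcat`, `Km_aa`, `Km_trna`,
#'   `Km_atp` (aminoacylation).
#' @param k_tran,k_chem single-turnover targets (s^-1); `k_chem` optional.
#' @param burst `TRUE`, `FALSE`, or `NA` (ignore).
#' @param tolerance relative tolerance per observable, in (0, 1].
#' @return a `fit_targets` list.
#' @export
fit_targets <- function(pp = NULL, aa = NULL, k_tran = NULL, k_chem = NULL,
                        burst = NA, tolerance = 0.15) {
  chk <- function(x) {
    if (!is.null(x) && any(unlist(x) <= 0)) stop("targets must be positive")
    x
  }
  if (!(tolerance > 0 && tolerance <= 1))
    stop("tolerance must be in (0, 1]")
  structure(list(pp = chk(pp), aa = chk(aa), k_tran = chk(k_tran),
                 k_chem = chk(k_chem), burst = burst,
                 tolerance = tolerance),
            class = "fit_targets")
}

#' Experimental constraints on kinetic parameters
#'
#' Pins a step's dissociation constant and/or association rate to a measured
#' value; constrained quantities are excluded from all search stages.
#'
#' @param step_id scheme step the measurement refers to (any member of a
#'   tied group pins the whole group).
#' @param K_d dissociation constant (uM).
#' @param k_on association rate (uM^-1 s^-1).
#' @param k_off dissociation rate (s^-1); with `k_on` implies
#'   `K_d = k_off/k_on`.
#' @return a one-row constraint data frame; concatenate with `rbind`.
#' @export
rate_constraint <- function(step_id, K_d = NA, k_on = NA, k_off = NA) {
  if (!is.na(k_on) && !is.na(k_off) && is.na(K_d)) K_d <- k_off / k_on
  if (all(is.na(c(K_d, k_on))))
    stop("a constraint needs K_d and/or k_on (or k_on + k_off)")
  if (any(c(K_d, k_on, k_off) <= 0, na.rm = TRUE))
    stop("constraint values must be positive")
  data.frame(step_id = step_id, K_d = K_d, k_on = k_on, k_off = k_off)
}

# map step-level constraints onto theta components; returns pinned names
.apply_constraints <- function(theta, constraints, variant) {
  pinned <- character(0)
  if (is.null(constraints) || !nrow(constraints))
    return(list(theta = theta, pinned = pinned))
  ties <- .tie_table(variant)
  for (i in seq_len(nrow(constraints))) {
    sid <- constraints$step_id[i]
    comp <- names(ties)[vapply(ties, function(x) sid %in% x$steps,
                               logical(1))]
    if (!length(comp)) stop("constraint on unknown step: ", sid)
    comp <- comp[1]
    if (ties[[comp]]$kind != "bind")
      stop("constraints apply to binding steps; ", sid, " is not one")
    if (!is.na(constraints$k_on[i])) {
      theta[[paste0(comp, ".kon")]] <- constraints$k_on[i]
      pinned <- c(pinned, paste0(comp, ".kon"))
    }
    if (!is.na(constraints$K_d[i])) {
      theta[[paste0(comp, ".Kd")]] <- constraints$K_d[i]
      pinned <- c(pinned, paste0(comp, ".Kd"))
    }
  }
  list(theta = theta, pinned = unique(pinned))
}

# log-space search: best of theta0 + n_random log-uniform draws, then
# coordinate golden-section refinement
.log_search <- function(loss, theta, dims, lower, upper, n_random = 60,
                        refine_passes = 2, seed = 1, polish_iters = 300) {
  set.seed(seed)
  eval_at <- function(vals) {
    th <- theta; th[dims] <- vals
    loss(th)
  }
  best_v <- theta[dims]
  best_l <- eval_at(best_v)
  trace <- best_l
  if (length(dims)) {
    for (r in seq_len(n_random)) {
      cand <- exp(stats::runif(length(dims), log(lower), log(upper)))
      l <- eval_at(cand)
      trace <- c(trace, l)
      if (l < best_l) { best_l <- l; best_v <- cand }
    }
    gr <- (sqrt(5) - 1) / 2
    for (pass in seq_len(refine_passes)) {
      for (j in seq_along(dims)) {
        a <- log(max(lower[j], best_v[j] / 30))
        b <- log(min(upper[j], best_v[j] * 30))
        x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
        f <- function(lx) { v <- best_v; v[j] <- exp(lx); eval_at(v) }
        f1 <- f(x1); f2 <- f(x2)
        for (it in 1:12) {
          if (f1 < f2) { b <- x2; x2 <- x1; f2 <- f1
                         x1 <- b - gr * (b - a); f1 <- f(x1) }
          else { a <- x1; x1 <- x2; f1 <- f2
                 x2 <- a + gr * (b - a); f2 <- f(x2) }
        }
        lx <- if (f1 < f2) x1 else x2
        lv <- min(f1, f2)
        if (lv < best_l) { best_l <- lv; best_v[j] <- exp(lx) }
        trace <- c(trace, best_l)
      }
    }
    if (length(dims) > 1 && polish_iters > 0) {
      # simplex polish on the log scale (box-clamped)
      for (round in 1:2) {
        po <- stats::optim(log(best_v), function(lv)
          eval_at(pmin(pmax(exp(lv), lower), upper)),
          method = "Nelder-Mead",
          control = list(maxit = polish_iters, reltol = 1e-9))
        if (po$value < best_l) {
          best_l <- po$value
          best_v <- pmin(pmax(exp(po$par), lower), upper)
        }
        trace <- c(trace, best_l)
        if (best_l < 1e-6) break
      }
    }
  }
  theta[dims] <- best_v
  list(theta = theta, loss = best_l, trace = trace)
}

.log_ratio_loss <- function(pred, target) {
  if (is.null(target) || !length(target)) return(0)
  s <- 0
  for (nm in names(target)) {
    p <- pred[[nm]]
    if (is.null(p) || !is.finite(p) || p <= 0) return(1e6)
    s <- s + log(p / target[[nm]])^2
  }
  s
}

.within_tol <- function(pred, target, tol) {
  if (is.null(target)) return(TRUE)
  all(vapply(names(target), function(nm) {
    p <- pred[[nm]]
    is.finite(p) && abs(p / target[[nm]] - 1) <= tol
  }, logical(1)))
}

# ---- stage 1: single turnover ---------------------------------------------

.st_ktran <- function(theta, variant) {
  rates <- .theta_to_rates(theta, variant)
  m <- enzyme_model("fit", rates, variant = variant)
  fit <- tryCatch(run_single_turnover(m, "transfer", method = "ode",
                                      duration = max(0.2, 8 / theta[["tran.kf"]])),
                  error = function(e) NULL)
  if (is.null(fit)) NA_real_ else fit$B
}

#' Stage 1: fit the single-turnover transfer observable
#'
#' Adjusts the transfer rate (and, if unconstrained, the tRNA-to-adenylate
#' binding) so that the simulated single-turnover assay reproduces the target
#' k_tran. The AMP-release and product-release steps belong to the
#' single-turnover subscheme but do not affect the charged-tRNA curve
#' (charging is counted at the chemistry); they keep provisional defaults and
#' remain free for stage 3.
#'
#' @param variant scheme variant (or an `aars_scheme`).
#' @param targets a [fit_targets()] with `k_tran` set.
#' @param constraints optional [rate_constraint()] rows.
#' @param seed integer search seed.
#' @param theta optional starting parameter vector (advanced).
#' @return a `fit_stage` list: `theta`, `fixed` (component parameters now
#'   frozen), `achieved`, `ok`.
#' @export
fit_stage_single_turnover <- function(variant, targets, constraints = NULL,
                                      seed = 1, theta = NULL) {
  if (inherits(variant, "aars_scheme")) variant <- variant$variant
  if (is.null(targets$k_tran) || targets$k_tran <= 0)
    stop("stage 1 requires a positive k_tran target")
  if (is.null(theta)) theta <- .default_theta(variant)
  ac <- .apply_constraints(theta, constraints, variant)
  theta <- ac$theta
  # at [E:Ad] = 50 uM the observed B is insensitive to the tRNA association
  # rate once binding outpaces transfer, so the curve identifies only the
  # transfer rate. Unconstrained, the association rate is set in that
  # insensitive regime, scaled to the capture efficiency (kcat/Km_trna) the
  # aminoacylation targets will demand of the adenylate state.
  if (!"trna_D.kon" %in% ac$pinned) {
    kon_D <- if (!is.null(targets$aa$kcat) && !is.null(targets$aa$Km_trna))
      3 * targets$aa$kcat / targets$aa$Km_trna else targets$k_tran / 5
    theta[["trna_D.kon"]] <- min(30, max(1, kon_D))
  }
  dims <- setdiff("tran.kf", ac$pinned)
  res <- .log_search(function(th) {
    b <- .st_ktran(th, variant)
    if (!is.finite(b)) 1e6 else log(b / targets$k_tran)^2
  }, theta, dims, lower = rep(1e-2, length(dims)),
     upper = rep(1e4, length(dims)), n_random = 25, refine_passes = 2,
     seed = seed)
  achieved <- .st_ktran(res$theta, variant)
  # the PPi-retaining transfer route is invisible to this assay (the
  # subscheme starts from the PPi-free adenylate); it defaults to the
  # measured transfer rate and stays free for stage 3
  res$theta[["tranP.kf"]] <- res$theta[["tran.kf"]]
  res$theta[["tranP.kb"]] <- res$theta[["tran.kb"]]
  fixed <- unique(c(ac$pinned, "tran.kf", "tran.kb", "trna_D.kon"))
  ok <- is.finite(achieved) &&
    abs(achieved / targets$k_tran - 1) <= targets$tolerance
  structure(list(theta = res$theta, fixed = fixed,
                 achieved = list(k_tran = achieved), ok = ok,
                 loss_trace = res$trace, stage = "single_turnover"),
            class = "fit_stage")
}

# ---- stage 2: pyrophosphate exchange --------------------------------------

.pp_obs <- function(theta, variant, grid_aa = NULL, grid_atp = NULL) {
  rates <- .theta_to_rates(theta, variant)
  sub <- build_pp_exchange_scheme()
  r <- rates[match(sub$steps$id, rates$step_id), ]
  if (any(is.na(r$step_id))) return(NULL)
  aa <- .steady_km(sub, r, "pp_exchange", "AA", grid = grid_aa)
  at <- .steady_km(sub, r, "pp_exchange", "ATP", grid = grid_atp)
  list(kcat = aa$kcat, Km_aa = aa$Km, Km_atp = at$Km)
}

#' Stage 2: fit the pyrophosphate-exchange observables
#'
#' Search dimensions are the parameters the exchange kcat/Km are sensitive
#' to: the amino-acid and ATP dissociation constants, the activation forward
#' and backward rates, and the pyrophosphate release rate. Parameters fixed
#' by stage 1 or by constraints are untouched; insensitive parameters keep
#' their experimental-default values.
#'
#' @param variant scheme variant (or scheme).
#' @param targets [fit_targets()] with `pp` containing `kcat` and at least
#'   one Km.
#' @param constraints optional constraint rows.
#' @param stage1 the `fit_stage` result of stage 1 (or `NULL`).
#' @param seed integer search seed.
#' @param n_random random-search budget.
#' @param polish_iters simplex-polish iteration budget (0 disables).
#' @param refine_passes coordinate-refinement passes.
#' @return a `fit_stage` list.
#' @export
fit_stage_pp_exchange <- function(variant, targets, constraints = NULL,
                                  stage1 = NULL, seed = 1, n_random = 80,
                                  polish_iters = 300, refine_passes = 2) {
  if (inherits(variant, "aars_scheme")) variant <- variant$variant
  if (variant == "class1_tRNA_required")
    stop("tRNA-required enzymes have no tRNA-free exchange subscheme")
  if (is.null(targets$pp) || is.null(targets$pp$kcat) ||
      !any(c("Km_aa", "Km_atp") %in% names(targets$pp)))
    stop("stage 2 requires pp kcat and at least one pp Km target")
  theta <- if (!is.null(stage1)) stage1$theta else .default_theta(variant)
  fixed <- if (!is.null(stage1)) stage1$fixed else character(0)
  ac <- .apply_constraints(theta, constraints, variant)
  theta <- ac$theta
  fixed <- unique(c(fixed, ac$pinned))
  dims <- setdiff(c("aa.Kd", "aa.kon", "atp.Kd", "act.kf", "act.kb",
                    "ppi.kf"), fixed)
  lower <- c(aa.Kd = 1, aa.kon = 0.05, atp.Kd = 10, act.kf = 1, act.kb = 0.1,
             ppi.kf = 1)[dims]
  upper <- c(aa.Kd = 1e4, aa.kon = 50, atp.Kd = 1e5, act.kf = 1e4,
             act.kb = 1e4, ppi.kf = 1e4)[dims]
  # the exchange observables leave (activation, PPi release) speeds
  # degenerate: only their equilibrium combination is pinned. The composite
  # chemistry rate k_chem ~ k_tran says the steps upstream of transfer are
  # fast, so solutions with slow activation or slow PPi release are
  # penalised relative to that reference.
  ref <- targets$k_chem %||% targets$k_tran
  # Woolf-Hanes grids centred on the target Kms (pilot runs otherwise)
  g5 <- c(0.2, 0.5, 1, 2, 5)
  grid_aa <- if (!is.null(targets$pp$Km_aa)) g5 * targets$pp$Km_aa
  grid_atp <- if (!is.null(targets$pp$Km_atp)) g5 * targets$pp$Km_atp
  # analytic warm start: with b = k_PPi_rel/(k_PPi_bind [PP]) and
  # a = act.kf/act.kb, the saturated exchange speed is act.kf/(1+a+ab) and
  # the apparent Kms are the dissociation constants scaled down by the same
  # factor
  kcat_t <- targets$pp$kcat
  if (!is.null(kcat_t) && !"ppi.kf" %in% fixed)
    theta[["ppi.kf"]] <- max(100, if (!is.null(ref)) 5 * ref else 0)
  if (!is.null(kcat_t)) {
    b <- theta[["ppi.kf"]] / (theta[["ppi.kb"]] * 2000)
    a <- 2
    cfac <- 1 + a + a * b
    if (!"act.kf" %in% fixed) theta[["act.kf"]] <- kcat_t * cfac / 0.8
    if (!"act.kb" %in% fixed) theta[["act.kb"]] <- theta[["act.kf"]] / a
    if (!is.null(targets$pp$Km_aa) && !"aa.Kd" %in% fixed)
      theta[["aa.Kd"]] <- targets$pp$Km_aa * cfac
    if (!is.null(targets$pp$Km_atp) && !"atp.Kd" %in% fixed)
      theta[["atp.Kd"]] <- targets$pp$Km_atp * cfac
  }
  res <- .log_search(function(th) {
    ob <- .pp_obs(th, variant, grid_aa, grid_atp)
    if (is.null(ob)) return(1e6)
    l <- .log_ratio_loss(ob, targets$pp)
    if (!is.null(ref))
      l <- l + 0.25 * (max(0, log(5 * ref / th[["act.kf"]]))^2 +
                       max(0, log(5 * ref / th[["ppi.kf"]]))^2)
    l
  }, theta, dims, lower, upper, n_random = n_random, seed = seed,
     polish_iters = polish_iters, refine_passes = refine_passes)
  achieved <- .pp_obs(res$theta, variant, grid_aa, grid_atp)
  fixed <- unique(c(fixed, c("aa.Kd", "aa.kon", "atp.Kd", "atp.kon",
                             "act.kf", "act.kb", "ppi.kf", "ppi.kb")))
  ok <- .within_tol(achieved, targets$pp, targets$tolerance)
  structure(list(theta = res$theta, fixed = fixed, achieved = achieved,
                 ok = ok, loss_trace = res$trace, stage = "pp_exchange"),
            class = "fit_stage")
}

# ---- stage 3: aminoacylation ----------------------------------------------

.aa_obs <- function(theta, variant, with_burst = FALSE,
                    grid_trna = NULL, grid_aa = NULL) {
  rates <- .theta_to_rates(theta, variant)
  m <- enzyme_model("fit", rates, variant = variant)
  tr <- .steady_km(m$scheme, rates, "aminoacylation", "tRNA",
                   grid = grid_trna)
  am <- .steady_km(m$scheme, rates, "aminoacylation", "AA", grid = grid_aa)
  out <- list(kcat = tr$kcat, Km_trna = tr$Km, Km_aa = am$Km)
  if (with_burst)
    out$burst_aps <- .burst_aps_ode(m$scheme, rates, m$scheme$site_count)
  out
}

#' Stage 3: fit the aminoacylation observables
#'
#' Completes the rate set: searches the tRNA dissociation constant, the
#' AMP-release and product-release rates, and the amino-acid affinity of the
#' tRNA-bound states, so the full-cycle assay reproduces the aminoacylation
#' kcat/Km (and the burst expectation, as a penalty at the 0.5/site
#' threshold). Parameters fixed in stages 1-2 are not revisited.
#'
#' @inheritParams fit_stage_pp_exchange
#' @param stage2 the `fit_stage` result of stage 2 (or stage 1, or `NULL`).
#' @return a `fit_stage` list whose `theta` expands to the complete rate set
#'   via the tied parameterisation.
#' @export
fit_stage_aminoacylation <- function(variant, targets, constraints = NULL,
                                     stage2 = NULL, seed = 1,
                                     n_random = 80, polish_iters = 300,
                                     refine_passes = 2) {
  if (inherits(variant, "aars_scheme")) variant <- variant$variant
  if (is.null(targets$aa)) stop("stage 3 requires aminoacylation targets")
  theta <- if (!is.null(stage2)) stage2$theta else .default_theta(variant)
  fixed <- if (!is.null(stage2)) stage2$fixed else character(0)
  ac <- .apply_constraints(theta, constraints, variant)
  theta <- ac$theta
  fixed <- unique(c(fixed, ac$pinned))
  # the amino-acid affinity of the tRNA-bound states starts from the
  # tRNA-free binding identified in stage 2
  if (!"aa_R.kon" %in% fixed) theta[["aa_R.kon"]] <- theta[["aa.kon"]]
  dims <- setdiff(c("trna.Kd", "trna.kon", "trna_D.Kd", "amp.kf", "rel.kf",
                    "aa_R.Kd", "aa_R.kon", "tranP.kf"), fixed)
  lower <- c(trna.Kd = 0.01, trna.kon = 0.3, trna_D.Kd = 0.01, amp.kf = 0.5,
             rel.kf = 0.05, aa_R.Kd = 1, aa_R.kon = 0.05, tranP.kf = 1)[dims]
  upper <- c(trna.Kd = 100, trna.kon = 30, trna_D.Kd = 10, amp.kf = 1e4,
             rel.kf = 1e3, aa_R.Kd = 1e4, aa_R.kon = 50, tranP.kf = 300)[dims]
  # warm start: split the cycle-time budget 1/kcat between transfer (fixed),
  # AMP release and product release; centre tRNA affinity on its Km
  kc <- targets$aa$kcat
  if (!is.null(kc)) {
    if (!"amp.kf" %in% fixed) theta[["amp.kf"]] <- 10 * kc
    rest <- 1 / kc - 1 / theta[["tran.kf"]] - 1 / theta[["amp.kf"]]
    if (!"rel.kf" %in% fixed && rest > 0) theta[["rel.kf"]] <- 1.2 / rest
    if (!is.null(targets$aa$Km_trna)) {
      if (!"trna.Kd" %in% fixed) theta[["trna.Kd"]] <- targets$aa$Km_trna
      if (!"trna.kon" %in% fixed)
        theta[["trna.kon"]] <- min(30, max(1, 3 * kc / targets$aa$Km_trna))
      if (!"trna_D.Kd" %in% fixed)
        theta[["trna_D.Kd"]] <- min(1, targets$aa$Km_trna)
    }
    if (!is.null(targets$aa$Km_aa) && !"aa_R.Kd" %in% fixed)
      theta[["aa_R.Kd"]] <- 3 * targets$aa$Km_aa
  }
  want_burst <- !is.na(targets$burst)
  g5 <- c(0.2, 0.5, 1, 2, 5)
  grid_trna <- if (!is.null(targets$aa$Km_trna)) g5 * targets$aa$Km_trna
  grid_aa3 <- if (!is.null(targets$aa$Km_aa)) g5 * targets$aa$Km_aa
  res <- .log_search(function(th) {
    ob <- .aa_obs(th, variant, with_burst = want_burst,
                  grid_trna = grid_trna, grid_aa = grid_aa3)
    l <- .log_ratio_loss(ob[names(targets$aa)], targets$aa)
    if (want_burst && is.finite(ob$burst_aps %||% NA)) {
      # keep the amplitude clear of the 0.5/site classification threshold
      # without fighting the kcat/Km targets far from it
      # a steep hinge just beyond the 0.5/site threshold: enforces the
      # phenotype with margin without dragging the kcat/Km targets
      aps <- ob$burst_aps
      pen <- if (isTRUE(targets$burst)) max(0, 0.60 - aps)
             else max(0, aps - 0.40)
      l <- l + 2 * pen^2
    }
    l
  }, theta, dims, lower, upper, n_random = n_random, seed = seed,
     polish_iters = polish_iters, refine_passes = refine_passes)
  achieved <- .aa_obs(res$theta, variant, with_burst = TRUE,
                      grid_trna = grid_trna, grid_aa = grid_aa3)
  ok <- .within_tol(achieved[names(targets$aa)], targets$aa,
                    targets$tolerance)
  if (want_burst && ok)
    ok <- isTRUE((achieved$burst_aps >= 0.5) == targets$burst)
  structure(list(theta = res$theta,
                 fixed = unique(c(fixed, setdiff(names(res$theta), fixed))),
                 achieved = achieved, ok = ok, loss_trace = res$trace,
                 stage = "aminoacylation"),
            class = "fit_stage")
}

#' Fit a complete enzyme model in three stages
#'
#' Composes [fit_stage_single_turnover()], [fit_stage_pp_exchange()] (skipped
#' for tRNA-required enzymes, whose exchange subscheme does not exist), and
#' [fit_stage_aminoacylation()], sharing one seed and carrying fixed
#' parameters forward. The returned model's rate set reproduces the target
#' observables within tolerance when `ok` is `TRUE`.
#'
#' @param enzyme enzyme name (sets the scheme variant, see [enzyme_model()]).
#' @param targets a [fit_targets()].
#' @param constraints optional [rate_constraint()] rows.
#' @param seed integer seed for all search stages.
#' @param n_random per-stage random-search budget.
#' @param polish_iters per-stage simplex-polish iteration budget.
#' @param variant scheme variant override.
#' @return an `aars_fit` list: `model` (an `aars_model`), `ok`, `stages`,
#'   `achieved`, `log` (seed, budget, per-stage loss traces).
#' @export
fit_enzyme <- function(enzyme, targets, constraints = NULL, seed = 1,
                       n_random = 80, variant = NULL, polish_iters = 300,
                       refine_passes = 2) {
  if (is.null(variant)) variant <- enzyme_variant(enzyme)
  stages <- list()
  s1 <- if (!is.null(targets$k_tran))
    fit_stage_single_turnover(variant, targets, constraints, seed = seed)
  else NULL
  stages$single_turnover <- s1
  s2 <- if (!is.null(targets$pp) && variant != "class1_tRNA_required")
    fit_stage_pp_exchange(variant, targets, constraints, stage1 = s1,
                          seed = seed + 1L, n_random = n_random,
                          polish_iters = polish_iters,
                          refine_passes = refine_passes)
  else s1
  stages$pp_exchange <- if (!identical(s2, s1)) s2 else NULL
  s3 <- fit_stage_aminoacylation(variant, targets, constraints, stage2 = s2,
                                 seed = seed + 2L, n_random = n_random,
                                 polish_iters = polish_iters,
                                 refine_passes = refine_passes)
  stages$aminoacylation <- s3
  rates <- .theta_to_rates(s3$theta, variant)
  model <- enzyme_model(enzyme, rates, variant = variant)
  ok <- s3$ok && (is.null(s1) || s1$ok) &&
    (is.null(stages$pp_exchange) || s2$ok)
  achieved <- c(if (!is.null(stages$pp_exchange))
                  stats::setNames(unlist(s2$achieved),
                                  paste0("pp_", names(s2$achieved))),
                stats::setNames(unlist(s3$achieved),
                                paste0("aa_", names(s3$achieved))),
                if (!is.null(s1)) c(k_tran = s1$achieved$k_tran))
  structure(list(model = model, ok = ok, stages = stages,
                 achieved = achieved,
                 log = list(seed = seed, n_random = n_random,
                            loss = lapply(Filter(Negate(is.null), stages),
                                          function(s) s$loss_trace))),
            class = "aars_fit")
}

#' @export
print.aars_fit <- function(x, ...) {
  cat("Staged enzyme fit:", x$model$enzyme,
      if (x$ok) "(all targets met)" else "(FAILED to meet all targets)",
      "\n")
  print(round(x$achieved, 4))
  invisible(x)
}
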