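# Fast deterministic observables: steady-state velocities from the
# mean-field equations with every substrate held at its nominal
# concentration (the textbook initial-velocity idealisation). Used as the
# inner loop of the staged fitting; the stochastic assay protocol in
# assays.R is the reference implementation the fits are confirmed against.

.ode_states_only <- function(scheme, rates, conc, E0, times,
                             start_state = "S0") {
  ns <- length(scheme$states)
  arr <- .step_arrays(scheme, rates)
  f1 <- arr$from + 1L; t1 <- arr$to + 1L
  cidx <- arr$consume + 1L; ridx <- arr$release + 1L
  nst <- length(f1)
  Mstate <- matrix(0, ns, nst)
  for (k in seq_len(nst)) {
    Mstate[f1[k], k] <- Mstate[f1[k], k] - 1
    Mstate[t1[k], k] <- Mstate[t1[k], k] + 1
  }
  has_c <- cidx > 0; has_r <- ridx > 0
  fmul <- rep.int(1, nst); fmul[has_c] <- conc[cidx[has_c]]
  bmul <- rep.int(1, nst); bmul[has_r] <- conc[ridx[has_r]]
  kf <- arr$kf; kb <- arr$kb
  y0 <- numeric(ns)
  y0[match(start_state, names(scheme$states))] <- E0
  deriv <- function(t, y, p) {
    vf <- kf * y[f1] * fmul
    vb <- kb * y[t1] * bmul
    list(drop(Mstate %*% (vf - vb)))
  }
  sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = 1e-9, atol = 1e-12)
  as.matrix(sol)[, -1, drop = FALSE]
}

.instant_velocity <- function(scheme, rates, x, conc, mode) {
  arr <- .step_arrays(scheme, rates)
  sp <- scheme$steps
  f1 <- arr$from + 1L; t1 <- arr$to + 1L
  cidx <- arr$consume + 1L; ridx <- arr$release + 1L
  fmul <- ifelse(cidx > 0, conc[pmax(cidx, 1L)], 1)
  bmul <- ifelse(ridx > 0, conc[pmax(ridx, 1L)], 1)
  vf <- arr$kf * x[f1] * fmul
  vb <- arr$kb * x[t1] * bmul
  if (mode == "pp_exchange") {
    k <- which(sp$id %in% c("act", "act_trna"))
    sum(vb[k])
  } else {
    k <- which(sp$id %in% product_steps(scheme))
    sum(vf[k] - vb[k])
  }
}

# steady-state per-enzyme velocity at fixed substrate concentrations (uM).
# With every pool held constant the mean-field occupancies obey a linear
# master equation, so the steady state is a direct solve (one row replaced
# by the conservation constraint); integration is the fallback for
# numerically singular cases.
.steady_velocity <- function(scheme, rates, conc, mode, t_end = 10) {
  E0 <- 1
  arr <- .step_arrays(scheme, rates)
  ns <- length(scheme$states)
  f1 <- arr$from + 1L; t1 <- arr$to + 1L
  cidx <- arr$consume + 1L; ridx <- arr$release + 1L
  fmul <- ifelse(cidx > 0, conc[pmax(cidx, 1L)], 1)
  bmul <- ifelse(ridx > 0, conc[pmax(ridx, 1L)], 1)
  kf_eff <- arr$kf * fmul     # from -> to
  kb_eff <- arr$kb * bmul     # to -> from
  A <- matrix(0, ns, ns)
  for (k in seq_along(f1)) {
    A[t1[k], f1[k]] <- A[t1[k], f1[k]] + kf_eff[k]
    A[f1[k], f1[k]] <- A[f1[k], f1[k]] - kf_eff[k]
    A[f1[k], t1[k]] <- A[f1[k], t1[k]] + kb_eff[k]
    A[t1[k], t1[k]] <- A[t1[k], t1[k]] - kb_eff[k]
  }
  A[ns, ] <- 1                              # conservation row
  b <- c(rep(0, ns - 1), E0)
  x <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(x) || any(x < -1e-8 * E0)) {
    xx <- .ode_states_only(scheme, rates, conc, E0, c(0, t_end, 2 * t_end))
    x <- xx[3, ]
  }
  .instant_velocity(scheme, rates, pmax(x, 0), conc, mode) / E0
}

# burst amplitude per site from a lean mean-field integration at the
# pre-steady-state assay concentrations (all pools held): enzyme states
# plus one cumulative-product accumulator, late-half linear extrapolation
# to t = 0 as in detect_burst. Fast surrogate used inside fitting loops.
.burst_aps_ode <- function(scheme, rates, sites = scheme$site_count,
                           duration = 2, n_out = 60) {
  conc <- c(A = 500, T = 5000, P = 0, M = 0, R = 10, Rs = 0)
  arr <- .step_arrays(scheme, rates)
  ns <- length(scheme$states)
  f1 <- arr$from + 1L; t1 <- arr$to + 1L
  cidx <- arr$consume + 1L; ridx <- arr$release + 1L
  nst <- length(f1)
  Mstate <- matrix(0, ns, nst)
  for (k in seq_len(nst)) {
    Mstate[f1[k], k] <- Mstate[f1[k], k] - 1
    Mstate[t1[k], k] <- Mstate[t1[k], k] + 1
  }
  fmul <- ifelse(cidx > 0, conc[pmax(cidx, 1L)], 1)
  bmul <- ifelse(ridx > 0, conc[pmax(ridx, 1L)], 1)
  kf <- arr$kf * fmul; kb <- arr$kb * bmul
  prod <- which(scheme$steps$id %in% product_steps(scheme))
  y0 <- numeric(ns + 1)
  y0[match("S0", names(scheme$states))] <- 1
  deriv <- function(t, y, p) {
    vf <- kf * y[f1]; vb <- kb * y[t1]
    net <- vf - vb
    list(c(drop(Mstate %*% net), sum(net[prod])))
  }
  tt <- seq(0, duration, length.out = n_out + 1)
  sol <- tryCatch(deSolve::lsoda(y0, tt, deriv, parms = NULL,
                                 rtol = 1e-8, atol = 1e-10),
                  error = function(e) NULL)
  if (is.null(sol)) return(NA_real_)
  y <- as.matrix(sol)[, ns + 2]
  late <- tt >= duration / 2
  cf <- stats::coef(stats::lm(y[late] ~ tt[late]))
  max(0, unname(cf[1])) / sites
}

.assay_conc <- function(assay, varied = NULL, value = NULL) {
  conc <- c(A = 500, T = 5000, P = if (assay == "pp_exchange") 2000 else 0,
            M = 0, R = if (assay == "aminoacylation") 10 else 0, Rs = 0)
  key <- c(AA = "A", ATP = "T", tRNA = "R")
  if (!is.null(varied)) conc[key[[varied]]] <- value
  conc
}

# deterministic kcat/Km for one varied substrate, Woolf-Hanes on a
# pilot-centred grid
.steady_km <- function(scheme, rates, assay, varied, grid = NULL) {
  mode <- if (assay == "pp_exchange") "pp_exchange" else "product"
  if (is.null(grid)) {
    km0 <- if (varied == "tRNA") 1 else 100
    g0 <- c(0.2, 1, 5) * km0
    v0 <- vapply(g0, function(cc)
      .steady_velocity(scheme, rates, .assay_conc(assay, varied, cc), mode),
      numeric(1))
    pf <- tryCatch(woolf_hanes_fit(data.frame(conc = g0, v = v0)),
                   error = function(e) NULL)
    kmp <- if (!is.null(pf) && isTRUE(pf$valid)) pf$Km else km0
    grid <- c(0.2, 0.5, 1, 2, 5) * kmp
  }
  v <- vapply(grid, function(cc)
    .steady_velocity(scheme, rates, .assay_conc(assay, varied, cc), mode),
    numeric(1))
  fit <- tryCatch(woolf_hanes_fit(data.frame(conc = grid, v = v)),
                  error = function(e) list(valid = FALSE, kcat = NA, Km = NA))
  list(kcat = fit$kcat, Km = fit$Km, valid = isTRUE(fit$valid), grid = grid)
}

#' Deterministic observable set of an enzyme model
#'
#' Computes the model's kinetic observables from the mean-field equations:
#' pyrophosphate-exchange kcat and Km for amino acid and ATP (on the
#' tRNA-free subscheme), aminoacylation kcat and Km for tRNA and amino acid,
#' the single-turnover transfer rate k_tran, the composite chemistry rate
#' k_chem, and the burst amplitude per site. This is the fast inner oracle of
#' the fitting procedure; the stochastic assays are the protocol-faithful
#' counterpart.
#'
#' @param model an `aars_model`.
#' @param what character subset of
#'   `c("pp","aa","k_tran","k_chem","burst")`.
#' @return named list of observables (NA where a subscheme is unavailable,
#'   e.g. exchange for tRNA-required enzymes).
#' @export
model_observables <- function(model,
                              what = c("pp", "aa", "k_tran", "burst")) {
  out <- list()
  if ("pp" %in% what) {
    if ("act" %in% model$rates$step_id) {
      sub <- build_pp_exchange_scheme()
      r <- model$rates[match(sub$steps$id, model$rates$step_id), ]
      aa <- .steady_km(sub, r, "pp_exchange", "AA")
      at <- .steady_km(sub, r, "pp_exchange", "ATP")
      out$pp_kcat <- aa$kcat; out$pp_Km_aa <- aa$Km; out$pp_Km_atp <- at$Km
    } else {
      out$pp_kcat <- out$pp_Km_aa <- out$pp_Km_atp <- NA_real_
    }
  }
  if ("aa" %in% what) {
    tr <- .steady_km(model$scheme, model$rates, "aminoacylation", "tRNA")
    am <- .steady_km(model$scheme, model$rates, "aminoacylation", "AA")
    out$aa_kcat <- tr$kcat; out$aa_Km_trna <- tr$Km; out$aa_Km_aa <- am$Km
  }
  if ("k_tran" %in% what) {
    fit <- tryCatch(run_single_turnover(model, "transfer", method = "ode"),
                    error = function(e) NULL)
    out$k_tran <- if (is.null(fit)) NA_real_ else fit$B
  }
  if ("k_chem" %in% what) {
    fit <- tryCatch(run_single_turnover(model, "chem", method = "ode"),
                    error = function(e) NULL)
    out$k_chem <- if (is.null(fit)) NA_real_ else fit$B
  }
  if ("burst" %in% what) {
    b <- tryCatch(run_burst_assay(model, method = "ode"),
                  error = function(e) NULL)
    out$burst_amplitude_per_site <- if (is.null(b)) NA_real_
                                    else b$amplitude_per_site
    out$burst <- if (is.null(b)) NA else b$burst
  }
  out
}
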