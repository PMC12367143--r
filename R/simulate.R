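# molecules per cubic micron per uM (Avogadro's number scaled); also
# molecules per litre per uM is MOLEC_PER_UM3_PER_UM * 1e15.
MOLEC_PER_UM3_PER_UM <- 602.214
MOLEC_PER_L_PER_UM <- 6.02214e17

#' Assay conditions for a simulation
#'
#' Pool concentrations are in uM. By default the abundant substrates (ATP,
#' amino acid, PPi, AMP) are treated as constant-concentration baths, which
#' makes their binding steps pseudo-first-order; tRNA and aa-tRNA are discrete
#' pools, as is the enzyme. When `volume` is `NULL` it is chosen so the enzyme
#' has `copies_target` copies at `enzyme_conc` (velocity estimates need enough
#' events; the conversion is N = c * V * N_A throughout).
#'
#' @param ATP,AA,PPi,AMP,tRNA,aatRNA pool concentrations (uM).
#' @param bath named logical vector over species codes
#'   `c("A","T","P","M","R","Rs")`; `TRUE` = held constant.
#' @param enzyme_conc total enzyme concentration (uM).
#' @param volume simulation volume in litres, or `NULL` to derive from
#'   `copies_target`.
#' @param copies_target enzyme copy number used to derive the volume.
#' @param duration simulated time (s).
#' @param n_samples number of evenly spaced output samples.
#' @param start_state enzyme state all copies start in (default `"S0"`).
#' @param demand zero-order drain rate converting free charged tRNA back to
#'   free uncharged tRNA (molecules/s); 0 disables it.
#' @return an `aars_conditions` list.
#' @export
assay_conditions <- function(ATP = 5000, AA = 500, PPi = 0, AMP = 0,
                             tRNA = 0, aatRNA = 0,
                             bath = c(A = TRUE, T = TRUE, P = TRUE, M = TRUE,
                                      R = FALSE, Rs = FALSE),
                             enzyme_conc = 0.01, volume = NULL,
                             copies_target = 200, duration = 10,
                             n_samples = 500, start_state = "S0",
                             demand = 0) {
  conc <- c(A = AA, T = ATP, P = PPi, M = AMP, R = tRNA, Rs = aatRNA)
  if (any(conc < 0)) stop("concentrations must be >= 0")
  full_bath <- c(A = TRUE, T = TRUE, P = TRUE, M = TRUE, R = FALSE, Rs = FALSE)
  full_bath[names(bath)] <- bath
  if (is.null(volume)) {
    volume <- if (enzyme_conc > 0)
      copies_target / (enzyme_conc * MOLEC_PER_L_PER_UM)
    else 200 / MOLEC_PER_L_PER_UM
  }
  if (volume <= 0) stop("volume must be > 0")
  structure(list(conc = conc, bath = full_bath, enzyme_conc = enzyme_conc,
                 volume = volume, duration = duration, n_samples = n_samples,
                 start_state = start_state, demand = demand),
            class = "aars_conditions")
}

.conv_factor <- function(conditions) conditions$volume * MOLEC_PER_L_PER_UM

.resolve_model <- function(model, rates) {
  if (inherits(model, "aars_model")) list(scheme = model$scheme,
                                          rates = model$rates)
  else if (inherits(model, "aars_scheme")) {
    if (is.null(rates)) stop("rates required when passing a bare scheme")
    list(scheme = model, rates = rates)
  } else stop("model must be an aars_model or aars_scheme")
}

.step_arrays <- function(scheme, rates) {
  sp <- scheme$steps
  r <- rates[match(sp$id, rates$step_id), ]
  list(from = match(sp$from, names(scheme$states)) - 1L,
       to = match(sp$to, names(scheme$states)) - 1L,
       kf = r$k_f, kb = r$k_b,
       consume = match(sp$consume, POOL_SPECIES, nomatch = 0L) - 1L,
       release = match(sp$release, POOL_SPECIES, nomatch = 0L) - 1L)
}

#' Steps whose forward firing creates one aa-tRNA product
#'
#' The amino-acid transfer steps when the scheme has them (product is counted
#' at the chemistry, matching quench assays which see charged tRNA whether
#' enzyme-bound or free); otherwise the steps that release aa-tRNA.
#' @param scheme an `aars_scheme`.
#' @return character vector of step ids.
#' @export
product_steps <- function(scheme) {
  sp <- scheme$steps
  is_tran <- vapply(seq_len(nrow(sp)), function(i) {
    d <- .multiset_diff(.comp_all(scheme$states[[sp$to[i]]]),
                        .comp_all(scheme$states[[sp$from[i]]]))
    setequal(d$plus, c("M", "Rs")) && setequal(d$minus, c("D", "R"))
  }, logical(1))
  if (any(is_tran)) return(sp$id[is_tran])
  sp$id[sp$release == "Rs"]
}

.traj <- function(times, res, scheme, conditions, enzyme_copies, conv,
                  stochastic) {
  colnames(res$states) <- names(scheme$states)
  colnames(res$pools) <- POOL_SPECIES
  colnames(res$fire_f) <- colnames(res$fire_b) <- scheme$steps$id
  structure(list(times = times, states = res$states, pools = res$pools,
                 fire_f = res$fire_f, fire_b = res$fire_b,
                 drain = res$drain, enzyme_copies = enzyme_copies,
                 conv = conv, scheme = scheme, conditions = conditions,
                 exhausted = isTRUE(res$exhausted),
                 events = res$events %||% NA_real_,
                 stochastic = stochastic),
            class = "aars_trajectory")
}

#' Stochastic simulation of a reaction scheme (Gillespie direct method)
#'
#' Simulates the continuous-time Markov chain of enzyme-state transitions
#' under the given assay conditions. Bath species never change; discrete
#' pools (tRNA, aa-tRNA by default) are updated per event. The same seed and
#' inputs give an identical event sequence.
#'
#' @param model an `aars_model`, or an `aars_scheme` with `rates` supplied.
#' @param conditions an [assay_conditions()] object.
#' @param rates an `aars_rates` set (when `model` is a bare scheme).
#' @param seed integer seed for the simulation (set via [set.seed()]);
#'   `NULL` leaves the RNG state alone.
#' @param max_events event budget guard.
#' @return an `aars_trajectory`: sampled times, enzyme-state occupancy
#'   counts, pool counts, cumulative per-step firing counts (forward and
#'   backward), and the demand-drain count.
#' @export
simulate_ssa <- function(model, conditions, rates = NULL, seed = NULL,
                         max_events = 5e7) {
  m <- .resolve_model(model, rates)
  if (!is.null(seed)) set.seed(seed)
  conv <- .conv_factor(conditions)
  enzyme_copies <- max(0L, as.integer(round(conditions$enzyme_conc * conv)))
  init <- integer(length(m$scheme$states))
  init[match(conditions$start_state, names(m$scheme$states))] <- enzyme_copies
  pool_init <- ifelse(conditions$bath, 0,
                      round(conditions$conc * conv))
  arr <- .step_arrays(m$scheme, m$rates)
  times <- seq(0, conditions$duration, length.out = conditions$n_samples + 1L)
  res <- .ssa_run(length(m$scheme$states), arr$from, arr$to, arr$kf, arr$kb,
                  arr$consume, arr$release, init, as.numeric(pool_init),
                  as.numeric(conditions$conc), as.logical(conditions$bath),
                  conv, times, conditions$demand,
                  match("Rs", POOL_SPECIES) - 1L,
                  match("R", POOL_SPECIES) - 1L, max_events)
  .traj(times, res, m$scheme, conditions, enzyme_copies, conv, TRUE)
}

#' Mean-field ODE simulation of a reaction scheme
#'
#' Deterministic counterpart of [simulate_ssa()]: integrates the mass-action
#' mean-field equations with `deSolve::lsoda`, including cumulative per-step
#' flux accumulators so that velocities can be measured exactly as in the
#' stochastic case. Output is expressed in expected copy numbers at the
#' condition volume, so trajectories are directly comparable to SSA ensemble
#' means.
#'
#' @inheritParams simulate_ssa
#' @param rtol,atol integration tolerances passed to `lsoda`.
#' @return an `aars_trajectory` with real-valued counts.
#' @export
simulate_ode <- function(model, conditions, rates = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  m <- .resolve_model(model, rates)
  scheme <- m$scheme
  ns <- length(scheme$states)
  nst <- nrow(scheme$steps)
  conv <- .conv_factor(conditions)
  arr <- .step_arrays(scheme, m$rates)
  f1 <- arr$from + 1L; t1 <- arr$to + 1L
  cidx <- arr$consume + 1L; ridx <- arr$release + 1L  # 0 = none
  bath <- as.logical(conditions$bath)
  bconc <- as.numeric(conditions$conc)
  demand_uM <- conditions$demand / conv
  i_R <- match("R", POOL_SPECIES); i_Rs <- match("Rs", POOL_SPECIES)

  # incidence matrices: enzyme states x steps, pools x steps
  Mstate <- matrix(0, ns, nst)
  Mpool <- matrix(0, 6, nst)
  for (k in seq_len(nst)) {
    Mstate[f1[k], k] <- Mstate[f1[k], k] - 1
    Mstate[t1[k], k] <- Mstate[t1[k], k] + 1
    if (cidx[k] > 0 && !bath[cidx[k]]) Mpool[cidx[k], k] <- -1
    if (ridx[k] > 0 && !bath[ridx[k]]) Mpool[ridx[k], k] <- 1
  }
  has_c <- cidx > 0; has_r <- ridx > 0
  kf <- arr$kf; kb <- arr$kb

  y0 <- numeric(ns + 6 + 2 * nst)
  y0[match(conditions$start_state, names(scheme$states))] <-
    conditions$enzyme_conc
  y0[ns + which(!bath)] <- bconc[!bath]

  deriv <- function(t, y, parms) {
    x <- y[1:ns]
    pool <- y[ns + 1:6]
    cc <- bconc
    cc[!bath] <- pool[!bath]
    fmul <- rep.int(1, nst); fmul[has_c] <- cc[cidx[has_c]]
    bmul <- rep.int(1, nst); bmul[has_r] <- cc[ridx[has_r]]
    vf <- kf * x[f1] * fmul
    vb <- kb * x[t1] * bmul
    net <- vf - vb
    dx <- drop(Mstate %*% net)
    dpool <- drop(Mpool %*% net)
    if (demand_uM > 0) {
      vd <- demand_uM * pool[i_Rs] / (pool[i_Rs] + 1e-9)
      if (!bath[i_Rs]) dpool[i_Rs] <- dpool[i_Rs] - vd
      if (!bath[i_R]) dpool[i_R] <- dpool[i_R] + vd
    }
    list(c(dx, dpool, vf, vb))
  }

  times <- seq(0, conditions$duration, length.out = conditions$n_samples + 1L)
  sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (lsoda istate ",
         attr(sol, "istate")[1], ")")
  sol <- as.matrix(sol)[, -1, drop = FALSE]
  res <- list(states = sol[, 1:ns, drop = FALSE] * conv,
              pools = sol[, ns + 1:6, drop = FALSE] * conv,
              fire_f = sol[, ns + 6 + 1:nst, drop = FALSE] * conv,
              fire_b = sol[, ns + 6 + nst + 1:nst, drop = FALSE] * conv,
              drain = rep(0, length(times)), exhausted = FALSE)
  .traj(times, res, scheme, conditions,
        conditions$enzyme_conc * conv, conv, FALSE)
}

#' Cumulative aa-tRNA product formed along a trajectory
#'
#' Net forward firings of the product-forming steps (see [product_steps()]).
#' @param traj an `aars_trajectory`.
#' @return numeric vector over the trajectory's sample times.
#' @export
trajectory_product <- function(traj) {
  ids <- product_steps(traj$scheme)
  rowSums(traj$fire_f[, ids, drop = FALSE]) -
    rowSums(traj$fire_b[, ids, drop = FALSE])
}

#' Initial reaction velocity from a trajectory
#'
#' `mode = "pp_exchange"` returns the pyrophosphate-exchange speed V: the
#' rate of reverse-activation firings (adenylate + PPi back to ATP + amino
#' acid) per second per enzyme, which is the labelled flux divided by the
#' specific activity at t = 0. `mode = "product"` returns the slope of
#' cumulative aa-tRNA product versus time per enzyme, measured over an early
#' window ending when `conversion_cap` of the limiting discrete pool has been
#' consumed (an intercept is fitted so a pre-steady-state burst does not bias
#' the slope).
#'
#' @param traj an `aars_trajectory`.
#' @param mode `"pp_exchange"` or `"product"`.
#' @param conversion_cap fraction of the limiting pool allowed to convert
#'   within the measurement window.
#' @param window_frac latest fraction of the duration used for the product
#'   window; the exchange mode uses all samples after a 5% equilibration.
#' @return velocity in s^-1 per enzyme, with attributes `se` (regression
#'   standard error), `n_events`, and `low_confidence` (fewer than 10
#'   events in the window).
#' @export
initial_velocity <- function(traj, mode = c("pp_exchange", "product"),
                             conversion_cap = 0.05, window_frac = 0.1) {
  mode <- match.arg(mode)
  E0 <- traj$enzyme_copies
  if (E0 <= 0) return(structure(0, se = 0, n_events = 0,
                                low_confidence = TRUE))
  tt <- traj$times
  if (mode == "pp_exchange") {
    act_ids <- intersect(c("act", "act_trna"), traj$scheme$steps$id)
    y <- rowSums(traj$fire_b[, act_ids, drop = FALSE])
    keep <- tt >= 0.05 * max(tt)
  } else {
    y <- trajectory_product(traj)
    # limiting pool: the discrete substrate pool (uncharged tRNA if present)
    lim <- Inf
    if (!traj$conditions$bath[["R"]] && traj$pools[1, "R"] > 0)
      lim <- traj$pools[1, "R"]
    t_cap <- if (is.finite(lim)) {
      over <- which(y >= conversion_cap * lim)
      if (length(over)) tt[over[1]] else max(tt)
    } else max(tt)
    keep <- tt <= min(t_cap, window_frac * max(tt))
    if (sum(keep) < 3) keep <- seq_along(tt) <= 3
  }
  fit <- stats::lm(y[keep] ~ tt[keep])
  slope <- unname(stats::coef(fit)[2])
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[2, 2]),
                 error = function(e) NA_real_)
  n_ev <- max(y[keep]) - min(y[keep])
  structure(slope / E0, se = se / E0, n_events = n_ev,
            low_confidence = n_ev < 10)
}

#' Write a trajectory as CSV
#'
#' Columns: time, one column per enzyme state, the discrete pool species,
#' and cumulative product. The header records the seed-bearing conditions
#' as comment lines.
#'
#' @param traj an `aars_trajectory`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  keep <- !traj$conditions$bath
  tab <- data.frame(time = traj$times, traj$states,
                    traj$pools[, keep, drop = FALSE],
                    product = trajectory_product(traj),
                    check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# %s trajectory; enzyme_copies=%d; volume=%.6g L",
                       if (traj$stochastic) "SSA" else "ODE",
                       traj$enzyme_copies, traj$conditions$volume),
               sprintf("# concentrations (uM): %s",
                       paste(names(traj$conditions$conc),
                             traj$conditions$conc, sep = "=",
                             collapse = " "))), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @export
print.aars_trajectory <- function(x, ...) {
  cat(if (x$stochastic) "SSA" else "ODE", "trajectory:",
      length(x$times), "samples over", max(x$times), "s;",
      x$enzyme_copies, "enzyme copies\n")
  invisible(x)
}
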