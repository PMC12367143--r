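#' Woolf-Hanes estimation of kcat and Km
#'
#' Plots substrate concentration over velocity against substrate
#' concentration and fits an ordinary least-squares line `y = m x + b`;
#' then `kcat = 1/m` and `Km = b/m`. Standard errors are propagated from the
#' regression covariance by the delta method. The regression is unweighted.
#'
#' @param points data frame with columns `conc` (uM), `v` (s^-1 per enzyme)
#'   and optionally `sd` over replicates.
#' @return an `mm_fit` list: `kcat`, `Km`, `kcat_se`, `Km_se`, `r_squared`,
#'   `slope`, `intercept`, `valid` (FALSE with a `reason` when the slope or
#'   intercept is non-positive).
#' @examples
#' s <- c(1, 2, 5, 10, 20)
#' pts <- data.frame(conc = s, v = 10 * s / (5 + s))
#' woolf_hanes_fit(pts)   # kcat = 10, Km = 5 exactly
#' @export
woolf_hanes_fit <- function(points) {
  if (!all(c("conc", "v") %in% names(points)))
    stop("points must have columns conc and v")
  pts <- points[points$v > 0 & is.finite(points$v), , drop = FALSE]
  if (nrow(pts) < 3) stop("need at least 3 points with positive velocities")
  x <- pts$conc
  y <- pts$conc / pts$v
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  b <- unname(cf[1]); m <- unname(cf[2])
  V <- suppressWarnings(stats::vcov(fit))  # noiseless data trips summary.lm
  out <- list(kcat = 1 / m, Km = b / m,
              kcat_se = NA_real_, Km_se = NA_real_,
              r_squared = suppressWarnings(summary(fit)$r.squared),
              slope = m, intercept = b, valid = TRUE, reason = NULL)
  if (!(m > 0) || !(b > 0)) {
    out$valid <- FALSE
    out$reason <- sprintf("non-positive slope (%.3g) or intercept (%.3g)",
                          m, b)
    return(structure(out, class = "mm_fit"))
  }
  # delta method: kcat = 1/m, Km = b/m
  out$kcat_se <- sqrt(V[2, 2]) / m^2
  g <- c(1 / m, -b / m^2)                 # d(Km)/d(b), d(Km)/d(m)
  out$Km_se <- sqrt(max(0, t(g) %*% V %*% g))
  structure(out, class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!x$valid) {
    cat("Woolf-Hanes fit: INVALID (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("Woolf-Hanes fit: kcat = %.4g +/- %.2g s^-1, Km = %.4g +/- %.2g uM (R^2 = %.4f)\n",
                x$kcat, x$kcat_se, x$Km, x$Km_se, x$r_squared))
  }
  invisible(x)
}

#' Fit a bounded exponential rise
#'
#' Fits `y(t) = A (1 - exp(-B t))` by nonlinear least squares
#' (`minpack.lm::nlsLM`) from a deterministic log-linearised initial guess
#' (`A0 = 1.05 max(y)`, `B0` from the slope of `-log(1 - y/A0)` against t).
#' This is the single-turnover model whose rate `B` is the transfer rate
#' k_tran (or the composite chemistry rate k_chem).
#'
#' @param times,values time points (s) and product values (non-decreasing
#'   within noise).
#' @return an `exp_fit` list: `A`, `B`, `resid_norm`, `A_se`, `B_se`.
#' @export
fit_exponential <- function(times, values) {
  if (length(times) < 5 || length(times) != length(values))
    stop("need >= 5 matched time points")
  if (max(values) <= 0) stop("degenerate input: no signal to fit")
  A0 <- 1.05 * max(values)
  ok <- values > 0 & values < 0.95 * A0 & times > 0
  if (sum(ok) >= 2) {
    z <- -log(1 - values[ok] / A0)
    B0 <- max(1e-6, unname(stats::coef(stats::lm(z ~ 0 + times[ok]))[1]))
  } else B0 <- 1 / stats::median(times[times > 0])
  dat <- data.frame(t = times, y = values)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-B * t)), data = dat,
                      start = list(A = A0, B = B0),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit failed: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, 2],
                 error = function(e) c(A = NA_real_, B = NA_real_))
  structure(list(A = unname(cf["A"]), B = unname(cf["B"]),
                 resid_norm = sqrt(sum(stats::resid(fit)^2)),
                 A_se = unname(se["A"]), B_se = unname(se["B"])),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Exponential fit: y = A(1 - exp(-B t)), A = %.4g, B = %.4g s^-1\n",
              x$A, x$B))
  invisible(x)
}

#' Detect pre-steady-state burst kinetics
#'
#' Fits a line to the late, steady phase of the cumulative product curve and
#' extrapolates to t = 0. The intercept is the burst amplitude: the product
#' trapped on the enzyme before the slow post-chemistry step turns over. The
#' burst flag is raised when amplitude per enzyme site reaches `threshold`
#' (default 0.5: a true burst traps about one product per site).
#' Steady-phase stationarity is checked by comparing slopes across the last
#' three windows of the late half (relative change < `slope_tol`).
#'
#' @param traj an `aars_trajectory` (or a list with `times` and a product
#'   vector via `product`).
#' @param enzyme_copies,sites total enzyme copies and catalytic sites per
#'   enzyme; defaulted from the trajectory.
#' @param product optional explicit product vector.
#' @param threshold burst amplitude per site declaring a burst.
#' @param slope_tol relative slope-stationarity tolerance.
#' @return a `burst_result` list: `amplitude` (molecules), `amplitude_per_site`,
#'   `burst` (flag), `steady_rate` (s^-1 per enzyme).
#' @export
detect_burst <- function(traj, enzyme_copies = traj$enzyme_copies,
                         sites = traj$scheme$site_count, product = NULL,
                         threshold = 0.5, slope_tol = 0.1) {
  tt <- traj$times
  y <- if (is.null(product)) trajectory_product(traj) else product
  n <- length(tt)
  late <- which(tt >= 0.5 * max(tt))
  if (length(late) < 9) stop("too few samples in the late phase")
  thirds <- split(late, cut(seq_along(late), 3, labels = FALSE))
  slopes <- vapply(thirds, function(i)
    unname(stats::coef(stats::lm(y[i] ~ tt[i]))[2]), numeric(1))
  ms <- mean(slopes)
  if (ms <= 0 || max(abs(slopes - ms)) / ms > slope_tol)
    stop("steady phase not detected: late-phase slope not stationary ",
         sprintf("(slopes %s)", paste(signif(slopes, 3), collapse = ", ")))
  fit <- stats::lm(y[late] ~ tt[late])
  amp <- max(0, unname(stats::coef(fit)[1]))
  aps <- amp / (enzyme_copies * sites)
  structure(list(amplitude = amp, amplitude_per_site = aps,
                 burst = aps >= threshold,
                 steady_rate = unname(stats::coef(fit)[2]) / enzyme_copies),
            class = "burst_result")
}

#' @export
print.burst_result <- function(x, ...) {
  cat(sprintf("Burst: %s (amplitude %.3g molecules, %.3f per site; steady rate %.3g s^-1/enzyme)\n",
              if (x$burst) "YES" else "no", x$amplitude,
              x$amplitude_per_site, x$steady_rate))
  invisible(x)
}
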