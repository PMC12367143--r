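# Michaelis-Menten reduction of the full kinetic scheme. ATP is assumed
# saturating at this level; AMP/PPi inhibition is represented only by the
# full scheme.

#' Michaelis-Menten velocity
#'
#' Per-enzyme rate `v = kcat * S / (Km + S)`.
#' @param kcat turnover number (s^-1).
#' @param Km Michaelis constant (uM).
#' @param S substrate concentration (uM), vectorised.
#' @return per-enzyme velocity (s^-1).
#' @export
mm_velocity <- function(kcat, Km, S) {
  stopifnot(all(S >= 0))
  kcat * S / (Km + S)
}

#' Multi-isoacceptor Michaelis-Menten velocity
#'
#' Charging rate of each tRNA isoacceptor by one synthetase with ATP
#' saturating: the amino-acid saturation factor multiplies a competitive
#' partition over isoacceptors,
#' `v(i) = kcat * AA/(Km_aa+AA) * (T_i/Km_t(i)) / (1 + sum_j T_j/Km_t(j))`.
#'
#' @param kcat turnover number (s^-1).
#' @param Km_aa amino-acid Michaelis constant (uM).
#' @param AA free amino-acid concentration (uM).
#' @param T_ free isoacceptor concentrations (uM).
#' @param Km_t per-isoacceptor Michaelis constants (uM), same length as `T_`.
#' @return per-isoacceptor per-enzyme rates (s^-1).
#' @export
mm_multi_isoacceptor <- function(kcat, Km_aa, AA, T_, Km_t) {
  if (length(T_) != length(Km_t))
    stop("T_ and Km_t must have the same length")
  denom <- 1 + sum(T_ / Km_t)
  kcat * (AA / (Km_aa + AA)) * (T_ / Km_t) / denom
}

#' Invert the Michaelis-Menten equation for substrate
#'
#' Solves `v = kcat S/(Km+S)` for S: `S = Km v / (kcat - v)`. Used to infer
#' the free uncharged tRNA concentration a model implies from its per-enzyme
#' turnover.
#'
#' @param kcat,Km MM parameters (s^-1, uM).
#' @param v per-enzyme velocity (s^-1), `0 < v < kcat`.
#' @return substrate concentration (uM).
#' @examples
#' invert_mm_for_substrate(69.44, 10.6, 4.44)   # 0.724 uM
#' @export
invert_mm_for_substrate <- function(kcat, Km, v) {
  if (any(v <= 0)) stop("v must be positive")
  if (any(v >= kcat)) stop("infeasible: v must be strictly below kcat")
  Km * v / (kcat - v)
}

#' Rescale kcat at fixed turnover and free substrate
#'
#' In the MM model, a turnover rate r at free substrate T_u pins only the
#' combination `kcat = r (Km + T_u) / T_u`; choosing a new Km therefore
#' rescales kcat while leaving the working point (r at T_u) unchanged.
#'
#' @param r per-enzyme turnover (s^-1).
#' @param T_u free uncharged substrate concentration (uM).
#' @param Km_new new Michaelis constant (uM).
#' @return the rescaled kcat (s^-1); `mm_velocity(kcat_new, Km_new, T_u)`
#'   equals `r` exactly.
#' @examples
#' rescale_kcat(4.44, 0.724, 0.64)   # ~8.36 s^-1
#' @export
rescale_kcat <- function(r, T_u, Km_new) {
  stopifnot(r > 0, T_u > 0, Km_new > 0)
  r * (Km_new + T_u) / T_u
}

#' Derive MM parameters from a full kinetic model
#'
#' Runs the aminoacylation assay varying tRNA and amino acid and packages
#' the Woolf-Hanes fits as MM parameters.
#'
#' @param model an `aars_model`.
#' @param seed integer seed (SSA method).
#' @param method `"ode"` (deterministic steady-state velocities, default) or
#'   `"ssa"` (the 10-replicate stochastic protocol).
#' @param E0 total enzyme concentration (uM) for `Vm = kcat * E0`.
#' @return an `mm_params` list: `kcat`, `Km_aa`, `Km_trna`, `E0`, `Vm`.
#' @export
derive_mm_from_full_model <- function(model, seed = 1,
                                      method = c("ode", "ssa"), E0 = 0.01) {
  method <- match.arg(method)
  if (method == "ode") {
    tr <- .steady_km(model$scheme, model$rates, "aminoacylation", "tRNA")
    am <- .steady_km(model$scheme, model$rates, "aminoacylation", "AA")
    kcat <- tr$kcat; km_t <- tr$Km; km_a <- am$Km
  } else {
    tr <- run_km_assay(model, "aminoacylation", "tRNA", seed = seed)
    am <- run_km_assay(model, "aminoacylation", "AA", seed = seed + 500L)
    if (!isTRUE(tr$fit$valid) || !isTRUE(am$fit$valid))
      stop("invalid Woolf-Hanes fit while deriving MM parameters")
    kcat <- tr$fit$kcat; km_t <- tr$fit$Km; km_a <- am$fit$Km
  }
  structure(list(kcat = kcat, Km_aa = km_a, Km_trna = km_t,
                 E0 = E0, Vm = kcat * E0),
            class = "mm_params")
}

#' @export
print.mm_params <- function(x, ...) {
  cat(sprintf("MM parameters: kcat = %.4g s^-1, Km_trna = %.4g uM, Km_aa = %.4g uM (Vm = %.4g uM/s at E0 = %.3g uM)\n",
              x$kcat, x$Km_trna, x$Km_aa, x$Vm, x$E0))
  invisible(x)
}

#' Is a kcat sufficient for an in vivo demand?
#'
#' The per-enzyme velocity can meet a turnover requirement r only when
#' `kcat > r`; when feasible, the free uncharged tRNA pool required to run
#' at exactly r is `invert_mm_for_substrate(kcat, Km, r)`.
#'
#' @param kcat,Km MM parameters (s^-1, uM); `Km` is the tRNA Km.
#' @param r required per-enzyme turnover (s^-1).
#' @return list `feasible`, and `required_Tu` (uM) or `deficit` (s^-1).
#' @export
kcat_sufficiency <- function(kcat, Km, r) {
  if (r < 0) stop("r must be >= 0")
  if (kcat > r) {
    list(feasible = TRUE,
         required_Tu = if (r > 0) invert_mm_for_substrate(kcat, Km, r) else 0)
  } else {
    list(feasible = FALSE, deficit = r - kcat)
  }
}
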