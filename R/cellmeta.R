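# Cellular-scale meta-analysis: consensus densities over proteomics
# measurements, per-enzyme turnover rates, unit conversions, transcriptome
# reconstruction from RPKM, codon usage, and the steady-state
# charging-demand simulation.

#' Consensus (violin) density over measurements with errors
#'
#' Builds the Gaussian-mixture density
#' `p(y) = (1/A) sum_i exp(-(y - y_i)^2 / (2 sigma_i^2))` with
#' `A = sum_i sqrt(2 pi) sigma_i`, so that `p` integrates to one. The grid
#' argmax is the consensus peak: the most likely value an experiment would
#' measure given the data points and their errors.
#'
#' @param values measurements `y_i` (e.g. per-enzyme turnover s^-1, or
#'   copies/cell).
#' @param sigma measurement errors; a default 20% of the value is used where
#'   absent (`NA`).
#' @param grid evaluation grid, or `NULL` for
#'   `[min(y) - 4 max(sigma), max(y) + 4 max(sigma)]` at `n_grid` points.
#' @param n_grid grid size for the default grid.
#' @return a `violin_density` list: `grid`, `density`, `A`, `peak`.
#' @export
violin_density <- function(values, sigma = NULL, grid = NULL,
                           n_grid = 2000) {
  if (!length(values)) stop("need at least one measurement")
  if (any(values <= 0)) stop("measurements must be positive")
  if (is.null(sigma)) sigma <- rep(NA_real_, length(values))
  sigma[is.na(sigma)] <- 0.2 * values[is.na(sigma)]
  if (any(sigma <= 0)) stop("errors must be positive")
  if (is.null(grid))
    grid <- seq(min(values) - 4 * max(sigma), max(values) + 4 * max(sigma),
                length.out = n_grid)
  A <- sum(sqrt(2 * pi) * sigma)
  dens <- vapply(grid, function(y)
    sum(exp(-(y - values)^2 / (2 * sigma^2))) / A, numeric(1))
  structure(list(grid = grid, density = dens, A = A,
                 peak = grid[which.max(dens)]),
            class = "violin_density")
}

#' @export
print.violin_density <- function(x, ...) {
  cat(sprintf("Consensus density over %s-point grid: peak at %.4g\n",
              length(x$grid), x$peak))
  invisible(x)
}

#' Per-enzyme turnover rate from usage and copy number
#'
#' `r_i = a_i / n_i`: amino-acid incorporation rate per cell divided by the
#' enzyme copy number.
#'
#' @param a amino-acid usage (molecules/s per cell).
#' @param n enzyme copies per cell (> 0).
#' @return turnover rate (s^-1 per enzyme).
#' @examples
#' turnover_rate(2714.8, 1610)   # ~1.69 s^-1
#' @export
turnover_rate <- function(a, n) {
  if (any(n <= 0)) stop("enzyme count must be > 0")
  if (any(a < 0)) stop("usage must be >= 0")
  a / n
}

#' Convert a concentration rate to molecules per second per cell
#'
#' uM/s times the cell volume in cubic microns times 602.214 molecules per
#' cubic micron per uM (Avogadro's number scaled).
#'
#' @param rate rate in uM/s.
#' @param volume cell volume in um^3.
#' @return molecules per second per cell.
#' @examples
#' conc_rate_to_per_cell(4.478, 1)   # ~2696.6
#' @export
conc_rate_to_per_cell <- function(rate, volume = 1) {
  if (any(volume <= 0)) stop("volume must be > 0")
  rate * volume * MOLEC_PER_UM3_PER_UM
}

#' Read a proteomics measurement table
#'
#' TSV with columns `enzyme`, `value`, `sigma` (optional), `source`
#' (optional), `mu` (optional, growth rate h^-1). Missing `sigma` defaults
#' to 20% of the value.
#' @param path file path.
#' @return data frame.
#' @export
read_proteomics <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("enzyme", "value") %in% names(tab)))
    stop("proteomics table needs columns enzyme, value")
  if (is.null(tab$sigma)) tab$sigma <- NA_real_
  tab$sigma[is.na(tab$sigma)] <- 0.2 * tab$value[is.na(tab$sigma)]
  tab
}

#' Reconstruct a transcriptome from RPKM abundances
#'
#' Normalises RPKM values to fractions `x(i) = n_R(i)/sum_j n_R(j)`, scales
#' by `alpha` so total nucleotide content meets `total_nt`, and rounds copy
#' numbers by largest remainder (keeping the nucleotide total within one
#' mRNA length of the target).
#'
#' @param rpkm named numeric vector of RPKM values (>= 0, at least one
#'   positive).
#' @param lengths mRNA lengths in nt (same names/order).
#' @param total_nt target total nucleotide content of the transcriptome.
#' @return a `transcriptome_spec` list: `fraction`, `alpha`, `copies`,
#'   `lengths`, `total_nt`.
#' @export
build_transcriptome <- function(rpkm, lengths, total_nt) {
  if (length(rpkm) != length(lengths)) stop("rpkm and lengths must match")
  if (any(rpkm < 0) || all(rpkm == 0)) stop("RPKM must be >= 0, not all zero")
  if (any(lengths <= 0)) stop("lengths must be positive")
  x <- rpkm / sum(rpkm)
  alpha <- total_nt / sum(x * lengths)
  ideal <- alpha * x
  copies <- floor(ideal)
  rem <- ideal - copies
  # largest-remainder rounding against the *count* total
  short <- round(sum(ideal)) - sum(copies)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    copies[add] <- copies[add] + 1
  }
  structure(list(fraction = x, alpha = alpha, copies = copies,
                 lengths = lengths, total_nt = total_nt,
                 achieved_nt = sum(copies * lengths)),
            class = "transcriptome_spec")
}

#' Codon usage of a reconstructed transcriptome
#'
#' Counts codons in the coding sequences weighted by transcript copy number.
#' Uses Biostrings when available; sequences must be in frame with lengths
#' divisible by three.
#'
#' @param spec a [build_transcriptome()] result.
#' @param cds named character vector (or `Biostrings::DNAStringSet`) of CDS
#'   sequences matching the transcriptome entries.
#' @return a `codon_usage` list: `counts` (named, weighted), `fractions`.
#' @export
codon_usage <- function(spec, cds) {
  if (inherits(cds, "DNAStringSet")) cds <- as.character(cds)
  cds <- toupper(cds)
  if (is.null(names(cds)) || is.null(names(spec$copies)))
    names(cds) <- names(spec$copies) <- seq_along(cds)
  bad <- which(nchar(cds) %% 3 != 0)
  if (length(bad))
    stop("CDS not a multiple of 3 nt: ", paste(names(cds)[bad], collapse = ", "))
  counts <- new.env()
  for (i in seq_along(cds)) {
    w <- spec$copies[[names(cds)[i]]]
    if (is.null(w) || w == 0) next
    cods <- substring(cds[i], seq(1, nchar(cds[i]), 3),
                      seq(3, nchar(cds[i]), 3))
    tab <- table(cods)
    for (cd in names(tab))
      assign(cd, (get0(cd, envir = counts, ifnotfound = 0)) + w * tab[[cd]],
             envir = counts)
  }
  cnt <- unlist(as.list(counts))
  cnt <- cnt[order(names(cnt))]
  structure(list(counts = cnt, fractions = cnt / sum(cnt)),
            class = "codon_usage")
}

#' Steady-state tRNA charging under a translation demand drain
#'
#' Couples an enzyme's charging scheme to a zero-order Poisson drain that
#' converts free charged tRNA back to free uncharged tRNA at the demand rate
#' (the stand-in for ternary-complex formation and ribosome consumption,
#' which are outside this package's scope). Reports the time-averaged tRNA
#' partition over the final half of the run: free uncharged, free charged,
#' and AARS-bound, plus achieved velocity versus the requirement.
#'
#' @param model an `aars_model`.
#' @param demand consumption rate (molecules/s) of charged tRNA.
#' @param tRNA_total total tRNA concentration (uM).
#' @param enzyme_conc enzyme concentration (uM).
#' @param AA,ATP bath concentrations (uM).
#' @param duration simulated time (s).
#' @param seed integer seed.
#' @param copies_target enzyme copy target for the volume.
#' @return a `demand_report` list: `charged_fraction`, `uncharged_fraction`,
#'   `bound_fraction`, `v` (achieved charging, molecules/s), `r` (demand),
#'   `sustainable`, `capacity` (kcat-limited throughput estimate,
#'   molecules/s).
#' @export
demand_charging_sim <- function(model, demand, tRNA_total = 10,
                                enzyme_conc = 1, AA = 500, ATP = 5000,
                                duration = 60, seed = 1,
                                copies_target = 200) {
  if (demand < 0) stop("demand must be >= 0")
  if (tRNA_total <= 0) stop("tRNA_total must be > 0")
  cond <- assay_conditions(ATP = ATP, AA = AA, PPi = 0, AMP = 0,
                           tRNA = tRNA_total, enzyme_conc = enzyme_conc,
                           copies_target = copies_target,
                           duration = duration, n_samples = 500,
                           demand = demand)
  traj <- simulate_ssa(model, cond, seed = seed)
  late <- traj$times >= 0.5 * max(traj$times)
  # tRNA partition: free pools plus tRNA moieties bound in enzyme states
  bound_per_state <- vapply(traj$scheme$states, function(cp)
    sum(.comp_all(cp) %in% c("R", "Rs")), numeric(1))
  bound <- as.numeric(traj$states[late, , drop = FALSE] %*% bound_per_state)
  free_u <- traj$pools[late, "R"]
  free_c <- traj$pools[late, "Rs"]
  total <- bound + free_u + free_c
  i0 <- which(late)[1]; iN <- length(traj$times)
  v <- (traj$drain[iN] - traj$drain[i0]) / (traj$times[iN] - traj$times[i0])
  # capacity: aminoacylation kcat times enzyme copies
  kcat <- .steady_km(model$scheme, model$rates, "aminoacylation", "tRNA")$kcat
  capacity <- kcat * traj$enzyme_copies
  charged_fraction <- mean(free_c / total)
  structure(list(charged_fraction = charged_fraction,
                 uncharged_fraction = mean(free_u / total),
                 bound_fraction = mean(bound / total),
                 mean_free_uncharged_uM = mean(free_u) / traj$conv,
                 v = v, r = demand,
                 sustainable = demand < 0.95 * capacity &&
                   charged_fraction > 0.05,
                 capacity = capacity,
                 total_tRNA = stats::median(total)),
            class = "demand_report")
}

#' @export
print.demand_report <- function(x, ...) {
  cat(sprintf("Charging demand: r = %.3g molecules/s vs capacity %.3g (%s)\n",
              x$r, x$capacity,
              if (x$sustainable) "sustainable" else "UNSUSTAINABLE"))
  cat(sprintf("  tRNA partition: %.1f%% free charged, %.1f%% free uncharged, %.1f%% AARS-bound\n",
              100 * x$charged_fraction, 100 * x$uncharged_fraction,
              100 * x$bound_fraction))
  invisible(x)
}
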