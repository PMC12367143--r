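# Rate sets: one forward and one backward rate constant per reversible step.
# Units convention (package-wide): time s, concentration uM; bimolecular
# directions carry uM^-1 s^-1, unimolecular directions s^-1.

#' Construct a rate set for a scheme
#'
#' @param scheme an `aars_scheme`.
#' @param k_f,k_b numeric vectors of forward/backward rate constants, either
#'   named by step id (missing steps filled with `default`) or unnamed and of
#'   length `nrow(scheme$steps)`.
#' @param default fill-in value for unspecified rates.
#' @return an `aars_rates` data frame with columns `step_id`, `k_f`, `k_b`,
#'   `units`.
#' @export
rate_set <- function(scheme, k_f = numeric(), k_b = numeric(), default = 1) {
  ids <- scheme$steps$id
  expand <- function(k) {
    if (is.null(names(k)) && length(k) == length(ids)) {
      out <- as.numeric(k); names(out) <- ids; return(out)
    }
    out <- rep(default, length(ids)); names(out) <- ids
    if (length(k)) {
      bad <- setdiff(names(k), ids)
      if (length(bad)) stop("unknown step ids: ", paste(bad, collapse = ", "))
      out[names(k)] <- k
    }
    out
  }
  kf <- expand(k_f); kb <- expand(k_b)
  if (any(!is.finite(kf)) || any(!is.finite(kb)) || any(kf < 0) || any(kb < 0))
    stop("all rates must be finite and >= 0")
  structure(data.frame(step_id = ids, k_f = unname(kf), k_b = unname(kb),
                       units = step_molecularity(scheme)$units,
                       stringsAsFactors = FALSE),
            class = c("aars_rates", "data.frame"))
}

.rate <- function(rates, step_id, dir = c("f", "b")) {
  dir <- match.arg(dir)
  i <- match(step_id, rates$step_id)
  if (any(is.na(i))) stop("unknown step id: ",
                          paste(step_id[is.na(i)], collapse = ", "))
  if (dir == "f") rates$k_f[i] else rates$k_b[i]
}

#' Dissociation constant of a binding step
#'
#' For a binding step with forward rate `k_f` (uM^-1 s^-1) and backward rate
#' `k_b` (s^-1), the dissociation constant is `K_d = k_b / k_f` in uM.
#'
#' @param rates an `aars_rates` set.
#' @param step_id the binding step id.
#' @return K_d in uM.
#' @examples
#' sc <- build_pp_exchange_scheme()
#' rs <- rate_set(sc, k_f = c(aa_bind_E = 0.024), k_b = c(aa_bind_E = 3.2))
#' dissociation_constant(rs, "aa_bind_E")   # ~133.3 uM
#' @export
dissociation_constant <- function(rates, step_id) {
  kf <- .rate(rates, step_id, "f")
  kb <- .rate(rates, step_id, "b")
  if (any(kf == 0)) stop("K_d undefined: forward rate is zero for ",
                         paste(step_id[kf == 0], collapse = ", "))
  kb / kf
}

#' Read / write per-enzyme rate tables
#'
#' TSV with columns `enzyme`, `step_id`, `k_forward`, `k_backward`, `units`.
#' When a `scheme` is supplied, step ids and unit strings are checked against
#' the step molecularity (`"bi/uni"` etc., see [step_molecularity()]).
#'
#' @param path file path.
#' @param scheme optional `aars_scheme` used for validation.
#' @return `read_rate_table`: a named list mapping enzyme name to
#'   `aars_rates`-style data frame; `write_rate_table`: the path, invisibly.
#' @export
read_rate_table <- function(path, scheme = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("enzyme", "step_id", "k_forward", "k_backward", "units")
  if (!all(need %in% names(tab)))
    stop("rate table must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(tab$k_forward) | !is.finite(tab$k_backward) |
               tab$k_forward < 0 | tab$k_backward < 0)
  if (length(bad))
    stop("negative or non-finite rate in row ", bad[1], " (enzyme ",
         tab$enzyme[bad[1]], ", step ", tab$step_id[bad[1]], ")")
  if (!is.null(scheme)) {
    mol <- step_molecularity(scheme)
    j <- match(tab$step_id, mol$id)
    if (anyNA(j)) {
      k <- which(is.na(j))[1]
      stop("unknown step id in row ", k, ": ", tab$step_id[k])
    }
    mism <- which(tab$units != mol$units[j])
    if (length(mism))
      stop("unit mismatch in row ", mism[1], ": step ", tab$step_id[mism[1]],
           " expects ", mol$units[j[mism[1]]], ", got ", tab$units[mism[1]])
  }
  out <- lapply(split(tab, tab$enzyme), function(d) {
    structure(data.frame(step_id = d$step_id, k_f = d$k_forward,
                         k_b = d$k_backward, units = d$units,
                         stringsAsFactors = FALSE),
              class = c("aars_rates", "data.frame"))
  })
  out
}

#' @rdname read_rate_table
#' @param rates an `aars_rates` set (or named list of them).
#' @param enzyme enzyme name column value (single rate set only).
#' @export
write_rate_table <- function(rates, path, enzyme = "enzyme") {
  if (inherits(rates, "aars_rates")) rates <- stats::setNames(list(rates), enzyme)
  tab <- do.call(rbind, lapply(names(rates), function(e) {
    r <- rates[[e]]
    data.frame(enzyme = e, step_id = r$step_id, k_forward = r$k_f,
               k_backward = r$k_b, units = r$units, stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scheme variant implied by an enzyme name
#'
#' argRS, gluRS and glnRS require tRNA for activation; class II enzymes and
#' the class I dimer metRS follow the flip-flop scheme; the class I dimers
#' tyrRS and trpRS behave as monomers.
#' @param enzyme enzyme name, e.g. `"cysRS"`.
#' @return a scheme variant string.
#' @export
enzyme_variant <- function(enzyme) {
  cls1_mono <- c("cysRS", "valRS", "ileRS", "leuRS", "tyrRS", "trpRS")
  trna_req <- c("argRS", "gluRS", "glnRS")
  cls2 <- c("serRS", "thrRS", "proRS", "hisRS", "aspRS", "asnRS", "lysRS",
            "alaRS", "glyRS", "pheRS", "metRS")
  if (enzyme %in% trna_req) "class1_tRNA_required"
  else if (enzyme %in% cls1_mono) "class1_monomer"
  else if (enzyme %in% cls2) "class2_flipflop"
  else stop("unknown enzyme '", enzyme, "'; pass variant explicitly")
}

#' Enzyme model: scheme variant plus rates
#'
#' Bundles an enzyme's scheme variant, rate set, class, and site count. The
#' three class I enzymes argRS, gluRS and glnRS require tRNA for activation;
#' class II enzymes and the class I dimer metRS follow the flip-flop scheme;
#' the class I dimers tyrRS and trpRS behave as monomers (half-of-sites
#' activity / asymmetric tRNA binding).
#'
#' @param enzyme enzyme name (e.g. `"cysRS"`).
#' @param rates an `aars_rates` set matching the enzyme's scheme variant.
#' @param variant scheme variant; if `NULL`, chosen from the enzyme name.
#' @return an `aars_model` list with elements `enzyme`, `class`, `variant`,
#'   `scheme`, `rates`, `sites`, `tRNA_required`.
#' @export
enzyme_model <- function(enzyme, rates, variant = NULL) {
  if (is.null(variant)) variant <- enzyme_variant(enzyme)
  scheme <- build_scheme(variant)
  if (!setequal(rates$step_id, scheme$steps$id))
    stop("rate set does not cover the steps of variant ", variant)
  klass <- if (variant == "class2_flipflop" && enzyme != "metRS") "II" else "I"
  structure(list(enzyme = enzyme, class = klass, variant = variant,
                 scheme = scheme, rates = rates,
                 sites = scheme$site_count,
                 tRNA_required = scheme$tRNA_required),
            class = "aars_model")
}

#' @export
print.aars_model <- function(x, ...) {
  cat("AARS enzyme model:", x$enzyme, "(class", x$class, ",", x$variant, ")\n")
  cat("  sites:", x$sites, " steps:", nrow(x$rates), "\n")
  invisible(x)
}

#' Load a packaged enzyme model
#'
#' Loads one of the rate tables shipped with the package. These tables are
#' synthetic: they were produced by this package's staged fitting procedure
#' ([fit_enzyme()]) so that the simulated assays reproduce published model
#' observables for the enzyme (pyrophosphate-exchange and aminoacylation
#' kcat/Km, single-turnover transfer rate, burst phenotype); they are not the
#' original authors' parameter values.
#'
#' @param enzyme `"cysRS"` or `"hisRS"`.
#' @return an `aars_model`.
#' @export
aars_model <- function(enzyme = c("cysRS", "hisRS")) {
  enzyme <- match.arg(enzyme)
  f <- system.file("extdata",
                   paste0(tolower(enzyme), "_rates_synthetic.tsv"),
                   package = "aarskinetics", mustWork = TRUE)
  rates <- read_rate_table(f)[[enzyme]]
  enzyme_model(enzyme, rates)
}
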