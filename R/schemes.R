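#' @useDynLib aarskinetics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Ligand codes used in state compositions and substrate pools:
#   A  amino acid        T  ATP             P  pyrophosphate
#   M  AMP               D  amino-acid adenylate (enzyme-bound only)
#   R  tRNA              Rs aa-tRNA (charged tRNA)
POOL_SPECIES <- c("A", "T", "P", "M", "R", "Rs")

SCHEME_VARIANTS <- c("class1_monomer", "class1_tRNA_required",
                     "class2_flipflop", "pp_exchange", "single_turnover")

.comp <- function(site1 = character(), site2 = character()) {
  list(site1 = site1, site2 = site2)
}

# Class I state compositions S0..S15 (single catalytic site).
# S0 empty; S5 adenylate only; S10->S11->S13 and S10->S12->S13 are the two
# pyrophosphate-release orderings around amino-acid transfer; S15 is the
# ATP-bound product state on the ATP-before-release path.
.class1_states <- function() {
  list(
    S0  = .comp(),
    S1  = .comp("A"),
    S2  = .comp("T"),
    S3  = .comp(c("A", "T")),
    S4  = .comp(c("D", "P")),
    S5  = .comp("D"),
    S6  = .comp("R"),
    S7  = .comp(c("A", "R")),
    S8  = .comp(c("T", "R")),
    S9  = .comp(c("A", "T", "R")),
    S10 = .comp(c("D", "P", "R")),
    S11 = .comp(c("D", "R")),
    S12 = .comp(c("M", "P", "Rs")),
    S13 = .comp(c("M", "Rs")),
    S14 = .comp("Rs"),
    S15 = .comp(c("T", "Rs"))
  )
}

# A reversible step: forward direction runs from -> to, consuming `consume`
# from the substrate pool and releasing `release` into it ("" = none).
# The backward direction mirrors both.
.step <- function(id, from, to, consume = "", release = "") {
  data.frame(id = id, from = from, to = to, consume = consume,
             release = release, stringsAsFactors = FALSE)
}

.class1_steps <- function(tRNA_required = FALSE) {
  s <- rbind(
    .step("aa_bind_E",     "S0",  "S1",  consume = "A"),
    .step("atp_bind_E",    "S0",  "S2",  consume = "T"),
    .step("atp_bind_EA",   "S1",  "S3",  consume = "T"),
    .step("aa_bind_ET",    "S2",  "S3",  consume = "A"),
    .step("act",           "S3",  "S4"),                  # A+T -> D+P on enzyme
    .step("ppi_rel",       "S4",  "S5",  release = "P"),
    .step("trna_bind_E",   "S0",  "S6",  consume = "R"),
    .step("trna_bind_EA",  "S1",  "S7",  consume = "R"),
    .step("trna_bind_ET",  "S2",  "S8",  consume = "R"),
    .step("trna_bind_EAT", "S3",  "S9",  consume = "R"),
    .step("trna_bind_ED",  "S5",  "S11", consume = "R"),
    .step("aa_bind_ER",    "S6",  "S7",  consume = "A"),
    .step("atp_bind_ER",   "S6",  "S8",  consume = "T"),
    .step("atp_bind_EAR",  "S7",  "S9",  consume = "T"),
    .step("aa_bind_ETR",   "S8",  "S9",  consume = "A"),
    .step("act_trna",      "S9",  "S10"),                 # activation, tRNA on
    .step("ppi_rel_pre",   "S10", "S11", release = "P"),
    .step("tran_ppi",      "S10", "S12"),                 # transfer, PPi bound
    .step("ppi_rel_post",  "S12", "S13", release = "P"),
    .step("tran",          "S11", "S13"),                 # D+R -> M+Rs on enzyme
    .step("amp_rel",       "S13", "S14", release = "M"),
    .step("prod_rel",      "S14", "S0",  release = "Rs"),
    .step("atp_bind_ERs",  "S14", "S15", consume = "T"),
    .step("prod_rel_atp",  "S15", "S2",  release = "Rs")
  )
  if (tRNA_required) s <- s[s$id != "act", , drop = FALSE]
  s
}

.class2_states <- function() {
  st <- .class1_states()[1:15]            # S0..S14, site 2 empty
  st <- lapply(st, function(x) x)
  c(st, list(
    S15 = .comp("Rs", "A"),
    S16 = .comp("Rs", "T"),
    S17 = .comp("Rs", c("A", "T")),
    S18 = .comp("Rs", c("D", "P")),
    S19 = .comp("Rs", "D")
  ))
}

.class2_steps <- function() {
  s1 <- .class1_steps()
  # flip-flop: no direct product release from site 1; release is gated on a
  # new activation event at site 2, after which site 2 becomes the active site
  s1 <- s1[!s1$id %in% c("prod_rel", "atp_bind_ERs", "prod_rel_atp"), ]
  rbind(
    s1,
    .step("aa_bind_s2",       "S14", "S15", consume = "A"),
    .step("atp_bind_s2",      "S14", "S16", consume = "T"),
    .step("atp_bind_s2b",     "S15", "S17", consume = "T"),
    .step("aa_bind_s2b",      "S16", "S17", consume = "A"),
    .step("act_s2",           "S17", "S18"),
    .step("ppi_rel_s2",       "S18", "S19", release = "P"),
    .step("prod_rel_flip_pp", "S18", "S4",  release = "Rs"),
    .step("prod_rel_flip",    "S19", "S5",  release = "Rs")
  )
}

#' Build an enzyme-state reaction scheme
#'
#' Constructs the labelled enzyme-state graph for one of the aminoacylation
#' scheme variants. Class I monomers use 16 states `S0`..`S15` connected by 24
#' reversible steps (48 rate parameters), including both pyrophosphate-release
#' orderings around amino-acid transfer (`S10->S11->S13` and `S10->S12->S13`)
#' and the ATP-before-product-release path through `S15`. The
#' tRNA-required variant (argRS, gluRS, glnRS) omits adenylate formation from
#' tRNA-free states. The class II flip-flop variant follows the class I steps
#' in site 1 of the dimer, retains the charged tRNA there through a second
#' activation at site 2, and releases it from either post-activation site-2
#' state regardless of site-2 tRNA status.
#'
#' @param variant one of `"class1_monomer"`, `"class1_tRNA_required"`,
#'   `"class2_flipflop"`, `"pp_exchange"`, `"single_turnover"`.
#' @param tRNA_required logical; must agree with the variant (it is implied
#'   by `"class1_tRNA_required"` and rejected for class II).
#' @return an object of class `aars_scheme`: a list with elements `variant`,
#'   `states` (named list of per-site ligand compositions), `steps`
#'   (data frame of reversible steps with pool stoichiometry), `site_count`,
#'   and `tRNA_required`.
#' @examples
#' sc <- build_scheme("class1_monomer")
#' length(sc$states)       # 16
#' n_parameters(sc)        # 48
#' @export
build_scheme <- function(variant = SCHEME_VARIANTS, tRNA_required = FALSE) {
  variant <- match.arg(variant)
  if (variant == "class2_flipflop" && isTRUE(tRNA_required))
    stop("tRNA-required activation is defined only for class I (argRS/gluRS/glnRS)")
  if (variant == "class1_tRNA_required") tRNA_required <- TRUE
  if (variant == "class1_monomer" && isTRUE(tRNA_required))
    variant <- "class1_tRNA_required"

  # schemes are immutable; construction and validation run once per variant
  cached <- get0(variant, envir = .scheme_cache, ifnotfound = NULL)
  if (!is.null(cached)) return(cached)

  sch <- switch(variant,
    class1_monomer = list(states = .class1_states(),
                          steps = .class1_steps(FALSE), site_count = 1L),
    class1_tRNA_required = list(states = .class1_states(),
                          steps = .class1_steps(TRUE), site_count = 1L),
    class2_flipflop = list(states = .class2_states(),
                          steps = .class2_steps(), site_count = 2L),
    pp_exchange = list(states = .class1_states()[1:6],
                          steps = .class1_steps(FALSE)[1:6, ], site_count = 1L),
    single_turnover = {
      st <- .class1_states()[c("S0", "S5", "S11", "S13", "S14")]
      sp <- .class1_steps(FALSE)
      list(states = st,
           steps = sp[sp$id %in% c("trna_bind_ED", "tran", "amp_rel",
                                   "prod_rel"), ],
           site_count = 1L)
    })

  out <- structure(list(variant = variant, states = sch$states,
                        steps = sch$steps, site_count = sch$site_count,
                        tRNA_required = isTRUE(tRNA_required)),
                   class = "aars_scheme")
  validate_scheme(out)
  assign(variant, out, envir = .scheme_cache)
  out
}

.scheme_cache <- new.env(parent = emptyenv())

#' @rdname build_scheme
#' @export
build_pp_exchange_scheme <- function() build_scheme("pp_exchange")

#' @rdname build_scheme
#' @export
build_single_turnover_scheme <- function() build_scheme("single_turnover")

#' Number of kinetic rate parameters in a scheme
#'
#' Each reversible step carries a forward and a backward rate constant.
#' @param scheme an `aars_scheme`.
#' @return integer parameter count (2 per step).
#' @export
n_parameters <- function(scheme) {
  stopifnot(inherits(scheme, "aars_scheme"))
  2L * nrow(scheme$steps)
}

# catalytic conversions permitted on-enzyme without pool exchange
.CONVERSIONS <- list(
  activation = list(minus = c("A", "T"), plus = c("D", "P")),
  transfer   = list(minus = c("D", "R"), plus = c("M", "Rs"))
)

.comp_all <- function(comp) c(comp$site1, comp$site2)

.multiset_diff <- function(a, b) {
  # returns list(plus, minus): elements of a not in b and vice versa
  for (x in b) {
    i <- match(x, a)
    if (!is.na(i)) a <- a[-i] else attr(b, "rest") <- c(attr(b, "rest"), x)
  }
  list(plus = a, minus = attr(b, "rest") %||% character())
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Validate an enzyme-state scheme
#'
#' Checks that every step's endpoints exist, that per-step composition change
#' balances its pool stoichiometry (allowing the two on-enzyme catalytic
#' conversions, activation and transfer), that each site holds at most one of
#' tRNA/aa-tRNA and at most one of ATP/AMP/adenylate, and that the state graph
#' is connected.
#'
#' @param scheme an `aars_scheme`.
#' @return the scheme, invisibly; errors on violation.
#' @export
validate_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "aars_scheme"))
  st <- scheme$states
  sp <- scheme$steps
  if (anyDuplicated(sp$id)) stop("duplicate step ids")
  bad <- setdiff(c(sp$from, sp$to), names(st))
  if (length(bad)) stop("dangling step endpoints: ", paste(bad, collapse = ", "))

  for (comp in st) {
    for (site in comp) {
      if (sum(site %in% c("R", "Rs")) > 1L)
        stop("a site may hold at most one of tRNA/aa-tRNA")
      if (sum(site %in% c("T", "M", "D")) > 1L)
        stop("a site may hold at most one of ATP/AMP/adenylate")
    }
  }

  for (i in seq_len(nrow(sp))) {
    d <- .multiset_diff(.comp_all(st[[sp$to[i]]]), .comp_all(st[[sp$from[i]]]))
    gained <- sort(d$plus); lost <- sort(d$minus)
    pool_in <- sp$consume[i]; pool_out <- sp$release[i]
    ok <- FALSE
    # plain binding/release: composition change mirrors the pool event
    if (identical(gained, sort(pool_in[nzchar(pool_in)])) &&
        identical(lost, sort(pool_out[nzchar(pool_out)]))) ok <- TRUE
    # catalytic conversion, optionally with a pool release folded in
    for (cv in .CONVERSIONS) {
      if (!ok && identical(gained, sort(cv$plus)) &&
          identical(lost, sort(cv$minus)) &&
          !nzchar(pool_in) && !nzchar(pool_out)) ok <- TRUE
    }
    # idealised single-step turnover (test-oracle mechanisms): bound tRNA
    # converted and released as aa-tRNA in one catalytic step
    if (!ok && !length(gained) && identical(lost, "R") &&
        identical(pool_out, "Rs") && !nzchar(pool_in)) ok <- TRUE
    if (!ok) stop("step ", sp$id[i], " does not balance composition vs pools")
  }

  # connectivity by breadth-first traversal over reversible steps
  start <- if ("S0" %in% names(st)) "S0" else names(st)[1]
  seen <- start
  repeat {
    nxt <- unique(c(sp$to[sp$from %in% seen], sp$from[sp$to %in% seen]))
    new <- setdiff(nxt, seen)
    if (!length(new)) break
    seen <- c(seen, new)
  }
  if (length(setdiff(names(st), seen)))
    stop("state graph not connected: unreachable ",
         paste(setdiff(names(st), seen), collapse = ", "))
  invisible(scheme)
}

#' States reachable from a start state
#'
#' Breadth-first traversal of the reversible step graph.
#' @param scheme an `aars_scheme`.
#' @param from starting state label (default `"S0"`).
#' @return character vector of reachable state labels (including `from`).
#' @export
reachable_states <- function(scheme, from = "S0") {
  sp <- scheme$steps
  seen <- from
  repeat {
    nxt <- unique(c(sp$to[sp$from %in% seen], sp$from[sp$to %in% seen]))
    new <- setdiff(nxt, seen)
    if (!length(new)) break
    seen <- c(seen, new)
  }
  seen
}

#' Per-direction molecularity of each step
#'
#' A direction is bimolecular when it consumes a pool species (its rate
#' constant is in per-micromolar per-second); otherwise unimolecular
#' (per-second).
#' @param scheme an `aars_scheme`.
#' @return data frame with columns `id`, `fwd_bimolecular`, `bwd_bimolecular`,
#'   and the conventional `units` string `"<fwd>/<bwd>"` with entries `"bi"`
#'   or `"uni"`.
#' @export
step_molecularity <- function(scheme) {
  sp <- scheme$steps
  fwd <- nzchar(sp$consume)
  bwd <- nzchar(sp$release)   # backward re-binds what forward released
  data.frame(id = sp$id, fwd_bimolecular = fwd, bwd_bimolecular = bwd,
             units = paste0(ifelse(fwd, "bi", "uni"), "/",
                            ifelse(bwd, "bi", "uni")),
             stringsAsFactors = FALSE)
}

#' Export a scheme as a plain-text edge list
#'
#' @param scheme an `aars_scheme`.
#' @return data frame (from_state, to_state, step_id, pool_consumed,
#'   pool_released) suitable for writing as TSV.
#' @export
scheme_edge_list <- function(scheme) {
  data.frame(from_state = scheme$steps$from, to_state = scheme$steps$to,
             step_id = scheme$steps$id, pool_consumed = scheme$steps$consume,
             pool_released = scheme$steps$release, stringsAsFactors = FALSE)
}

#' @export
print.aars_scheme <- function(x, ...) {
  cat("AARS reaction scheme:", x$variant, "\n")
  cat("  states:", length(x$states), " steps:", nrow(x$steps),
      " rate parameters:", n_parameters(x), "\n")
  invisible(x)
}
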