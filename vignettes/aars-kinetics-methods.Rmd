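---
title: "Modelling aminoacylation kinetics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling aminoacylation kinetics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aarskinetics)
```

## The model

Aminoacyl-tRNA synthetases (AARS) charge tRNAs in two catalytic steps:
activation of the amino acid with ATP to form an enzyme-bound
aminoacyl-adenylate (releasing pyrophosphate), and transfer of the amino
acid from the adenylate to the tRNA 3' end (releasing AMP and the charged
tRNA). Each step has its own kcat and Km, which is why the pyrophosphate
exchange assay (a proxy for activation) and the aminoacylation assay (the
full cycle) report kcat values that differ by an order of magnitude or more
for the same enzyme.

This package represents an enzyme as a labelled state graph. For class I
monomers there are 16 states `S0`..`S15` joined by 24 reversible steps, i.e.
48 rate constants. The graph encodes three mechanistic features that matter
for reproducing measured Kms:

* **random substrate binding** — amino acid, ATP and tRNA bind in any
  order; an ordered-binding reduction depresses the apparent tRNA Km by an
  order of magnitude relative to measurements;
* **dual pyrophosphate-release paths** — with tRNA bound, PPi release can
  precede (`S10 -> S11 -> S13`) or follow (`S10 -> S12 -> S13`) amino-acid
  transfer; collapsing this to one path depresses the apparent ATP and
  amino-acid Kms;
* **ATP-assisted product release** — ATP can bind before the charged tRNA
  leaves (`S14 -> S15 -> S2`), which keeps the enzyme from being
  product-inhibited at cellular AMP/PPi concentrations.

Dimeric class II enzymes (and the class I dimer metRS) follow a kinetic
flip-flop: site 1 runs the class I steps, but the charged tRNA is only
released after a fresh activation in site 2, upon which site 2 becomes the
active site. We allow release from either post-activation site-2 state,
with or without PPi still bound, regardless of whether tRNA has arrived at
site 2. Class I dimers tyrRS and trpRS are treated as monomers
(half-of-sites activity). argRS, gluRS and glnRS require tRNA for
activation, so their schemes have no adenylate formation from tRNA-free
states. Editing/proofreading and enzyme conformational substates are
deliberately outside the model.

The composition of each state (which of amino acid, ATP, PPi, AMP,
adenylate, tRNA, aa-tRNA each site holds) is what the code validates, not
the labels: every step must balance its composition change against its pool
stoichiometry, with activation (`A+T -> D+P`) and transfer (`D+R -> M+R*`)
as the two permitted on-enzyme conversions. A useful corollary, enforced in
the tests, is that amino-acid, adenosine, tRNA and phosphate moieties
balance across every step and therefore along every cycle.

### A note on one ambiguous edge

The ATP-before-release path is described as returning to the start of the
cycle. Composition dictates that releasing the charged tRNA from the
ATP-bound product state (`S15` = E·ATP·aa-tRNA) leaves E·ATP (`S2`), so the
edge is `S15 -> S2`; the cycle closes through `S2` rather than `S0`.
Similarly, 24 reversible steps require omitting one conceivable binding
edge; we omit tRNA binding to the transient adenylate·PPi state `S4`, the
shortest-lived species in the scheme.

## Simulation

`simulate_ssa()` is an exact Gillespie direct-method sampler over enzyme
states (C++ core). Abundant substrates — ATP, amino acid, PPi, AMP, held at
micromolar-to-millimolar concentrations in the assay protocols — are
treated as constant baths by default, making their binding pseudo-first
order; tRNA, charged tRNA and the enzyme are discrete. This keeps the event
rate independent of millimolar pool sizes while preserving exactness for
the species whose fluctuations matter. A flag (`bath`) makes any pool
discrete or constant.

The protocols never state a simulation volume; we choose it so the enzyme
has at least ~100–2000 copies at the assay concentration (e.g. 200 copies
at 10 nM), recorded in the conditions object. `simulate_ode()` integrates
the matching mean-field equations (deSolve::lsoda) with cumulative per-step
flux accumulators, so velocities are measured identically in both engines;
the tests require SSA ensemble means to agree with the ODE within 5% at
1000 enzyme copies.

Exchange velocity is measured by counting reverse-activation firings
(adenylate + PPi back to ATP + amino acid) rather than tracking labelled
PP*/ATP* explicitly: at time zero the labelled flux is the exchange speed
times the specific activity, so the two differ only by a known constant,
and event counting has lower variance. Initial velocities come from a
linear fit (with intercept, so a pre-steady-state burst does not bias the
slope) over a window that ends when 5% of the limiting pool has been
consumed, or at half of the short assay duration, whichever is earlier.

## Assays and estimators

* **kcat/Km** (`run_km_assay()`): 10 stochastic replicates per
  concentration over a grid `c(0.2, 0.5, 1, 2, 5)` times a pilot-estimated
  Km (the published protocols state concentration ranges, not grids; this
  grid puts leverage on both sides of Km). Velocities are fit on the
  Woolf–Hanes plot ([S]/v against [S]) by unweighted ordinary least
  squares — the plain linearisation, with kcat = 1/slope and
  Km = intercept/slope; standard errors come from the regression covariance
  by the delta method. Defaults: exchange at [PP] 2 mM, [ATP] 5 mM,
  [AA] 0.5 mM; aminoacylation at [ATP] 5 mM, [AA] 0.5 mM, [tRNA] 10 µM;
  enzyme 10 nM. Where a protocol states a range ("0.5–1 mM"), the lower
  bound is the default.
* **single turnover** (`run_single_turnover()`): enzyme pre-loaded with
  adenylate at 50 µM mixed with 5 µM tRNA ("transfer"), or everything mixed
  at once from the free enzyme ("chem"); the charged-tRNA curve is fit to
  `A(1 - exp(-B t))` by Levenberg–Marquardt from a log-linearised start,
  giving k_tran or k_chem.
* **burst** (`run_burst_assay()`): [AA] 500 µM, [ATP] 5 mM, [tRNA] 10 µM,
  [E] 0.25 µM, millisecond sampling over 2 s. The late half of the product
  curve is checked for slope stationarity (relative change < 10% across
  three windows), fit linearly, and extrapolated to t = 0; the intercept
  per enzyme site is the burst amplitude. Amplitude ≥ 0.5/site declares a
  burst — a true burst traps about one product per site, and the published
  figures are classified qualitatively, so 0.5 is this package's
  operationalisation of that phenotype. tRNA is held constant over this
  short window so the steady phase stays linear.

Product is counted at the transfer chemistry (enzyme-bound plus free
charged tRNA), matching quench assays, which is also why a burst is visible
at all: the charged tRNA accumulates on the enzyme behind the slow release
step.

## Staged parameter identification

The full class I scheme has 48 rate constants, but the three assays probe
nested subschemes: the single-turnover transfer subscheme (8 parameters),
the tRNA-free exchange subscheme (12), and the full cycle (48). Fitting
proceeds in that order, never revisiting a parameter fixed earlier, over a
reduced, tied parameterisation: activation with and without tRNA is
identical (an explicit modelling assumption), binding steps for one ligand
share k_on and K_d, and parameters with little effect on the observables
default to experimental dissociation constants with k_on = 1 µM⁻¹s⁻¹
unless constrained. The two transfer routes (PPi released before or after
the chemistry) are separate components: the single-turnover assay starts
from the PPi-free adenylate and measures only one of them, and the
PPi-retaining route is a genuine degree of freedom that the burst
amplitude is sensitive to (`rate_constraint()` pins measured K_d/k_on/k_off
values, e.g. threonine on thrRS at 0.024 µM⁻¹s⁻¹ and 3.2 s⁻¹).

Design choices worth knowing:

* **What stage 1 actually identifies.** At 50 µM enzyme the transfer curve
  saturates binding, so it identifies the transfer rate alone; AMP release
  and product release sit downstream of the counted chemistry and remain
  free for stage 3. The tRNA association rate to the adenylate state is set
  in the curve's insensitive regime, scaled to the capture efficiency
  (kcat/Km for tRNA) that the aminoacylation targets will demand.
* **Breaking the exchange degeneracy.** The exchange observables pin only
  the equilibrium combination of activation and PPi-release speeds; slow
  solutions exist that would throttle the full cycle. The measured
  chemistry rate (k_chem ≈ k_tran) says the steps upstream of transfer are
  fast, so stage 2 penalises activation or PPi release slower than ~5x
  that reference.
* **Search algorithm.** Per stage: an analytic warm start derived from the
  targets, log-uniform random search over the stage's sensitive dimensions
  (bounds spanning roughly 10⁻² to 10⁴ in natural units, association rates
  capped near the diffusion limit), two passes of coordinate golden-section
  refinement, and a Nelder–Mead polish on the log scale. The loss is the
  sum of squared log-ratios between predicted and target observables, plus
  a burst-phenotype penalty at the 0.5/site threshold when a burst
  expectation is given. Everything is seeded; the same seed reproduces the
  same rate set bitwise.
* **Deterministic inner loop.** During search, observables come from
  steady-state mean-field velocities with substrates held at their nominal
  concentrations (the initial-velocity idealisation) on Woolf–Hanes grids
  centred on the target Kms. The stochastic assay protocol is then the
  confirmation layer: the packaged tables are checked by the full
  10-replicate SSA assays in the acceptance tests.
* **Default tolerance** 15% per observable, comparable to the spread of
  published measurements for the same enzyme.

Rate-level identifiability is not claimed — many rate sets reproduce the
same observables — so recovery tests are at the observable level: refitting
a random synthetic ground-truth enzyme to its own simulated observables
must reproduce those observables, not the underlying rates.

### The packaged cysRS and hisRS tables

The per-enzyme rate tables shipped in `inst/extdata/` are synthetic: they
were produced by `fit_enzyme()` targeting published model observables for
E. coli cysRS (exchange kcat 85 s⁻¹, Km 27/279 µM for amino acid/ATP;
aminoacylation kcat 2.96 s⁻¹, Km_trna 1.05 µM, Km_aa 16 µM; k_tran
14.9 s⁻¹; burst) and hisRS (exchange kcat 130 s⁻¹, Km 37/498 µM;
aminoacylation kcat 7.2 s⁻¹, Km_trna 0.44 µM, Km_aa 7.7 µM; k_tran
18.8 s⁻¹; no burst). They are not the original study's parameter values,
which is also why the filenames carry the `_synthetic` suffix.

## Michaelis–Menten reduction

The full scheme is well approximated by the MM form, and
`derive_mm_from_full_model()` packages the aminoacylation fits as MM
parameters. Two identities matter for cellular reasoning: solving
`v = kcat S/(Km+S)` for S gives the free uncharged tRNA a model implies
from its turnover (`invert_mm_for_substrate()`), and holding the working
point (turnover r at free tRNA T_u) fixed while changing Km rescales
`kcat = r (Km + T_u)/T_u` (`rescale_kcat()`) — the rescaled pair reproduces
r at T_u exactly, which the tests assert to machine precision. Multiple
isoacceptors compete through a shared denominator
(`mm_multi_isoacceptor()`), with ATP assumed saturating at this level.
AMP/PPi inhibition exists only in the full scheme.

## Cellular meta-analysis

Per-enzyme in vivo turnover is amino-acid usage per cell over enzyme copy
number (`turnover_rate()`), with µM/s converted to molecules/s via
602.214 molecules per µm³ per µM (`conc_rate_to_per_cell()`). Proteomics
measurements disagree substantially between groups, so a consensus is
taken as the peak of a Gaussian-mixture density over the measurements with
their errors (`violin_density()`; 20% default error where none is
reported). The evaluation grid spans the data padded by four times the
largest error, at 2000 points — the peak is a grid argmax, so its
resolution is the grid spacing.

`build_transcriptome()` reconstructs mRNA copy numbers from RPKM fractions
scaled to a total-nucleotide target, rounding by largest remainder (the
scaling yields non-integers; largest-remainder keeps the total within one
mRNA length). `codon_usage()` then gives copy-weighted codon counts for
cross-checking against measured codon bias.

`demand_charging_sim()` couples a charging scheme to a zero-order Poisson
drain that converts free charged tRNA back to uncharged at a stated demand
rate. This is an explicit simplification: it stands in for ternary-complex
formation, EF-Tu cycling and ribosome consumption, which belong to a full
translation model and are out of scope here. Consequently the simulation
reports only the three-way partition (free uncharged / free charged /
AARS-bound) and sustainability against the kcat·E0 capacity; it does not
reproduce ribosome-bound or ternary-complex pools, in vivo charged
fractions, or elongation speeds. Demands beyond capacity are reported as
unsustainable (the charged pool collapses), not raised as errors.

## What the synthetic data does and does not show

The synthetic generators (`make_mm_oracle_fixture()`,
`make_synthetic_enzyme()`) emulate clean in vitro kinetics: exact
mass-action schemes, no pipetting noise, no temperature dependence (the
published measurement temperatures are metadata only), no crowding. Tests
passing on them demonstrate that the estimators invert what the simulator
generates and that the fitting procedure is self-consistent — not that the
packaged rate constants are uniquely correct for the real enzymes, nor
that in vivo behaviour (where crowding, compartmentalisation and the full
translation network operate) is captured.

## Numerical choices and problem sizes

Tolerances: lsoda at rtol 1e-8 (1e-9 for the steady-state inner loop);
steady-state velocities accepted when the flux changes by <0.2% over a
doubling of the integration horizon; exponential fits bounded below at
1e-12 with at most 200 LM iterations. Degenerate inputs fail loudly: zero
forward rate has no dissociation constant, all-zero RPKM has no
transcriptome, constant-zero time courses have no exponential fit, and a
Hanes line with non-positive slope or intercept is returned as invalid
rather than coerced.

Default problem sizes keep every check at desk scale: assays use 200
enzyme copies (500 for burst, 2000 for single turnover), 10 replicates,
and seconds of simulated time; the SSA/ODE consistency check uses 1000
copies; the synthetic-recovery property uses reduced search budgets with
the same staged algorithm. All sizes are arguments, so larger runs are one
call away.
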