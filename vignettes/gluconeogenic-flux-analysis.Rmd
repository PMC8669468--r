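---
title: "Quantifying carbon and energy flux partitioning during gluconeogenic growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying carbon and energy flux partitioning during gluconeogenic growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Bacteria such as *Pseudomonas putida* and *Comamonas testosteroni* grow
faster on gluconeogenic substrates (organic acids that enter metabolism at
the TCA cycle, such as succinate) than on glycolytic sugars. Understanding
why requires quantifying how carbon entering the TCA cycle is partitioned
between oxidation for energy, biosynthetic precursor supply, and the uphill
gluconeogenic route to sugar phosphates — and how the NADH, NADPH and ATP
budgets close when the oxidative pentose phosphate pathway, the canonical
NADPH source of sugar metabolism, is inactive or absent.

`emumfa` implements the complete quantitative chain for this question:

1. atom-mapped central-carbon network models with cofactor stoichiometry
   and biomass drains (`read_flux_model()`, bundled reconstructions for
   both species);
2. elementary-metabolite-unit (EMU) simulation of mass isotopomer
   distributions (MIDs) under parallel ^13^C tracers (`emu_network()`,
   `emu_simulate()`), with an exhaustive isotopomer enumerator as an
   independent oracle (`simulate_isotopomers()`);
3. natural-abundance correction (`correct_natural_abundance()`);
4. multi-start variance-weighted flux estimation with a chi-square
   goodness-of-fit verdict, profile-likelihood confidence intervals,
   carry-over influx gating and flux precision scores (`fit_fluxes()`,
   `flux_confidence_interval()`, `gate_unlabeled_influx()`,
   `precision_score()`);
5. biomass demand and cofactor/ATP accounting with transhydrogenase
   closure (`biomass_efflux()`, `cofactor_ledger()`), plus the adenylate
   energy charge (`energy_charge()`);
6. growth, uptake and secretion physiology (`fit_growth()`,
   `exchange_rates()`, `carbon_partition()`);
7. differential protein abundance by a two-component-uncertainty Z score
   with q-value control (`differential_proteins()`);
8. a synthetic-data generator that emulates the full study design so every
   stage is testable end to end (`pputida_succinate_demo()`).

The numbered scripts under `analysis/` run these stages as a narrative
workflow and write their tables under `results/`.

## The steady-state flux model

A network of $n$ reactions with stoichiometric matrix $S$ over the balanced
(intracellular, steady-state) metabolites satisfies $S v = 0$. Fluxes are
normalized so that substrate uptake equals 100; conversion to
mmol\,gCDW^-1^\,h^-1^ happens only at reporting time via the measured
uptake rate (`scale_fluxes()`). The constraint system (steady state plus
equality constraints such as the uptake value) is QR-factorized with column
pivoting; the non-pivot columns become *free fluxes*, and completing any
free-flux assignment satisfies the constraints exactly. Reversible
reactions carry a net flux plus a non-negative exchange flux; the forward
and backward directed fluxes are $\max(v,0)+x$ and $\max(-v,0)+x$.

The bundled model files are *reconstructions* of the two species'
central-carbon networks assembled from their known pathway topology —
uptake, EMP, ED, oxidative and non-oxidative PP, TCA, glyoxylate shunt,
anaplerosis/cataplerosis, proxy amino-acid drains, overflow routes and
carry-over influx points — at a declared granularity that yields 63
reactions for *P. putida* and 51 for *C. testosteroni* (the *C.
testosteroni* file omits the oxidative PP pathway, the ED pathway and
pyruvate/PEP carboxylation, which its genome lacks). They are documented as
reconstructions in their JSON headers, not as deposited models. Succinate
and fumarate are symmetric molecules; every reaction producing them lists
both atom-map orientations at equal weight, which is how the classic
scrambling of `[2,3-13C]` label into all four carbons arises. The malic
enzyme is modeled NAD-dependent, so TCA-derived NADPH comes only from
isocitrate dehydrogenase and the anabolic NADPH deficit that the
transhydrogenase must close is substantial — the regime the species under
study operate in. FADH~2~ and ubiquinol are lumped with NADH into one
respiratory pool.

Most near-equilibrium steps are written in their gluconeogenic direction
and fixed there: with succinate feeding, the EMP and non-oxidative PP
reactions only ever run toward sugar phosphates, and their exchange fluxes
are not identifiable from the tracer pair used here. The two reactions
whose reversibility carries real information under these tracers — the
fumarase and malate dehydrogenase steps that scramble the succinate
backbone — keep explicit exchange coordinates.

## EMU simulation and its oracle

The EMU decomposition walks atom maps backwards from the observed fragments
to the tracer boundary, collecting the minimal set of (metabolite, carbon
subset) units. Units of equal size satisfy a linear balance
$A(v)X = -B(v)Y$ where $Y$ stacks tracer-boundary MIDs and convolutions of
smaller units; the cascade is solved size by size with dense factorizations
(one per size block, shared across tracers, since $A$ and $B$ depend only on
the fluxes). Pools with zero turnover — a shut-down pathway branch — are
treated as unlabeled; they contribute nothing downstream because every
consuming flux is zero too, and this keeps the simulation well defined on
the boundary of the feasible region where real solutions live.

Simulated MIDs are natural-abundance-free and compared against corrected
measurements (natural ^13^C abundance 0.0107, carbon skeleton only; the
correction is the inverse of the binomial convolution matrix with negative
clipping and renormalization). Tracer impurity is handled at the tracer
boundary: each labeled position carries the configured enrichment (default
0.99).

The package ships a brute-force reference: `simulate_isotopomers()`
enumerates all $2^n$ positional isotopomers per metabolite and iterates the
steady-state balance to a fixed point. It shares no code path with the EMU
cascade and is exponential in carbon count, so it runs only on the bundled
toy networks (up to 12 balanced carbons); on those, EMU and enumeration
agree to better than $10^{-8}$ across seeded random feasible flux draws,
including scrambling, cleavage/condensation, reversible exchange and
unlabeled influx.

## Flux estimation

The objective is the variance-weighted sum of squared residuals over every
MID entry of every tracer and replicate ("six sets of isotopomer data" in
the default design: two tracers times three replicates) plus any rate
measurements. Fitting runs 100 Levenberg–Marquardt solves from random
initial values (seeded, hence bit-reproducible), keeps the best
sign-feasible solution, and declares statistical acceptance when the SSR
falls below the 95% chi-square quantile at
dof = (independent residuals) − (free parameters); each fragment's MID
contributes length−1 independent entries because fractions sum to one.

Several numerical choices matter and were made deliberately:

- **No optimizer boxes.** Box-projected Levenberg–Marquardt wedges
  parameters at bounds in this problem's curved, ill-conditioned valleys.
  Exchange coordinates are therefore carried as unbounded logits of
  $e = x/(1+x)$ (capped at 0.9999), and irreversibility and flux-magnitude
  limits enter the residual vector as smooth hinge penalties (weight 10 per
  unit of violation, magnitude limit 500, carry-over influxes capped at the
  uptake). A residual sign violation of up to 0.5 flux units
  (0.5% of uptake) is tolerated in the reported solution.
- **Feasible, rate-consistent starts.** Uniform random draws are projected
  onto the sign-feasible, rate-consistent affine manifold by an iterated
  active-set linear least squares before the nonlinear solve; newly
  activated constraints receive randomized positive targets so the starts
  stay diverse.
- **Weak L2 regularization** (0.03 per flux unit, and on the exchange
  logits) removes the otherwise perfectly flat directions spanned by
  label-invisible futile cycles (e.g. exactly opposed kinase/synthase
  pairs), pinning the reported solution near the minimum-norm point of the
  optimal ridge. At the measurement weights used, this contributes far less
  than one noise unit to any identifiable flux.
- **Two-phase multi-start**: a 50-iteration pass over all starts, then
  full-depth polishing of the eight leaders. Ties break to the lowest start
  index.
- The SD floor on MID fractions is 0.005 (configurable); biomass-efflux
  rate SDs can be inflated exactly 2x via `biomass_sd_factor` to mirror the
  two-standard-deviation imprecision allowance.

In the benchmark protocol the biomass drains are *constrained* at the
calculated biosynthetic efflux (growth rate times macromolecular
composition), which is how the efflux enters the analysis chain; fitting
them as soft rate residuals remains supported and is exercised on the toy
benchmarks. Fixing them reduces the nonlinear search space to the
labeling-informed fluxes (around a dozen parameters), which 100 random
starts solve reliably.

Confidence intervals are profile-likelihood: the flux of interest is added
as an equality constraint, all other parameters are re-optimized
(warm-started, since free fluxes are actual reactions), and the 95% bound
is located by bisection where the SSR exceeds the optimum by
$\chi^2_1(0.95) = 3.84$ (tolerance 0.01 flux units by default). Bounds that
run into the magnitude limit are flagged; structurally non-identifiable
fluxes — the parallel cataplerosis routes malic enzyme / OAA decarboxylase /
PEP carboxykinase form a genuine equal-SSR continuum under this tracer
pair — show up exactly this way, and downstream "recovery" checks exclude
box-flagged or very wide intervals. The flux precision score between two
conditions is the squared ratio of 95% interval widths.

## Carry-over gating

Unlabeled medium carry-over is modeled by influx reactions feeding malate,
pyruvate, G6P, DHAP and acetyl-CoA. Gating decides which influxes are free
in the fit: an influx is enabled iff the mean M+0 fraction of its
metabolite strictly exceeds 0.01. That threshold is meaningful only on a
fully labeled tracer: under positional tracers the TCA intermediates carry
~10% M+0 from ordinary multi-turn label loss to CO~2~. The pipeline
therefore gates on a dedicated `[U-13C4]`-succinate dataset, in which any
unlabeled fraction beyond the purity floor must be scavenged carbon — the
same logic as the wet washing experiments the gate mimics.

## Cofactor ledger and energy charge

From an absolute flux vector, production and consumption of NADH/UQH~2~,
NADPH and ATP are summed from the signed per-flux reaction stoichiometries;
anabolic demand (per-precursor cofactor coefficients plus polymerization
ATP, all linear in the growth rate) is added to consumption. The NADPH
deficit is closed by a net NADH-to-NADPH transhydrogenase flux, after which
NADPH production equals consumption identically. Respirable NADH/UQH~2~
(production minus all post-closure consumption) yields ATP at a fixed P/O
ratio of 1.5 (configurable); total ATP production is oxidative plus
substrate-level phosphorylation, and the surplus over consumption absorbs
maintenance and unmodeled processes, an exact identity. SDs propagate as
root-sum-of-squares of contributing flux SDs, ignoring flux-flux
correlations (a documented simplification). Pathway attribution assigns
transhydrogenase-derived NADPH (and oxidative ATP) to the pathways that
produced the NADH consumed, so the TCA cycle's dominance of the energy
budget is visible directly.

The adenylate energy charge is
$([\mathrm{ATP}] + 0.5[\mathrm{ADP}])/([\mathrm{ATP}]+[\mathrm{ADP}]+[\mathrm{AMP}])$,
scale-invariant and bounded in $[0,1]$.

## Physiology and proteomics

Growth rates come from the log-linear balanced-growth fit on an explicit
exponential window (flagged below $R^2 = 0.95$); the exponential window is
a user decision, not automatic changepoint detection. OD converts to dry
weight by ordinary linear regression (flagged at $R^2 \le 0.750$). Specific
exchange rates use the balanced-growth estimator $q = \mu\,|dC/dX|$ from
the regression of concentration on biomass, with uptake reported positive
under a role flag; carbon partitioning of uptake into biomass, secretion
and "other" (CO~2~ and unaccounted) is computed on carbon-mmol scales and
is a probability vector by construction.

The proteomics statistic divides the between-condition difference in mean
log2 abundance by the *sum* of the two per-condition uncertainties — as the
assay defines it, not a root-sum-of-squares across conditions — where each
condition's uncertainty is the root-square sum of the between-replicate SD
and the mean within-replicate standard error. Z maps to two-sided
standard-normal p-values; multiplicity control uses Storey q-values
(smoother pi0 estimate over a lambda grid; Benjamini–Hochberg available),
with significance at q <= 0.05. q-values control the false discovery rate —
the strongest claim the procedure supports, whatever terminology one
attaches to it. Proteins detected in fewer than two replicates of a
condition are demoted to presence/absence calls.

## The synthetic benchmark

`pputida_succinate_demo()` fixes the study conditions: growth rate 0.55
h^-1^ with a 3 h lag, succinate uptake 9.5 mmol gCDW^-1^ h^-1^, two
positional tracers (`[1,4-13C4]`- and `[2,3-13C4]`-succinate, purity 0.99)
with three replicates each, additive truncated-Gaussian MID noise of SD
0.005 followed by renormalization, multiplicative lognormal OD noise of 2%,
a `[U-13C4]` gating dataset, a 1000-protein two-condition proteome with 10%
true shifts of four summed-uncertainty units, and adenylate pools built to
an energy charge of 0.68. The flux truth is the exactly balanced pattern
obtained by fixing uptake, the composition-derived biomass drains and the
genome-implied shut routes (glyoxylate shunt, oxidative PP, ED): the
steady-state constraints then determine a reductive TCA flux of about 128%
of uptake and a gluconeogenic PEP-to-EMP flux of about 20% — the
qualitative shape of the measured phenotype, without claiming numeric
equality to any deposited value. Carry-over scenarios add unlabeled influx
at a configured fraction of uptake (up to the reported 7%), split across
entry metabolites in proportion to the reported unlabeled-fraction pattern.

What the generator does *not* emulate: real fragment-specific measurement
error structure (noise is i.i.d. per mass), LC-MS peak-picking artifacts,
natural-abundance contamination (simulated data are abundance-free, as
corrected data would be), metabolite proxies measured in place of their
precursors, and biological replicate-to-replicate flux variation. Passing
tests therefore demonstrate the correctness and calibration of the
algorithms under the stated noise model, not instrument-level robustness.

## Problem sizes used by the test suite

The acceptance checks run the EMU-versus-enumeration sweep at 100 draws per
toy network; the benchmark recovery at the full 100 starts (noisy and
noiseless variants); interval coverage with 100 replications of the
two-free-flux branch toy at 3 starts each; and the carry-over comparison at
40 starts per condition. These sizes were chosen as the smallest that
exercise the claims meaningfully.

## Known limitations

- Exchange fluxes are reported on the $x/(1+x)$ scale and are typically
  only bounded from below once scrambling saturates; treat large fitted
  exchange values as "fast equilibration", not point estimates.
- The reported solution on a non-identifiable ridge is the (regularized)
  minimum-norm representative; only the profile intervals, not the point
  values, are meaningful for such fluxes — the cofactor ledger's ATP terms
  inherit mild seed-to-seed variation from this.
- Transhydrogenase closure is the only NADPH-balancing mechanism modeled;
  alternative routes (e.g. NADPH-generating ferredoxin reductases) are out
  of scope.
- The chi-square cutoff depends on the residual-counting convention above;
  with correlated renormalized noise it is approximate, as it is in
  standard practice.
- Maintenance ATP is not modeled; it is absorbed into the reported ATP
  surplus by design.
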