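# emumfa

¹³C metabolic flux analysis for gluconeogenic growth, built on elementary
metabolite units (EMUs), with the full downstream accounting chain:
cofactor/ATP ledgers with transhydrogenase closure, biomass-demand
partitioning, growth physiology, and differential proteomics statistics.

## Who this is for

Researchers quantifying how bacteria that prefer gluconeogenic substrates —
organic acids such as succinate that feed directly into the TCA cycle —
partition carbon between energy generation, biosynthesis and the uphill
gluconeogenic route to sugar phosphates. The package ships curated
central-carbon reconstructions for *Pseudomonas putida* KT2440 (63
reactions) and *Comamonas testosteroni* KF-1 (51 reactions), and a
synthetic-data generator that emulates the complete study design (parallel
positional ¹³C tracers, replicate MID measurements, carry-over influx,
growth curves, a two-condition proteome), so the entire chain runs and is
tested without any external data.

## The core method

At metabolic steady state the flux vector satisfies `S v = 0`. Cells fed
`[1,4-¹³C₄]`- and `[2,3-¹³C₄]`-succinate imprint flux-dependent mass
isotopomer distributions (MIDs) on their metabolites; the EMU decomposition
reduces the isotopomer balance to a cascade of small linear systems, one
per carbon-subset size, so MIDs can be simulated for any candidate flux
distribution. Fluxes are estimated by minimizing the variance-weighted sum
of squared residuals over all tracers and replicates jointly, from 100
random starts; the fit is accepted when the SSR passes the 95% chi-square
cutoff, and each flux gets a profile-likelihood 95% confidence interval
(SD = interval width / 3.92). From the optimized fluxes the ledger sums
NADH/UQH₂, NADPH and ATP production and consumption, closes the anabolic
NADPH deficit with a net NADH→NADPH transhydrogenase flux, and converts
respirable NADH/UQH₂ to ATP at P/O = 1.5.

Two bespoke statistics round out the chain: the adenylate energy charge
`(ATP + ADP/2)/(ATP + ADP + AMP)`, and the flux precision score
`P = ((UB95−LB95)_unwashed / (UB95−LB95)_washed)²` comparing interval
widths between experimental conditions. Differential protein abundance uses
`Z = (mean₁ − mean₂)/(u₁ + u₂)` on log2 abundances, where each `u` is the
root-square sum of the between-replicate SD and the mean within-replicate
standard error, with Storey q-value control at 0.05.

## Worked example

```r
library(emumfa)

# synthetic benchmark: paper-shaped truth on the P. putida reconstruction,
# 2 tracers x 3 replicates, MID noise SD 0.005
run <- run_pipeline(seed = 7, n_starts = 100, out_dir = "results/run")
```

The pipeline logs each stage and prints, for seed 7:

```
[gate] influxes enabled: none
[fit] SSR 373.363 (dof 354, cutoff 398.9) accepted
[ci] SDH: [128.45, 128.69]
[ci] CS: [35.99, 36.24]
[ci] ENO: [20.10, 20.37]
```

meaning: no unlabeled carry-over was detected on the `[U-¹³C₄]` gating
data; the fit is statistically acceptable; the reductive TCA flux (SDH) is
~128% of succinate uptake (carbon cycles through the TCA cycle more than
once per molecule taken up), citrate synthase carries ~36%, and the
gluconeogenic PEP→EMP flux ~20% — against generator truths of 128.3, 35.9
and 20.0. The ledger then reports, in mmol gCDW⁻¹ h⁻¹:

```
nadph      production    9.315  consumption    9.315
transhydrogenase 5.87 (63% of NADPH production)
```

i.e. after closure the transhydrogenase supplies roughly two-thirds of the
NADPH demanded by biosynthesis — the energetic bypass that lets these
species grow fast on succinate with the oxidative PP pathway silent.
`analysis/01_simulate_scenario.R` … `04_physiology_proteome.R` run the same
stages as a step-by-step workflow and write their tables under `results/`.

## Layout

| path | contents |
| --- | --- |
| `R/` | package implementation (models, EMU, fitting, ledger, physiology, proteomics, generators, pipeline) |
| `inst/extdata/` | bundled species model reconstructions (TSV dialect, documented header) |
| `analysis/` | numbered narrative drivers over the package |
| `tests/testthat/` | unit, property and acceptance suites |
| `vignettes/` | methods vignette: models, assumptions, numerical choices, limitations |
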