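# epigrn

Stochastic simulation of the epigenetic OCT4 gene regulatory network:
the pluripotency transcription factor OCT4 coupled to the chromatin
modifiers TET1 (DNA demethylase) and JMJD2 (H3K9me3 demethylase), each
gene carrying a five-state chromatin modification circuit over its
nucleosomes. The package is for systems biologists studying how chromatin
state shapes cellular differentiation and iPSC reprogramming: it asks,
mechanistically, when co-overexpressing a DNA demethylase or a histone
demethylase alongside OCT4 makes reprogramming faster, more efficient and
less variable.

## Model in brief

Each gene has `D_tot = 50` nucleosomes in states D (bare), D^A
(H3K4me3/ac), D^R1 (CpGme), D^R2 (H3K9me3), D^R12 (both repressive
marks). In normalized time τ (21 days ≡ τ = 201.6) the circuit per gene
comprises:

- recruited activating writing `D → D^A` at
  `κ_WA · (X_O/K_A)/(1 + X_O/K_A) · n_D` (OCT4 recruits H3K4 writers on
  all three genes), plus auto-catalysis `n_A n_D / D_tot`;
- de-novo, auto- and cross-catalytic establishment of H3K9me3 and CpGme
  (strengths `α`, `ᾱ`, `α′ = r·α`);
- passive dilution by replication at `ε_d` (CpGme at `η·ε_d` — DNMT1
  maintenance makes `η` small), basal erasure at `ε_e`, and erasure
  recruited by opposing marks at `ε′`, with asymmetries `μ̃` (H3K9me3,
  scaled by JMJD2 abundance) and `μ̃′` (CpGme, scaled by TET1 abundance);
- gene expression `∅ → X` at `p̄·γ̂·n_A`, decay `γ̂·X`, and exogenous
  overexpression `ū_X(τ)·γ̂`.

MBD proteins shield methylated DNA from TET1:
`μ̃′ = F5/(F2·B/K_B + 1)`. The 90-channel system is simulated exactly
with Gillespie's direct-method SSA (compiled inner loop, counter-based
per-trajectory RNG streams), with experiment drivers, first-passage
metrics (efficiency %O^A, latency distribution f̄_L, latency SD/IQR), an
optional binomial-partitioning cell-division mode, and independent
validation oracles (exact chemical-master-equation solutions on small
state spaces; mean-field ODE reduction).

## Worked example

Reprogramming from the fully repressed, DNA-methylated state under
constant OCT4 overexpression, with and without TET1:

```r
library(epigrn)

params <- grn_params(mu_tilde_prime = 0.5, eps_d = 0.2, eps_e = 0.2)

with_tet1 <- run_reprogramming(experiment_spec(
  name = "OCT4 + TET1 overexpression", params = params,
  schedule = overexpression_schedule(O = 320, T = 160),
  N = 50, seed = 1))
print(with_tet1)
#> Ensemble result 'OCT4 + TET1 overexpression': N = 50 trajectories
#>   reactivation efficiency at 21.0 days: 100.0% (0 censored)
#>   latency: mean 2.74 d, SD 0.32 d, IQR 0.38 d

oct4_only <- run_reprogramming(experiment_spec(
  name = "OCT4 alone", params = params,
  schedule = overexpression_schedule(O = 320), N = 50, seed = 1))
print(oct4_only)
#> Ensemble result 'OCT4 alone': N = 50 trajectories
#>   reactivation efficiency at 21.0 days: 26.0% (37 censored)
#>   latency: mean 16.38 d, SD 2.95 d, IQR 2.50 d
```

Reading the numbers: every trajectory starts with all 50 OCT4 nucleosomes
carrying both repressive marks and zero protein. A trajectory counts as
reprogrammed when its OCT4 active-mark count reaches 40; the efficiency is
the percentage of the `N = 50` trajectories doing so within 21 days, and
the latency statistics summarize when. Adding TET1 overexpression
(`ū_T = 160`) erases DNA methylation actively instead of waiting for
replication dilution, so reactivation becomes near-deterministic (100%,
latency ≈ 2.7 ± 0.3 days), while OCT4 alone reactivates only 26% of
trajectories, late and with a ten-fold wider latency spread — the model's
mechanistic account of why demethylase co-expression boosts iPSC yields.

`run_differentiation()` runs the complementary study (spontaneous OCT4
silencing from the active state), `run_comparison_grid()` sweeps
parameter grids with paired seeds, and `sim_config(division_mode =
"binomial")` switches dilution to explicit binomial partitioning at cell
division. A thin CLI lives at `inst/cli/epigrn`
(`epigrn run --config cfg.yaml --out dir --seed 1`). See the vignette
(`vignettes/epigenetic-oct4-network.Rmd`) for the full model description
and the calibration rationale of the defaults.

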