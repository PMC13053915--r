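# nmrdyn

Comparative per-residue NMR dynamics analysis for detecting **dynamic
allostery**: how ligand binding at one site of a protein reshapes
backbone motion everywhere else, even far from the binding pocket.

## Who this is for

Solution-NMR groups comparing a protein in two ligand states (apo vs
bound) through the standard battery of backbone-amide observables:

* **CSP** — chemical-shift perturbations of the ¹H–¹⁵N amide peaks,
  CSP = [(Δδ_H)² + (Δδ_N)²/10]^½, with disappearing peaks tracked as a
  separate call;
* **R₁, R₂, hetNOE** — longitudinal and transverse ¹⁵N relaxation rates
  from monoexponential decay fits, and the steady-state {¹H}–¹⁵N NOE
  ratio I_sat/I_ref, reporting on ps–ns motion;
* **R_ex** — the µs–ms conformational-exchange contribution to
  transverse relaxation, extracted from constant-time CPMG relaxation
  dispersion, R_ex = R₂,eff(ν_min) − R₂,eff(ν_max).

Differences between states (apo minus bound) are flagged when they
exceed two standard deviations of the empirical difference
distribution; residues with R_ex > 7.5 s⁻¹ are called
strong-exchange sites; and significant residues are grouped into
spatial clusters by single-linkage on the Cα–Cα distance graph
(8 Å cutoff) of a PDB structure.

## The model at the core

Two-site chemical exchange A ⇌ B (populations p_A, p_B, exchange rate
k_ex = k_AB + k_BA, shift difference Δω) under a CPMG pulse train is
simulated by numerical propagation of the Bloch–McConnell equations for
the transverse magnetization, with each echo element τ/2–180°–τ/2
applied n = 2·ν_CPMG·T_relax times:

    R₂,eff(ν) = −(1/T_relax)·ln |M(T_relax)| / |M(0)|

Two closed forms serve as oracles and fast forward models: the
Carver–Richards expression (all timescales) and the Luz–Meiboom
fast-exchange limit

    R₂,eff = R₂⁰ + (p_A p_B Δω²/k_ex)·(1 − (4ν/k_ex)·tanh(k_ex/4ν)).

Dispersion curves are fitted per residue by weighted least squares with
multi-start initialization; a flat (no-exchange) model is preferred
unless an F-test at α = 0.01 says otherwise, and R_ex uncertainties come
from first-order Gaussian propagation of the parameter covariance.

Because the real deposited measurements of any given study are external,
the package ships a fully seeded **synthetic study generator** with
planted ground truth — a toy helical structure, a binding pocket whose
effects decay as exp(−d/10 Å), a sparse long-range network of
full-effect residues, planted exchange above/below the 7.5 s⁻¹ rule, and
disappearing peaks — so every rule in the pipeline can be validated
end to end.

## Worked example

```r
library(nmrdyn)

# one residue: simulate a noisy dispersion curve and fit it
sch   <- cpmg_schedule()                     # 25-2000 Hz, T_relax 40 ms
truth <- exchange_params(p_b = 0.03, k_ex = 1500, delta_omega = 500,
                         r2_a = 10)
curve <- simulate_dispersion(truth, sch, noise_fraction = 0.015,
                             rng_seed = 42)
fit   <- fit_dispersion(curve)
print(fit)
#> CPMG dispersion fit (residue 1): two_site model
#>   k_ex = 772.7 /s  p_b = 0.01578  delta_omega = 566.7 rad/s  R2_0 = 10.78 /s
#>   Rex = 3.852 +/- 0.561 /s   red. chi2 = 1.13

# full study: generate the default 120-residue two-state dataset and
# run the comparative pipeline
study  <- generate_study(file.path(tempdir(), "demo"), seed = 1)
result <- run_pipeline(study_config(study))
print(result)
#> Comparative NMR dynamics analysis: apo vs bound
#>   115 matched residues; CSP threshold 0.208 ppm, 14 significant
#>   r1: 14 significant, 9 cluster(s)
#>   r2: 14 significant, 9 cluster(s)
#>   noe: 14 significant, 9 cluster(s)
#>   rex: 7 significant, 7 cluster(s)
#>   csp: 14 significant, 9 cluster(s)
#>   strong exchange (Rex > 7.5 /s): apo = {85,96,100,102,110},
#>     bound = {30,36,47,58,68,85,96,98,100,102,104,110}
```

The fitted R_ex (3.85 ± 0.56 s⁻¹) brackets the true value of the
simulated curve (4.04 s⁻¹). In the study run, 5 of 120 residues
disappear on binding, 14 residues carry CSPs above the 2-SD threshold of
0.208 ppm (the pocket-adjacent and planted network residues), and the
bound state shows 12 strong-exchange residues against 5 in the apo state
— the local-plus-distal signature of dynamic allostery. The pipeline
writes a master table, per-observable difference tables, a cluster
report, score-annotated PDB files and a run log into the output
directory.

A command-line wrapper with `simulate`, `run`, `csp`, `fit-relax`,
`fit-cpmg` and `cluster` subcommands lives in `inst/scripts/nmrdyn.R`.

## Acceptance script

`scripts/acceptance.R` regenerates the default seeded synthetic study at
zero and at default noise, runs the complete pipeline on both, reports
recovery of the planted ground truth to stderr, and writes the JSON
result object:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
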