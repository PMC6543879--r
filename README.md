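# indeldfe

Maximum-likelihood inference of the distribution of fitness effects (DFE)
for short insertions and deletions (INDELs, ≤ 50 bp) from polarized site
frequency spectra, with explicit correction and estimation of
ancestral-state misidentification, plus two linked-selection genome scans.
Written for population geneticists analyzing resequencing data polarized
against outgroup genomes — the setting in which a misoriented insertion
masquerades as a high-frequency deletion and vice versa, corrupting every
downstream selection inference.

## The model

For a sample of *n* chromosomes, the observed insertion/deletion spectra
are a linear mixture of the true ones:

φ<sub>i</sub><sup>ins,obs</sup> = (1−ε<sup>ins</sup>) φ<sub>i</sub><sup>ins</sup> + ε<sup>del</sup> φ<sub>n−i</sub><sup>del</sup>,  
φ<sub>n−i</sub><sup>del,obs</sup> = (1−ε<sup>del</sup>) φ<sub>n−i</sub><sup>del</sup> + ε<sup>ins</sup> φ<sub>i</sub><sup>ins</sup>,

solvable per frequency pair whenever ε<sup>ins</sup>+ε<sup>del</sup> < 1.
Counts in each frequency class are modeled as independent Poisson
variables (a Poisson random field) with mean

E[φ<sub>i</sub>] = r<sub>i</sub> θL C(n,i) ∫₀¹ (1−e<sup>−γ(1−x)</sup>)/((1−e<sup>−γ</sup>) x(1−x)) x<sup>i</sup>(1−x)<sup>n−i</sup> dx,

where θ = 4N<sub>e</sub>μ per site, γ = 4N<sub>e</sub>s, L is the number
of callable sites and r<sub>i</sub> are optional demography nuisance
multipliers shared between a neutral reference region and the focal
region. DFE families: discrete site classes, or a deleterious gamma
distribution on |γ|; model variants (class counts, equal vs variable
mutation rates) are compared by AIC. Equal-rate fits yield the adaptive
proportion of fixations α = 1 − d<sub>pred</sub>/d<sub>obs</sub> with
d<sub>pred</sub> = d<sub>neutral</sub> Σ w<sub>j</sub> γ<sub>j</sub>/(1−e<sup>−γ<sub>j</sub></sup>).

The genome scans measure linked selection: θ (or π) in 2-kb bins of
distance from the nearest exon out to 100 kb, and π / Tajima's D in 2-Mb
windows against local recombination rates from cubic genetic-map fits,
with partial Spearman correlations (divergence as confounder) separating
linked selection from recombination-driven mutagenesis.

## Worked example

```r
library(indeldfe)

# a CDS-like dataset: bimodal DFE, realistic polarization error
truth <- synth_sfs_truth(
  theta_neutral = c(ins = 1.39e-4, del = 2.14e-4),
  focal = list(ins = list(gammas = c(-1.14, -801), thetas = c(4.92e-6, 1.34e-4)),
               del = list(gammas = c(-2.70, -649), thetas = c(8.32e-6, 2.06e-4))),
  eps = orientation_errors(0.0799, 0.0368), seed = 1)
dat <- simulate_sfs_dataset(truth)
fit <- fit_model(dat, dfe_model_spec("discrete", 2, "equal",
                                     gamma_bounds = c(-5000, 0)),
                 n_starts = 5, seed = 2)
fit
#> DFE fit (discrete, equal mutation rate): lnL = -147.321, AIC = 314.642, k = 10
round(natural_params(fit)[c("eps_ins", "eps_del")], 4)
#> eps_ins eps_del
#>  0.1001  0.0400

# effectively-neutral fractions of the published noncoding DFEs
gamma_mass(shape = 0.0345, scale = 1553, lo = 0, hi = 1)  # insertions
#> [1] 0.7909073
gamma_mass(shape = 0.106, scale = 715, lo = 0, hi = 1)    # deletions
#> [1] 0.5249739
```

The polarization error injected into the simulation (0.0799 / 0.0368) is
recovered close to the generating values (about one standard error off on
this realization), and the gamma-CDF banding
reproduces the ~80% (insertions) and ~52% (deletions) effectively-neutral
fractions implied by the published noncoding maximum-likelihood estimates.

The numbered scripts under `analysis/` run the whole pipeline on
synthetic data — `01_simulate.R` (datasets + toy genome with known
truth), `02_fit_dfe.R` (AIC model choice, α, θ band splitting),
`03_scan_exons.R` (distance bins, trend tests, bin-removal robustness),
`04_scan_recomb.R` (windowed diversity vs recombination with partial
correlations) — writing tables and JSON summaries under `results/`.

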