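# mitoclock

Epigenetic mitotic clocks from DNA methylation arrays: estimate the
cumulative number of stem-cell divisions (mitotic age, TNSC) and the
tissue-intrinsic annual stem-cell division rate (IR) from beta-value
matrices with known sample ages.

Somatic stem cells accumulate DNA methylation at a set of fetally
unmethylated, PRC2-marked CpGs as they divide. `mitoclock` implements the
stochastic model behind the epiTOC2 clock — per division, a CpG dyad
undergoes maintenance with probability μ and de novo methylation with
total probability δ, giving the closed-form trajectory

    β_t = 1 − (1 − δ/2)^t + β₀ (1 − δ/2)^t,   t = Age × IR

— together with the full calibration pipeline: per-CpG grid-multi-start
non-linear least squares for (δᵢ, βᵢ₀, IR), a δ·IR ≥ 0.001 assay-resolution
filter, a (δ, IR)-mode consensus that pins the single tissue-level IR, and
a fixed-IR refit that yields the per-CpG parameter table. Mitotic age is
then the first-order inverse

    TNSC(s) = (2/n) Σᵢ (β_is − βᵢ₀) / (δᵢ (1 − βᵢ₀))

and the intrinsic rate is the cohort median of TNSC(s)/Age(s). The earlier
epiTOC pcgtAge average and the comparator HypoClock score (mean beta over
constitutively methylated solo-WCGW CpGs, with age adjustment and
dynamic-range rescaling) are included, as are turnover-time converters for
comparing estimated rates with the experimental literature. A synthetic
cohort generator with beta-distributed, age-heteroscedastic noise makes
every step testable offline and reproduces the parameter-identifiability
experiment.

For the model, the estimation procedure, the non-identifiability of
(δ, IR) per site and how the consensus step resolves it, see the methods
vignette (`vignettes/mitotic-clocks.Rmd`).

## Worked example

Simulate the reference identifiability design — 163 loci, 656 individuals
aged 19–101 with a realistic age distribution, true IR = 35
divisions/stem cell/year, β₀ = 0.05, true δ drawn from a seven-value pool —
then recover the parameters from the data alone:

```r
library(mitoclock)

sim <- simulate_cohort(simulation_spec(seed = 1))
fit <- fit_cohort(sim$betas, sim$ages)
fit
#> Cohort fit: 163 sites, 140 retained (delta*IR >= threshold)
#>   modal delta 0.00075, modal IR 35 divisions/stem cell/year

tnsc <- estimate_tnsc(sim$betas[fit$params$probe_id, ], fit$params)
intrinsic_rate(tnsc, sim$ages)
#> IR(tissue) = 28.14 divisions/stem cell/year (median of 656 samples)

turnover_to_ir(10)      # 36.5  -- blood renewing every 10 days
skin_lifetime_ir(50)    # 13.21 -- lifetime-average skin rate at age 50
```

Reading the output: the 23 loci dropped by the filter are the slow ones
(δ·IR below the ~1%-per-decade assay resolution); the consensus vote over
the 140 retained loci lands exactly on the generating rate IR = 35; the
refit per-CpG δ estimates rank-correlate with truth at ρ ≈ 0.99. The
scored cohort rate (28.1) sits below 35 because the TNSC estimator inverts
the first-order model and the simulation pool deliberately includes
fast-saturating loci; with clock-like kinetics (δ = 5e-5) it returns 34.0
(~3% saturation bias) — see the vignette's validity-domain section.

The same pipeline runs from the shell on delimited text files (probes ×
samples matrix plus a `sample_id`/`age` metadata table):

```sh
Rscript inst/scripts/mitoclock simulate --seed 1 --out-prefix cohort
Rscript inst/scripts/mitoclock fit --betas cohort_betas.tsv \
    --metadata cohort_metadata.tsv --out params.tsv
Rscript inst/scripts/mitoclock score --betas cohort_betas.tsv \
    --metadata cohort_metadata.tsv --params params.tsv --out scores.tsv
Rscript inst/scripts/mitoclock rate --scores scores.tsv
```

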