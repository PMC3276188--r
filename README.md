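# mhcrec

Estimation of a per-generation recombination rate from the
recombinant-haplotype spectrum of an expanding population with a dated
founding event — the "Poisson method" — together with the founder-mosaic
parsimony classifier that produces the spectrum, the Verhulst /
harmonic-mean effective-size calculator used to contrast it with coalescent
ρ = 4·Ne·c conversions, and a forward-time simulator that validates the
estimator by parameter recovery.

## The problem

The Mauritian cynomolgus macaque population descends from roughly a dozen
animals introduced ~400 years ago, carrying seven MHC haplotypes that are
distinguishable with a panel of 17 microsatellites. Any crossover inside the
region since founding produces a haplotype explainable only as a mosaic of
founders. If crossovers accumulate neutrally and independently at constant
rate, the number of detectable recombinations per sampled haplotype is
Poisson distributed, and its intensity — divided by the number of elapsed
generations — is a direct estimate of the per-generation recombination
rate, with no effective-size estimate required.

For a spectrum `n_k` (haplotypes with exactly `k` detected recombinations,
`n = Σ n_k`):

- **MLE**: `λ̂ = Σ k·n_k / n` (the spectrum mean);
- **CI**: `λ̂ ± u_{α/2}·√(λ̂/n)` (asymptotic normality / Slutsky);
- **fit**: Pearson χ² over k-classes, tail bins merged until every expected
  count ≥ 5, referred to χ²(bins − 2);
- **rate**: `c = λ̂ / (E/g)` for founding `E` years ago and generation time
  `g`, corrected for invisible events by dividing by the heterozygote
  frequency (0.90 here).

The package is aimed at population geneticists working with dense multi-
allelic marker panels in bottlenecked, historically dated populations.

## Worked example

The packaged fixtures hold the seven founding haplotypes and the observed
spectrum of 1500 phased haplotypes (750 animals). The one-call pipeline:

```r
library(mhcrec)
sp <- read_spectrum_table(system.file("extdata",
        "mauritian_mhc_spectrum.tsv", package = "mhcrec"))
report <- run_pipeline(spectrum = sp)
print(report)
#> === recombination-rate report ===
#> spectrum n = 1500 ; counts: 1030, 382, 74, 14
#> lambda_hat = 0.381, CI [0.350, 0.413]
#> gof chi-squared = 1.436 (df 2, p = 0.488)
#> rate/generation (gen time 4 y): 0.0038 detectable, 0.0042 corrected
#> rate/generation (gen time 8 y): 0.0076 detectable, 0.0085 corrected
#> harmonic-mean Ne range: 63-3251
```

Reading: the 1500 haplotypes carry on average 0.381 detectable
recombinations accumulated since founding (95% CI 0.350–0.413), and the
spectrum is statistically indistinguishable from a Poisson distribution
(p = 0.49), supporting the constant-rate, independent-accumulation model.
Spread over 50–100 generations (generation time 8 or 4 years across 400
years), that is 0.38–0.76% recombination per generation across the region;
dividing by the 0.90 heterozygote frequency corrects for crossovers hidden
in founder-homozygous animals. The Ne range shows why the alternative
coalescent route (c = ρ/4Ne) is fragile here: the harmonic-mean effective
size under plausible logistic-growth parameters spans 63–3252.

Classifying haplotypes yourself, and validating by simulation:

```r
fd <- read_founder_table(system.file("extdata",
        "mauritian_mhc_founders.tsv", package = "mhcrec"))
cfg <- sim_config(fd$founders)        # 12 founders -> K = 12000, T = 100
sim <- simulate_population(cfg, seed = 1)
classify_population(fd$panel, fd$founders, sim$haplotypes)
rec <- recovery_experiment(cfg, replicates = 5, seed = 1)
```

A command-line wrapper with subcommands `classify`, `estimate`,
`demography`, `simulate` and `run` is installed at
`system.file("cli", "mhcrec.R", package = "mhcrec")`.

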