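# sigmark

Mutational signatures as markers of drug sensitivity in cancer cell lines.

Cancer cell lines are sequenced without a matched normal sample, so their
variant calls mix somatic mutations with residual germline variants — and
the trinucleotide spectrum of germline variation differs between human
ancestries, confounding mutational-signature inference. `sigmark`
implements the analysis chain around this problem for computational cancer
genomicists:

* **Ancestry-matched germline subtraction.** Cell lines are clustered with
  a germline-only baseline panel on principal components of common
  variants (after pruning batch-associated components with a random-forest
  classifier and trimming outliers with robust k-means); each cluster's
  *median* germline 96-channel spectrum is subtracted from its cell lines'
  observed spectra, negatives clamped at zero:

  `s_hat = max(0, x_observed − median(germline spectra of ancestry cluster))`

* **Signature extraction.** Bootstrapped non-negative matrix factorization
  (multiplicative updates, Frobenius objective, in compiled code) over a
  rank sweep, with a relative-tolerance filter on diverged runs, CLARA
  k-medoid clustering of the pooled solutions, and hierarchical
  re-extraction that removes well-reconstructed samples (cosine ≥ 0.97) so
  rare signatures can surface. Candidates are matched to a COSMIC-style
  catalog by weighted cosine (`0.9·spectrum + 0.1·exposure`) and named by
  the `SBS26/12L` convention; unmatched candidates become `SBS-CL`
  signatures. Exposures are binarized at 5% of the second-highest value.

* **Replication association screening.** Binary markers × drug responses,
  per tissue, scored by Cohen's d
  (`d = (mean(neg) − mean(pos)) / s_pooled`, positive = sensitivity on the
  ln IC50 scale) in two datasets; the two-way score is the *weaker* effect
  (min for sensitivity, max for resistance) and its p-value comes from
  joint label randomization. Three replication flavors: a second drug
  screen, another drug with the same molecular target, and CRISPR knockout
  of the target gene. Storey q-values per tissue × direction × flavor,
  genomic inflation λ diagnostics, Fisher pooling of signature groups, and
  silver/golden recurrence tiers.

* **Predictive benchmarking.** Repeated 10×5-fold cross-validated RRMSE
  against a training-mean default model, with Iman–Davenport corrected
  Friedman tests and Nemenyi critical-distance rank diagrams.

The real cohorts this methodology targets are access-restricted, so the
package ships a synthetic-data generator (population-structured genotypes,
biased germline spectra, signature-driven somatic calls, screens with
planted effects) that gives every stage a ground-truthed test surface. See
the methods vignette (`vignettes/mutational-signature-markers.Rmd`) for
the model, parameter choices and limitations.

## Worked example

```r
library(sigmark)

cohort <- simulateCohort(nCellLines = 200, nBaseline = 150,
                         model = populationModel(nCommonVariants = 1000),
                         seed = 1)
bench <- benchmarkReconstruction(cohort, kGrid = 2:4, bootstrapReps = 50,
                                 seed = 2)
bench$summary
#>                  method meanAE
#> 1      ancestry-matched  50.24
#> 2 frequency-filter-only  85.52
#> 3       bootstrap-floor  49.14
```

Ancestry-matched subtraction reconstructs the somatic spectra with a mean
absolute error of 50.2 counts per sample — essentially at the bootstrap
self-similarity floor of 49.1 (the error a resample of the truth makes
against itself) and far below the 85.5 of population-frequency filtering
alone.

```r
est <- estimateSomaticSpectra(bench$observedSpectra, bench$model)
cfg <- extractionConfig(nBootstraps = 20, rankRange = 2:8, maxIter = 1000,
                        tol = 1e-9, medoidKRange = 2:10, seed = 3)
sigset <- matchAndName(hierarchicalExtract(est, cfg,
                                           catalog = cohort$signatures),
                       cohort$signatures)
head(signatureMatches(sigset)[, c("name", "spectrumCosine", "novel")])
#>    name spectrumCosine novel
#> C1 SYN3          0.988 FALSE
#> C2 SYN2          0.999 FALSE
#> C3 SYN4          0.998 FALSE
#> C4 SYN1          0.999 FALSE
#> C5 SYN5          0.998 FALSE
#> C6   C6          0.975 FALSE
```

All five planted signatures are recovered at cosine ≥ 0.99 and claimed by
their catalog entries; surplus candidates (near-duplicates from different
ranks, e.g. `C6`) stay unnamed because each catalog entry names only its
single best match.

```r
bin <- binarizeExposures(sigset)
bundle <- simulateScreens(
  bin$binary, factor(rep(paste0("T", 1:4), length.out = 200)),
  plantedEffects = data.frame(marker = colnames(bin$binary)[1],
                              response = "D1", tissue = "all", d = 1.5,
                              direction = "sensitivity"),
  nDrugs = 10, seed = 4)
rec <- runReplicationScreen(bundle, testPolicy(nRandomizations = 2000),
                            "screen-replication", seed = 5)
rec[rec$significant & rec$marker == "SYN3",
    c("response", "tissue", "d_primary", "d_secondary", "p", "q")]
#>  response tissue d_primary d_secondary     p      q
#>        D1     T1     1.254       2.151 0e+00 0.0650
#>        D1     T2     1.646       1.467 0e+00 0.0650
#>        D1     T3     1.278       1.536 0e+00 0.0650
#>        D1     T4     1.735       1.746 0e+00 0.0217
```

The marker planted on drug D1 (binarized exposure of the recovered `SYN3`)
replicates across both screens in all four tissues at q < 0.15 with large
effects in both datasets.

A thin command-line front end over the same functions lives at
`inst/exec/sigmark.R` (subcommands `simulate`, `ancestry`, `extract`,
`associate`).

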