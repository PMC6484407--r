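# polwave

Per-gene RNA polymerase II **elongation-rate inference** from DRB-release
nascent-RNA time courses, and the **kinetic-coupling statistics** that sit
downstream of it.

DRB reversibly stalls RNAPII before productive elongation. On washout, the
accumulated polymerases release as a synchronized wave; how far the wave
has traveled at each harvest time gives the per-gene elongation rate
*v* (bases/min). polwave implements both read-outs of that experiment:

* **4sU-DRB-seq**: timed 4sU pulse labeling and sequencing of nascent RNA.
  Coverage is binned TSS-relative per gene; the wave-front *x<sub>t</sub>*
  is the maximum-likelihood breakpoint of a two-segment Poisson model
  (high upstream mean, low downstream mean), and
  *v = (x<sub>t2</sub> − x<sub>t1</sub>)/(t<sub>2</sub> − t<sub>1</sub>)*
  (or a regression slope over ≥ 3 times).
* **qPCR**: pre-mRNA signal at an exon–intron junction *d* kb from the TSS
  rises once the wave passes it; detection is the earliest sampled time at
  ≥ 50% of the plateau and *v = d / t<sub>detect</sub>*.

Downstream analyses: differential percent-spliced-in
(PSI = 100·inc/(inc+exc)) with a beta-posterior ΔPSI test
(call when |ΔPSI| ≥ 10 and directional posterior ≥ 0.95), exon/intron
length statistics (Mann–Whitney), motif RNA maps with permutation
significance, ΔPSI-versus-log2FC regression, gene-length sliding-window
downregulation curves, and Fisher gene-set overlap tests. A synthetic-data
generator reproduces the generative structure of the whole design —
release at t = 0, 10-min pulse, harvests at 0/5/15 min,
genotype-specific rate distributions, condition-dependent inclusion,
length-dependent downregulation — so every stage is testable without
external data. It is intended for genomics analysts studying
transcription kinetics and its coupling to splicing and gene expression.

## Worked example

Simulate two genotypes over 150 genes, call fronts at 5 and 15 min,
estimate rates on genes usable in both genotypes, and compare:

```r
library(polwave)

genes <- make_genes(150, log(1.2e5), 0.35, c(6e4, 3e5), seed = 11)
wt   <- simulate_wave_coverage(genes, preset_wt_rate(),   pulse_design(),
                               genotype = "wt",   seed = 12)
slow <- simulate_wave_coverage(genes, preset_slow_rate(), pulse_design(),
                               genotype = "slow", seed = 13)
rates_wt   <- estimate_rates(call_fronts(wt,   times = c(5, 15)))
rates_slow <- estimate_rates(call_fronts(slow, times = c(5, 15)))
common <- common_genes(list(wt = rates_wt, slow = rates_slow))
compare_rates(rates_wt[rates_wt$gene_id %in% common, ],
              rates_slow[rates_slow$gene_id %in% common, ],
              labels = c("wt", "slow"))
#> Elongation-rate comparison (Mann-Whitney, normal approximation)
#>   wt: n = 145, mean = 2302, median = 2000 bases/min
#>   slow: n = 145, mean = 1757, median = 1700 bases/min
#>   U = 12829.5, two-sided p = 0.00117
```

The wild-type mean sits near its generative 2,450 bases/min (the gap is
mixture sampling noise at n = 150), the slow mean near 1,780, and the
Mann–Whitney test separates the genotypes. The qPCR variant on the
textbook junction:

```r
rate_from_junction(133, 40)$reported   # junction 133 kb, detected 40 min
#> [1] 3.3
```

— 3.3 kb/min, with the unrounded 3.325 kept internally. Differential
splicing on 200 simulated events, 30 of them with a true ΔPSI of −20 at
read depth 200:

```r
ev <- simulate_junction_counts(200, psi_base = 50,
                               dpsi_true = rep(c(-20, 0), c(30, 170)),
                               depth = 200, seed = 14)
summarize_calls(diff_splice(ev, seed = 15))
#>   type UP DOWN unchanged not_testable total
#> 1   CE  0   30       170            0   200
```

All 30 shifted events are called DOWN and no null event is called — the
calibration the double criterion (|ΔPSI| ≥ 10, directional posterior
≥ 0.95) is designed for.

`run_all(config, out_dir)` chains every stage (simulate → bin →
wave-front → qPCR → splice → coupling) into a run directory with a
manifest of seeds, config, and output checksums; `report(out_dir)`
summarizes it. A thin command-line wrapper lives at
`inst/cli/polwave.R` (`run-all`, `report`, `bin`, `wavefront`, `qpcr`,
`splice`, `lengthbias`).

See `vignettes/polwave-methods.Rmd` for the models, parameter choices,
and what the synthetic generator does and does not emulate.

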