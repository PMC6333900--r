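# ngpd — next-generation phage display enrichment analysis

`ngpd` is an R package for analysing biopanning experiments read out by
deep sequencing (next-generation phage display, NGPD). Instead of
picking and assaying individual phage clones after selection, the
insert-coding region of the whole selected pool is amplified, barcoded
and sequenced; binders reveal themselves as peptides statistically
enriched in the target-selected pool relative to a control-protein
pool. The package was built around the analysis of randomised
nonapeptide gpVIII-display libraries panned against the USP11 DUSP–UBL
domains, but every stage is generic.

It provides, end to end:

* **Synthetic data with ground truth** — a random-peptide library
  generator, a multi-round panning simulator (multiplicative binder
  enrichment + lognormal amplification noise), and an Ion Torrent-style
  barcoded amplicon FASTQ emitter (frame-offset pads, per-base
  substitution errors, optional indels), so the whole pipeline is
  testable without any external download.
* **Read processing** — barcode demultiplexing, three-frame forward
  translation (via Biostrings), extraction of inserts flanked by the
  conserved gpVIII anchor sequences `AEGEF` … `DPAKAA`, and paired
  target-vs-control peptide count tables.
* **Enrichment ranking** — the pooled two-proportion Z statistic

  $$Z = \frac{p_1 - p_2}{\sqrt{\hat p(1-\hat p)(1/n_1 + 1/n_2)}},
  \qquad \hat p = \frac{x_1 + x_2}{n_1 + n_2},$$

  ranking each peptide's frequency in the target pool ($x_1/n_1$)
  against the control pool ($x_2/n_2$); top-N selection for motif input.
* **Motif discovery** — zero-or-one-occurrence-per-sequence (ZOOPS) EM
  motif elicitation (`em_fit`, returning a classed `motif_model` with
  PWM, occurrence prior λ, members and information content), sequential
  multi-motif discovery with erasure, and executable degenerate
  consensus patterns such as `(YNHC)-(±)-L-(±)-φ-R`.
* **ITC fitting** — the one-site Wiseman binding isotherm with
  perfusion-cell dilution and displaced-volume corrections, synthetic
  noisy titrations, and a multi-start Levenberg–Marquardt fitter
  (`fit_one_site`, returning a classed `onesite_fit` with
  N, K_D, ΔH, dilution offset, standard errors and c-value guard).

## Worked example

Simulate a small screen (2 000 clones, 3 spiked binders enriched
10-fold per round for 3 rounds, 10 000 reads per arm), process it, and
rank:

```r
library(ngpd)
outdir <- tempfile("ngpd_demo")
sim <- run_simulate(ngpd_config(seed = 42, paths = list(outdir = outdir),
  simulate = list(n_clones = 2000, n_binders = 3, n_reads = 10000)))
rk <- run_rank(ngpd_config(seed = 42, paths = list(outdir = outdir)))
#> ngpd rank: reads_total=20000 unassigned=975 target_reads=9512
#>   control_reads=9513 target_extracted=8335 control_extracted=8357
#>   unique_peptides=3343
head(rk$ranking, 5)
#>     peptide         z   x1   n1 x2   n2          p1           p2
#> 1 ALRIDKWAM 36.519700 1232 8335  0 8357 0.147810438 0.0000000000
#> 2 FEVFHGEYA 36.197017 1236 8335  9 8357 0.148290342 0.0010769415
#> 3 TELWVQLRK 35.275232 1166 8335  4 8357 0.139892022 0.0004786407
#> 4 ALRIDKWAI  4.007196   16 8335  0 8357 0.001919616 0.0000000000
#> 5 ADGQADVNK  3.167397   10 8335  0 8357 0.001199760 0.0000000000
```

The three spiked binders (`TELWVQLRK`, `FEVFHGEYA`, `ALRIDKWAM`) occupy
the top three ranks with Z ≈ 35–37; rank 4 is a sequencing-error
derivative of the top binder — exactly the structure real screens show.
About 5% of reads are unassigned (barcode hit by an error) and ~12% of
assigned reads fail extraction (error in an anchor or insert), matching
the error model.

Fit a one-site isotherm to a noisy synthetic titration of the
highest-affinity reported peptide (30 µM protein cell, 300 µM peptide
syringe, 30 × 8 µl injections, 25 °C, K_D = 8.86 µM, ΔH = −8 kcal/mol,
2% peak-scale noise):

```r
pr <- itc_protocol()
h <- simulate_titration(pr, N = 1, K_D = 8.86e-6, dH = -8, q_dil = -0.05,
                        noise_frac = 0.02, seed = 11)
fit_one_site(h)
#> One-site ITC fit
#>   N      = 1 +/- 0.04
#>   K_D    = 8.808 +/- 1.8 uM
#>   dH     = -7.981 +/- 0.69 kcal/mol
#>   q_dil  = -0.0923 +/- 0.24 kcal/mol
#>   c-value = 3.41; RSS = 0.2268; sigma = 0.0953 kcal/mol
```

The fit recovers the generating parameters within its own standard
errors; at c ≈ 3.4 the isotherm is a shallow sigmoid and single-run K_D
uncertainty is genuinely ~20%.

Check a peptide against an executable degenerate consensus:

```r
match_degenerate("YKLKIRTPQ", motif_patterns()$motif1)
#> [1] TRUE
#> attr(,"offset")
#> [1] 1
```

A thin CLI wraps the same stages:
`ngpd all --config config.yml --seed 1`.

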