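# mblfp — multi-brain LFP analysis for group-housed mice

`mblfp` analyses simultaneous local field potential (LFP) recordings from
several freely behaving mice sharing an arena, the "hyperscanning" design
used to ask how social context shapes prefrontal brain dynamics. It is
aimed at electrophysiologists who have per-animal raw traces plus
per-second behavioural annotations and want the full chain from file
decoding to interbrain statistics, and at methodologists who want a seeded
synthetic cohort generator with planted ground truth to validate that
chain.

## What it computes

The core statistic is the **high-to-low-power ratio (HLR)** of each 1-s
segment,

$$\mathrm{HLR}(t) \;=\; \frac{\overline{P}_{31\text{–}150\,\mathrm{Hz}}(t)}
                             {\overline{P}_{0\text{–}12\,\mathrm{Hz}}(t)},$$

where $\overline{P}$ is the mean Hamming-windowed Welch PSD density in the
band (gamma/high-gamma over delta/theta/alpha), computed from unnormalised
powers after 200 Hz low-pass and 60/120 Hz notch filtering. The HLR rises
with behavioural mobility and falls during huddling, making it a compact
per-second brain-state index. On top of it the package provides:

* **io**: the hexadecimal space-delimited telemetry dialect (16-bit
  two's-complement, 30-min segments), plain-text and int16 formats,
  YAML/JSON session manifests, annotation CSVs with closed vocabulary and
  completeness checks;
* **spectral**: per-second band powers for delta/theta/alpha/beta/gamma/
  high-gamma, band–band correlation matrices, robust-scaled spectrograms;
* **behavior**: huddle episodes (trunk-to-trunk contact persisting > 10 s),
  time budgets, immobility-defined sleep, locomotive-state × context HLR
  cell means;
* **interbrain**: lag-0 HLR cross-correlation for the four pair-provenance
  classes (group, group-shuffled, group–single-shuffled, single-shuffled),
  a 10,000-draw shuffled-pair permutation null with ±1.96 SD band,
  locomotion-residualised correlation over 15-min segments, and lag-1
  Granger-causality directionality graphs;
* **synthetic_data**: a layered cohort generator (Markov locomotive
  states, shared huddle process, planted band gains, cohort-shared
  modulator, leader→follower lag-1 influence) with ground truth.

See `vignettes/multibrain-lfp-methods.Rmd` for the model, its assumptions
and the reasoning behind the defaults.

## Worked example

Simulate a 1-h, 4-mouse group session at the band-power level, then run
the behavioural and interbrain stages:

```r
library(mblfp)
cfg <- cohort_sim_config(duration_s = 3600, seed = 42)
bundle <- simulate_cohort(cfg)            # band-power level: fast
h <- bundle_hlr(bundle)                   # per-subject HLR series

condition_means(h, bundle$annotations)
#>   locomotive_state           context   mean     sd    n
#> 1         inactive     group_huddled 0.0364 0.0276 5785
#> 2     active_still     group_huddled 0.4302 0.2664  348
#> 3           active     group_huddled 1.8264 1.0815   49
#> 4         inactive group_non_huddled 0.0422 0.0279  722
#> 5     active_still group_non_huddled 0.6659 0.5350 2391
#> 6           active group_non_huddled 2.3719 1.6390 5105
```

The cell means show the two planted (and empirically reported) orderings:
HLR grows with mobility within every context, and non-huddled seconds have
higher HLR than huddled ones within every locomotive state.

```r
pair_correlation(h[[1]], h[[2]])
#> <pair_correlation> c01_m1 ~ c01_m2 [group]: r = 0.8076 (n = 3600)

classify_directionality(granger_matrix(h, lag = 1))
#> <granger_graph> alpha = 0.05 (none): 1 unidirectional, 2 bidirectional, 3 none
#> edges:
#>    from     to             p
#>  c01_m1 c01_m2 9.791313e-227
#>  c01_m2 c01_m1  2.231170e-06
#>  ...
```

The high pair correlation reflects the cohort-shared HLR modulator
(`coupling_strength = 0.6` by default) plus huddle-synchronised behaviour;
with shared coupling this strong, pairwise Granger tests mostly report
bidirectional influence — the common-input caveat discussed in the
vignette. A proper permutation null pools the HLRs of *all* cohorts and
conditions (`permutation_null()` on the pooled list); building it from one
coupled cohort alone, as a quick demo would, produces an intentionally wide
band.

For a raw-voltage run end to end (synthesis → filtering → Welch →
behaviour → interbrain → Granger, with every table written as CSV/JSON):

```r
run_pipeline(cohort_sim_config(duration_s = 900, fs = 512, seed = 1),
             out_dir = "out", signal = "lfp")
```

A thin command-line wrapper lives in `inst/scripts/mblfp.R`
(`simulate`, `pipeline`, `spectral`, `granger`, `validate` subcommands).

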