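# respburst

Analysis of respiratory motor output from multiunit nerve recordings, for
experiments that perturb the medullary respiratory network (Bötzinger
complex, pre-Bötzinger complex, rostral ventral respiratory group) by local
drug microinjection and read the response from the phrenic (PNA) and
central vagus (VNA) nerves of an in situ perfused preparation.

The package implements the full measurement chain:

* **Integrated traces** — ∫PNA, ∫VNA: the rectified signal smoothed by a
  centered 0.05-s moving average.
* **Burst detection and phase segmentation** — inspiratory duration
  `Ti` from burst onset to the onset of the sharp terminal decrease; cycle
  duration `Ttot` from one inspiratory offset to the next;
  `Te = Ttot − Ti`; inspiratory ratio `Ti/Ttot`; instantaneous frequency
  `f = 60/Ttot` (cycles/min).
* **Burst-triggered averaging** — per-channel mean waveforms aligned on
  burst onsets in 20-s windows advanced in 10-s steps; ∫PNA amplitude and
  post-inspiratory ∫VNA amplitude are measured from the averaged
  waveforms against a pre-trigger baseline.
* **Drug-response quantification** — every metric normalized so the mean
  over the 100 s before injection is 100%; *change rates* (mean percent
  over a post-injection analysis window); one-sample t vs 100%, paired t,
  and repeated-measures ANOVA with exact balanced Dunnett many-to-one
  comparisons against the last pre-injection bin (p < 0.05, means ± SEMs).
* **Synthetic sessions** — a seeded generator of PNA/VNA/ECG/PP recordings
  with known per-cycle ground truth and a multiplicative drug-effect model
  (linear rise to peak at ~2 min, exponential recovery within ~10 min), so
  the whole chain is testable without animal data.

## Worked example

Simulate a cohort in which an injection at t = 120 s attenuates burst
amplitude to 80% and shortens expiration to 70% at peak effect, then run
the complete analysis:

```r
library(respburst)

config <- pipeline_config(
  synth    = synth_config(fs = 500, m_amp = 0.80, m_Ti = 1.00, m_Te = 0.70,
                          seed = 11),
  protocol = drug_protocol("BotC", "HA", injection_times = 120,
                           post_duration = 240),
  n_subjects = 4,
  analysis_window = c(90, 150),   # brackets the ~2-min effect peak
  seed = 11)

grp <- run_pipeline(config, out_dir = "out")
grp
#> <rb_group_result> 4 subjects
#> Group change rates (% of baseline, mean +/- SEM):
#>   amp_PNA              80.3 +/-  3.1  (t=-6.27, p=0.00819) *
#>   amp_postinsp_VNA     75.2 +/-  3.2  (t=-7.76, p=0.00446) *
#>   f                   125.0 +/-  1.2  (t=20.2, p=0.000267) *
#>   Ti                   99.4 +/-  1.5  (t=-0.405, p=0.713)
#>   Te                   74.5 +/-  0.7  (t=-34.2, p=5.5e-05) *
#>   ratio               123.9 +/-  1.2  (t=20, p=0.000273) *
#>   HR                  100.0 +/-  0.1  (t=0.294, p=0.788)
```

Reading the output: the pipeline recovers the injected 0.80 amplitude
multiplier as a change rate of 80.3% of baseline, leaves inspiratory
duration unchanged (99.4%, not significant), and finds expiration shortened
(74.5% — near 73%, the expected value given that the analysis window
averages the effect kernel at ~0.88 of its peak). Frequency rises to 125%
because only expiration shortens, and the inspiratory ratio rises
accordingly. Asterisks mark p < 0.05 against 100%. The `out/` directory
receives per-subject cycle tables, metric time courses, change rates, group
statistics, Dunnett comparisons and a JSON manifest; identical config and
seed reproduce the bundle byte for byte.

A shell interface with `simulate`, `analyze` and `run` subcommands is
installed at `system.file("cli", "respburst.R", package = "respburst")`.

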