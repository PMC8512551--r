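# tugtmg

Tools for linking **Timed Up-and-Go (TUG) subtask times** to **muscle
contractile properties measured by tensiomyography (TMG)**.

The TUG test (stand up, walk 3 m, turn, walk back, sit down) is a standard
mobility and fall-risk assessment in older adults.  Recorded with a
chair-mounted ultrasonic rangefinder (10 Hz, ~3 cm accuracy), the test
becomes a distance-over-time signal in which the five subtasks correspond
to distance bands: sit-up/sit-down below 0.99 m, walking between 1 and
3.19 m, turnaround between 3.20 and 3.50 m, with the test starting and
ending seated (< 0.10 m).  TMG measures the radial displacement of a
muscle belly during an evoked twitch; each trace is summarized by the
maximal displacement D_m (mm), the delay time T_d (stimulus → 10 % of D_m,
ms) and the contraction time T_c (10 % → 90 % of D_m, ms).

The package implements the full analysis chain for cohorts of such
recordings:

* `tug_segment()` — distance-band segmentation of one TUG recording into
  sit-up, walk-forward, turnaround, walk-back, sit-down and total time,
  with interpolated boundary crossings, hysteresis against sensor noise,
  and model-based refinements for the seated and turn boundaries;
* `tmg_extract_params()` / `tmg_average_responses()` — twitch-parameter
  extraction and parameter-level averaging of replicate responses;
* `build_participant_records()`, `correlation_table()`,
  `descriptive_table()` — participant-level means, the 12 × 6 Spearman
  correlation table (exact permutation p-values for n ≤ 9, t
  approximation otherwise) with raw and Bonferroni-adjusted significance
  flags (0.05/12 ≈ 0.0042), and pooled descriptive statistics;
* `generate_cohort()` — a synthetic-data generator producing whole
  cohorts (raw signals included) with known ground truth and a
  controllable rank-correlation structure via a Gaussian copula, so the
  chain can be validated end to end as a parameter-recovery experiment;
* `run_pipeline()` — synthesis or CSV/manifest input → segmentation →
  extraction → tables → `report.json`, byte-reproducible under a fixed
  seed.

## Worked example

Simulate one recording at the cohort-mean subtask durations, segment it,
and extract twitch parameters for a vastus medialis-like response:

```r
library(tugtmg)

sig <- generate_tug_signal(tug_profile(), noise_model(seed = 1))
tug_segment(sig)
#> TUG subtask times (s):
#>       sit_up_s walk_forward_s         turn_s    walk_back_s     sit_down_s
#>           4.58           3.84           2.78           4.51           4.58
#>        total_s
#>          20.30

tw <- generate_twitch(twitch_truth(amplitude_mm = 5.84))
tmg_extract_params(tw)
#> TMG parameters: D_m = 5.84 mm, T_d = 11.63 ms, T_c = 26.95 ms (n averaged = 1)
```

The profile asked for (4.51, 3.78, 3.00, 4.41, 4.59) s; the segmenter
recovers each phase within a quarter of a second despite 3 cm Gaussian
noise, 3 cm quantization and dropout (the median per-subtask error across
many seeds is about 0.05 s).  The twitch was generated with a
5.84 mm target amplitude (the cohort-mean vastus medialis D_m); delay and
contraction times follow from the 10 ms onset latency and the 20/200 ms
rise/decay constants.

A whole synthetic study with an injected muscle-mobility association:

```r
spec <- cohort_spec(n_participants = 23, tests_per_participant = 6,
                    target_correlations = data.frame(
                      parameter = "VM_T_d", subtask = "sit_up", rho = 0.80),
                    seed = 123)
coh <- generate_cohort(spec)
m   <- measure_cohort(coh)                      # segment + extract everything
rec <- build_participant_records(m$tug, m$tmg)  # participant means
tab <- correlation_table(rec)                   # 72 Spearman cells
subset(tab, muscle == "VM" & parameter == "T_d" & tug_time == "sit_up_s")
#>    muscle parameter tug_time       rho      p_value  n sig_raw sig_adj note
#> 61     VM       T_d sit_up_s 0.7460474 4.368973e-05 23    TRUE    TRUE <NA>
```

The injected population Spearman correlation of 0.80 between the vastus
medialis delay time and the sit-up duration comes back as 0.75 after the
full signal-level round trip at n = 23 — inside the sampling interval for
a cohort of this size — and is flagged significant at both the raw and
the Bonferroni-adjusted threshold.

See `vignettes/tug-tmg-pipeline.Rmd` for the models, the estimator design
and the generator's assumptions.

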