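# larvamotor

Locomotor phenotyping of larval zebrafish from tail kinematics and fictive
motor recordings.

Manganese overexposure produces a movement disorder (manganism), and larval
zebrafish reared in Mn-containing medium develop a measurable phenotype:
they float sideways, curve their spines, swim in circles, and their tail
movements change — fewer startle-scale tail beats, each lasting much
longer, with matching changes in the motor-neuron output recorded in
paralyzed larvae. `larvamotor` implements the quantitative layer of such a
study as a tested, reusable pipeline for anyone analyzing tracked tail
coordinates, extracellular spike recordings, dose–survival tables or
phenotype scoring counts. Because no raw recordings ship with studies of
this kind, the package includes a synthetic-data generator that emulates
control, Mn-treated and recovered larvae, so the entire pipeline runs — and
is closed-loop tested — with no external data.

## What it computes

**Body-angle kinematics.** Three tracked points per frame — head H,
mid-trunk/swim-bladder M, tail T — give the body angle at M:

```
θ(deg) = 360 − (180/π)·arccos[ (H−M)·(T−M) / (‖H−M‖‖T−M‖) ]
```

θ = 180° is the resting (straight) posture and the arccos range keeps
θ ∈ [180°, 360°]. Movement events are excursions out of a rest band
(180° ± 5° by default), classified by peak angle: **wags** (< 200°,
clustered low-amplitude beats) and **LAMs** (large-angle movements,
200°–270°, the startle-scale beats); peaks ≥ 270° are reported separately
as "extreme" and never counted as LAMs. Since the arccos discards the bend
side, left/right direction is recovered from the sign of the planar cross
product (H−M) × (T−M). Durations are rest-to-rest; summaries report LAM
counts per 20-s window, duration means ± s.e.m. and the empirical CDF of
LAM durations.

**Fictive motor patterns.** Spike times (detected from a voltage trace by
rising-edge thresholding, or supplied directly) are sorted by inter-spike
interval in one left-to-right pass: ISI < 10 ms → same burst; 10–100 ms →
new burst, same episode; > 100 ms → new episode. From the segmentation come
the four motor-pattern metrics: spikes per burst, burst duration, burst
period (successive burst starts within an episode) and bursts per episode.

**Group statistics.** Chi-square scoring of phenotype count tables (pooled
or batch-stratified), Wilcoxon rank-sum with Bonferroni correction,
tie-corrected Kruskal–Wallis, a Lilliefors-gated paired comparison
(repeated-measures ANOVA when every group passes normality, Friedman
otherwise), and LC50 estimation from dose–survival tables by log-linear
interpolation (default) or a two-parameter logistic fit.

## Worked example

```r
library(larvamotor)

# a control larva: 20 s at 300 fps, known ground truth
sim    <- simulate_trajectory(trajectory_preset("control", seed = 1))
trace  <- compute_body_angle(sim$track)
events <- detect_events(trace)
summarize_events(events)
#> Kinematics summary (window 20 s)
#>   window_start lam_count wag_count extreme_count
#> 1            0        10        94             0
#>   event_class     n mean_ms sem_ms
#> 1 LAM            10    55.3  3.27
#> 2 wag            94    31.4  0.461
```

Ten LAMs in the 20-s window with a 55-ms mean duration is a typical
control draw (the generator schedules Poisson(13.2) LAMs of 57 ± 10 ms);
an Mn-treated preset gives ~2 much longer events. The fictive side:

```r
st  <- simulate_spike_train(spike_train_preset("mn", seed = 1),
                            include_trace = FALSE)
seg <- segment_spikes(st$spike_times)
seg
#> Spike segmentation: 150 spikes, 27 bursts, 6 episodes (ISI bands: <10 ms burst, <=100 ms episode)
tidy(burst_metrics(seg))
#>   metric                 n  mean   sem
#> 1 spikes_per_burst      27  5.56 0.216
#> 2 burst_duration_ms     27 25.5  0.599
#> 3 burst_period_ms       21 69.0  1.66
#> 4 bursts_per_episode     6  4.5  0.764
```

The 25.5-ms mean burst duration reflects the Mn-like preset (control-like
recordings segment to ~10-ms bursts at a ~35-ms period). Toxicology side:

```r
lc50_estimate(simulate_survival(survival_params(seed = 1)))
#> LC50 estimate: 1.878 (interpolation)
#>   log-linear interpolation between 1 and 2
```

Single draws scatter around the true 2 mM midpoint; the median estimate
over 50 simulation seeds is 2.0 mM. `run_pipeline(run_config(seed = 1), "out/")`
runs every stage for all three presets and writes event tables, metrics,
a statistics report and a manifest; reruns with the same config are
byte-identical. `plot_angle_trace()`, `plot_lam_ecdf()`,
`plot_dose_survival()` and `plot_burst_metrics()` draw the standard
figures, and `tidy()`/`glance()` methods return tibbles for downstream
work.

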