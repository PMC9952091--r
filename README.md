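# chemotaxr

Single-cell chemotaxis is heterogeneous: genetically identical cells under
the same chemoattractant gradient migrate at very different speeds and with
very different persistence. chemotaxr is an R package for asking *why*, at
single-cell resolution, from live-cell kinase translocation reporter (KTR)
movies or per-cell track tables. It is written for quantitative cell
biologists and image analysts working with multi-channel time-lapse data
(nuclear marker + Akt-KTR + ERK-KTR, 4-min frame interval over ~24 h).

The analysis chain it implements:

1. **Synthetic ground truth** (`generate_tracks`, `render_frame`,
   `render_images`) — a tested generator of tracks and 16-bit
   multi-channel movies with known oscillation amplitudes, couplings,
   diffusivity and drift, so every downstream stage is verifiable without
   an external dataset.
2. **Segmentation & quantification** (`segment_nuclei`, `segment_cells`,
   `quantify_ktr`, `measure_morphology`, `measure_frame`,
   `measure_movie`) — adaptive thresholding, nucleus-seeded watershed,
   kinase activity as log2(cytoplasmic/nuclear intensity), best-fit
   ellipse morphology and nuclear polarization.
3. **Tracking** (`build_tracks`, `link_frames`, `resolve_mitosis`,
   `compute_speeds`) — gated Hungarian assignment on nuclear positions
   with a morphology penalty, gap closing, and mitosis trimming.
4. **Oscillation analysis** (`detrend`, `bandpass`, `band_amplitude`,
   `band_amplitudes`, `amplitude_sweep`) — per-cell amplitudes of
   short-period (28–60 min) and long-period (92–124 min) signaling waves:
   for a band-filtered signal s(t), amplitude A = √2 · RMS(s), which
   equals the peak amplitude of a pure tone.
5. **Population statistics** (`quantile_regress`, `emd_1d`,
   `normalized_emd`, `top_quartile_proportion`, `polar_histogram`) —
   conditional-quantile fits min Σ ρ_τ(y − a − bx) with
   ρ_τ(u) = u(τ − 1{u<0}); Wasserstein-1 distances between per-cell
   distributions, normalized by control-replicate distances.
6. **Event analysis** (`detect_ar_peaks`, `align_events`,
   `collect_events`, `stratify_by_polarization`,
   `polarization_regressions`) — aspect-ratio peaks aligned to time zero,
   ERK-minimum lags, elongation vs ERK-drop coupling, and the
   polarization-gated speed burst.
7. **Motility inference** (`build_density`, `infer_motility`,
   `select_terms`, `normalize_conditions`) — weak-form least-squares
   inversion of the advection–diffusion equation
   ∂ρ/∂t = D∇²ρ − **v**·∇ρ on track-derived density fields: D measures
   random migration, **v** directed motion; drug conditions are reported
   as D_drug/D_control and (v∥/|v|)_drug / (v∥/|v|)_control.

`run_pipeline()` ties the stages together from a YAML/`pipeline_config()`
configuration; all artifacts are plain CSV/JSON and byte-reproducible from
the seed.

## Worked example

```r
library(chemotaxr)

# a 24 h movie of 60 cells with the default couplings
sim <- generate_tracks(synth_config(n_cells = 60, rng_seed = 9))

# per-cell band amplitudes and mean speed
amp <- band_amplitudes(sim$tracks)
fit <- quantile_regress(amp$erk_short, amp$mean_speed, taus = 0.5,
                        B = 200, seed = 1)
fit[, c("tau", "slope", "p_value")]
#>   tau    slope p_value
#> 1 0.5 1.191585       0

top_quartile_proportion(amp$mean_speed, amp$erk_short)
#> [1] 1

# aspect-ratio peak events: ERK alignment and the speed burst
ev <- collect_events(sim)
median(ev$events$dt_erk_min, na.rm = TRUE)
#> [1] 0
st <- stratify_by_polarization(ev)
st$window_times[which.max(st$polarized$speed)]  # burst lag, min
#> [1] 16
max(st$polarized$speed)                          # burst height
#> [1] 1.273483
```

The median-quantile slope of speed on short-ERK amplitude recovers the
generator's planted coupling (slope 1.2; the bootstrap p-value underflows
to zero at this coupling strength), every cell in the fastest speed
quartile is also in the top amplitude quartile, aspect-ratio peaks
coincide with ERK minima (median lag 0 min), and polarized events show a
~25% speed burst peaking ~20 min (here the 16-min window sample) after
the elongation peak.

Motility inference on a 2000-cell population:

```r
cfg <- synth_config(n_cells = 2000, duration = 400, D_true = 1,
                    v_true = c(0.05, 0), speed_coupling = NULL,
                    exclusion_radius = 0, init = "gaussian",
                    init_sigma = 80, field_size = c(1200, 1200),
                    noise_sd = c(erk = 0, akt = 0, aspect_ratio = 0),
                    burst_gain = 0, rng_seed = 1)
den <- build_density(generate_tracks(cfg)$tracks, cfg$field_size,
                     h = 30, sigma = 60, dt_agg = 20)
fit <- infer_motility(den)
c(D = fit$D, v_par = fit$v_par)
#>          D      v_par 
#> 0.98097754 0.04708473
```

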