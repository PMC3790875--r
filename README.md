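# vsdqc

Quality metrics for voltage-sensitive dye (VSD) recordings of the pyloric
central pattern generator.

## What this is for

VSDs make it possible to image the membrane potential of many identified
neurons of the crustacean stomatogastric ganglion (STG) at once, but they
bleach, get internalized into the cytoplasm, and can poison the very
network being recorded. Evaluating a dye — or monitoring an ongoing
long-term experiment — requires four quantitative readouts, all of which
this package implements on top of a ground-truth synthetic-data generator:

1. **Pyloric pattern statistics** — burst detection by an interspike-
   interval threshold, then cycle period `P` (PD burst onset to next PD
   burst onset), burst duration, spikes per burst `k`, intraburst
   frequency `(k − 1)/duration`, instantaneous frequency `1/ISI`, and
   phase `(t − t_PD)/P` in `[0, 1)`.
2. **Cycle-triggered signal-to-noise** — amplitude = max − min of the
   cycle-averaged, DC-removed (±3 s sliding mean) optical trace; noise =
   SD over one period of the cycle-averaged, high-pass-filtered
   (±0.01 s sliding mean) trace; `S/N = amplitude / noise SD`.
3. **Photostability** — ROI mean grey values of 8-bit image stacks,
   normalized to the brightest picture; exponential decay fit
   `a·exp(−t/τ) + b`; 256-bin luminosity histograms; and an
   internalization detector (interior brightening above an automatic
   noise floor while the membrane ring dims).
4. **Toxicity profile** — LP instantaneous frequencies classified into
   the closed bands 0–2 Hz (interburst), 3–9 Hz (intermediate) and
   10–55 Hz (intraburst) plus an explicit `other` class; band occupancy
   in 60-s windows on the standard schedule (every 10 min for an hour,
   then 90, 120, 180 min); deviation from a pre-dye control as the
   total-variation distance `½·Σ|p − q|`, classed
   none / moderate / strong, with `extreme` reserved for windows where
   spikes were unidentifiable.

Intended users: electrophysiologists and imaging labs working with
rhythmic preparations who want reproducible, scriptable versions of these
otherwise partly visual analyses — and a simulator to validate them.

## Worked example

```r
library(vsdqc)

# a healthy 17-cycle triphasic rhythm and its LP fluorescence trace
r  <- generate_rhythm(rhythm_spec(n_cycles = 17, period_jitter_sd = 0,
                                  seed = 100))
tr <- render_fluorescence(r, optics_spec(noise_sd = 0.75,
                                         spike_transient_amplitude = 0,
                                         seed = 200), neuron = "LP")
trig <- r$bursts$onset[r$bursts$neuron == "LP"][1:16]
compute_snr(tr, trig)
#> cycle-triggered S/N: amplitude 10.95, noise SD 0.1785, S/N 61.34
#> (n = 16 cycles, period 1.2 s)

head(cycle_metrics(r$spikes), 3)
#>    cycle cycle_period neuron burst_duration n_spikes intraburst_frequency onset_phase offset_phase
#> 1      1          1.2     PD           0.30       10                   30        0.00       0.2500
#> 17     1          1.2     LP           0.35        8                   20        0.40       0.6917
#> 33     1          1.2     PY           0.24        7                   25        0.75       0.9500

# an image stack that bleaches (tau = 1200 s) and internalizes at t = 1200 s
st  <- render_stack(stack_spec(internalization_onset = 1200))
roi <- Reduce(`|`, lapply(st$meta$masks, `[[`, "soma"))
bc  <- bleach_curve(st, roi)
round(bc$normalized, 3)
#> [1] 1.000 0.635 0.417 0.354 0.223 0.149 0.121
attr(bc, "tau")       # fitted decay constant, s (pulled up by the
#> [1] 1323.175        # internalization brightening the somata)
detect_internalization(st)
#> internalization detected at frame 4
```

The S/N of 61 sits near the theoretical `A/(σ/√16) = 10/(0.75/4) ≈ 53`
for this trace (the max−min amplitude has a small positive noise bias);
the per-cycle table reproduces the generator's phases and frequencies
exactly; and the detector flags the first frame at which the cell
interior brightens while the membrane ring keeps bleaching.

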