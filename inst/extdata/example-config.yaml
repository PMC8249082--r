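# Example gpdcnet pipeline configuration.  Every key shown here has the
# same value as the package default (except the inputs, which you must
# supply); omit any section to inherit the defaults.
seed: 1
output_dir: gpdcnet-run
inputs:
  - path: wt_animal1.tsv        # delimited text (+ .meta.yaml sidecar) or EDF
    group: WT
  - path: ko_animal1.tsv
    group: KO
    events: ko_animal1_events.tsv   # optional: columns time_s, label
preprocessing:
  cutoff_hz: 200          # Butterworth low-pass cutoff
  filter_order: 4
  target_fs: 500          # common rate after decimation
  zero_phase: false       # causal (forward-only) filtering
window:
  length_s: 10
  overlap_s: 0
mvar:
  order: 7
grid:
  f_min: 1
  f_max: 200
  spacing: 1
significance:
  method: surrogate       # or: asymptotic
  alpha: 0.05
  n_surrogates: 99
bands:
  width_hz: 10
  line_hz: 60             # 0 disables harmonic exclusion
smoothing:
  k: 4                    # 9-point centered smooth
export_windows: false     # per-window long-format GPDC tables are large
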