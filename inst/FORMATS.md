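# File interfaces

All pipeline artifacts are plain files written under one run directory.

## spikes.csv
One row per spike.
Columns: `unit_id`, `condition_id`, `trial_index` (global index within the
protocol), `spike_time_s` (seconds relative to stimulus onset for gratings
and flicker epochs; relative to movie start for the mapping movie),
`protocol` (`spatial` | `temporal` | `contrast` | `direction` | `flicker` |
`movie`).

## protocol_<set>.csv
One row per trial/epoch.
Columns: `trial_index`, `condition_id`, `kind`, `sf_cpd`, `tf_hz`,
`contrast`, `direction_deg`, `repeat_index`, `duration_s`, `pre_blank_s`,
`post_blank_s`, `t_start_s`, `t_end_s`.

## movie.rds
A `noise_movie`: 3D numeric array (time x y x x) of intensities in [0, 1]
with attributes `deg_per_pixel`, `frame_rate_hz`, `timestamps_s`, `spec`
(the generating `noise_movie_spec`), `clip_fraction`.

## ground_truth.json
Array of objects, one per simulated neuron, with every generator parameter
and class label produced by `sample_population()`.

## cell_reports.csv
One row per unit with every estimated metric and classification
(see `?characterize_unit`), plus `true_*` label columns when ground truth
was available.

## population_summary.json / classification_table.csv / population_report.md
Population-level outputs of `run_report()`: axis-by-level counts and
fractions, metric summaries (mean +/- SEM or median with quartiles as the
distribution warrants), and ground-truth agreement where applicable.
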