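# File formats

All artifacts are plain text. Region and band indices are 1-based
(atlas convention); feature names follow the canonical schema
`r<region>.<family>.<descriptor>[.b<band>]`.

## ROI time series (`*.tsv` + `*.json` sidecar)

One row per region. Columns: `region` (integer atlas index) followed by
`t1..tN` (BOLD-like values, full double precision). The sidecar JSON
(same basename, `.json`) holds `tr_s` (repetition time, seconds),
`participant_id`, `session_id`.

## `participants.csv`

`participant_id, sex (F|M), diagnosis (PD|control), severity_score
(0 for controls), n_sessions`.

## `feature_table.csv` + `feature_table.csv.schema.json`

One row per participant-session: the label columns `participant_id,
session_id, sex, diagnosis, severity_score` followed by one column per
canonical feature name. The schema JSON records the filter bank
(`fLo`, `fHi`, `nBands`), the feature count, and the package version.

## `ranking.csv`

`feature, importance, runs_appeared` — all features ordered by mean
split-frequency importance over the stability runs.

## `selection.csv`

`feature, mean_importance, runs_appeared, wfss_selected` — the stable
feature set, flagging members of the wrapper-refined subset.

## `metrics.json`

`mean` and `sd` of accuracy/F1/precision/recall over outer folds,
`per_fold` values, and `n_features_per_fold`.

## `mca_coordinates.csv`

`id, kind (group|region), dim1, dim2, axis1_share, axis2_share` — joint
principal coordinates of groups and region categories with the per-axis
inertia shares.

## `run_manifest.json`

Configuration snapshot, root seed, package version, timestamp, and an
MD5 digest per written artifact.
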