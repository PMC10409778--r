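# Example simulation configuration for `cannascreen simulate`.
# Any argument of sim_config() may appear here; omitted knobs keep their
# defaults (see ?sim_config for units and meanings).
n_patients: 500
years: [2000, 2021]
notes_per_patient: 6
misspelling_rate: 0.05
dx_code_rate: 0.145
osm_frac: 0.5
seed: 1
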