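# Proposed climate-and-health surveillance configuration: per-hazard
# reportable-outcome ICD code sets and seasonal windows. Heat outcome
# matching is restricted to May-September; flood matching is year-round.
# The drought reportable-outcome set is still in development and ships
# empty (the drought exposure trigger is active regardless).
code_sets:
  heat:
    icd10: [X30]
    icd9: ["992", E900.0, E900.9]
    season: ["05-01", "09-30"]
  flood:
    icd10: [W69, W70, X38]
    icd9: [E908.2, E908.9, E910.8, E910.9]
    season: ~
  drought:
    icd10: []
    icd9: []
    season: ~
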