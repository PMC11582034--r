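# Role declaration for the synthetic example panel. Sign conventions:
# HbA1c reduction positive-is-good, weight loss positive / gain negative,
# mortality odds ratio lower-is-better (undesirable output).
variables:
  dose_frequency: {role: input, unit_label: per day}
  hba1c_reduction: {role: desirable_output, unit_label: "%"}
  weight_change: {role: desirable_output, unit_label: "%"}
  mortality_or: {role: undesirable_output, unit_label: odds ratio}
era_threshold_year: 2010
reference_threshold: 0.01
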