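schema_version: 1
study_id: copd_biomarker_study
entity_column: pat_id
event_columns:
  - visit_id
  - exacerbation_id
date_column: Date
attribute_column: Attribute
value_column: Value
attribute_map:
  calcium: Ncal
  leukocytes: leuco
event_map: []
unmapped_attribute_policy: skip_with_warning
missing_row_policy: error
duplicate_policy: error
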