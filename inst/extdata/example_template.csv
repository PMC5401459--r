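patient_id,redcap_event_name,Ncal,leuco,hb,mono
100001,visit_1,,,,
100002,visit_1,,,,
100001,visit_2,,,,
100002,exacerbation_1,,,,
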