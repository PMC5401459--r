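pat_id,visit_id,exacerbation_id,Date,Attribute,Value
100001,visit_1,,150321,calcium,6.2
100001,visit_1,,150321,leukocytes,6.5
100002,visit_1,,150321,calcium,2.45
100002,visit_1,,150321,leukocytes,6.5
100001,visit_2,,150917,calcium,2.51
100001,visit_2,,150917,leukocytes,6.2
100002,,exacerbation_1,150613,calcium,2.44
100002,,exacerbation_1,150613,leukocytes,8.1
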