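drug,adr_cases,adr_pct,serious_cases,serious_pct,patients_exposed,incidence
levofloxacin,181,68.82,25,83.33,72938,0.0025
moxifloxacin,52,19.77,4,13.33,11590,0.0045
ciprofloxacin,30,11.41,1,3.33,5143,0.0058
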