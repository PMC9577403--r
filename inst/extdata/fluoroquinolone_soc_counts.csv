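soc,drug,cases
Skin and appendage disorders,levofloxacin,119
Skin and appendage disorders,moxifloxacin,33
Skin and appendage disorders,ciprofloxacin,21
Gastrointestinal system disorders,levofloxacin,38
Gastrointestinal system disorders,moxifloxacin,3
Gastrointestinal system disorders,ciprofloxacin,4
Body as a whole-general disorders,levofloxacin,7
Body as a whole-general disorders,moxifloxacin,5
Body as a whole-general disorders,ciprofloxacin,1
Respiratory system disorders,levofloxacin,22
Respiratory system disorders,moxifloxacin,3
Respiratory system disorders,ciprofloxacin,2
Central and peripheral nervous system disorders,levofloxacin,40
Central and peripheral nervous system disorders,moxifloxacin,13
Central and peripheral nervous system disorders,ciprofloxacin,8
Cardiovascular and circulatory system disorders,levofloxacin,41
Cardiovascular and circulatory system disorders,moxifloxacin,17
Cardiovascular and circulatory system disorders,ciprofloxacin,5
Haematological system disorders,levofloxacin,2
Haematological system disorders,moxifloxacin,0
Haematological system disorders,ciprofloxacin,0
Metabolic and nutritional disorders,levofloxacin,2
Metabolic and nutritional disorders,moxifloxacin,0
Metabolic and nutritional disorders,ciprofloxacin,0
Vision disorders,levofloxacin,5
Vision disorders,moxifloxacin,0
Vision disorders,ciprofloxacin,0
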