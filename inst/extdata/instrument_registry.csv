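"instrument","version","reporter","n_items","scale_kind","scale_size"
"ADI-R","Standard","clinician",93,"quality",4
"ADOS-2","Module 1","clinician",29,"quality",4
"ADOS-2","Module 2","clinician",28,"quality",4
"ADOS-2","Module 3","clinician",28,"quality",4
"ADOS-2","Module 4","clinician",38,"quality",4
"BASC-3","Preschool","parent",139,"frequency",4
"BASC-3","Child","parent",175,"frequency",4
"BASC-3","Adolescent","parent",192,"frequency",4
"BRIEF2","Parent","parent",63,"frequency",3
"CBCL","Preschool","parent",100,"frequency",3
"CBCL","School-age","parent",113,"frequency",3
"Conners 3","Parent","parent",110,"frequency",4
"SRS-2","Preschool","parent",65,"frequency",4
"SRS-2","School-age","parent",65,"frequency",4
"VADRS","Parent","parent",55,"frequency",4
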