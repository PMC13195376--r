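source,condition,year,numerator,denominator
MNEHRC,diabetes,2022,415914,4376805
MNEHRC,hypertension,2021,1365413,4243000
PLACES,diabetes,2022,435481,4389028
PLACES,hypertension,2021,1311459,4389028
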