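stratum,exposure_level,survived,died,is_reference
black,nonsmoker,500,150,1
black,smoker,200,150,0
white,nonsmoker,2700,500,1
white,smoker,500,300,0
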