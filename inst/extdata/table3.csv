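stratum,exposure_level,survived,died,is_reference
50-59,never,42568,1169,1
50-59,former,26324,959,0
50-59,current,34958,2674,0
60-69,never,39334,2109,1
60-69,former,29930,2624,0
60-69,current,26392,4335,0
70-79,never,21416,4833,1
70-79,former,17897,6310,0
70-79,current,10069,4998,0
80-84,never,5325,4705,1
80-84,former,3976,4673,0
80-84,current,1566,1977,0
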