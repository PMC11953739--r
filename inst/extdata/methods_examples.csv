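plate_id,assay_type,orientation,odorant,vehicle,cohort,c_left,c_midleft,c_midright,c_right
EX1,chemotaxis,A,butanone 10%,ethanol,d1,1,45,45,9
EX2,chemotaxis,A,butanone 10%,ethanol,d1,5,15,35,45
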