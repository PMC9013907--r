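run_label,a,b,c,response_pg_per_mg,factor_value,significant
0,-1,-1,-1,81.8,NA,NA
a,1,-1,-1,74.9,3.55,No
b,-1,1,-1,130.6,34.95,Yes
c,-1,-1,1,180.8,66.95,Yes
ab,1,1,-1,168.0,6.5,No
ac,1,-1,1,181.8,-11.7,No
bc,-1,1,1,188.9,-36,Yes
abc,1,1,1,171.6,NA,NA
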