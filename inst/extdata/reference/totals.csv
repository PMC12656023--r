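group,total_min,total_max,peq_hi_min,peq_hi_max,cb_hi
toddlers,31.07,34.81,7.06,7.91,3.98
adolescents,17.40,19.50,3.95,4.43,2.15
adults,14.54,16.35,3.30,3.72,1.76
elderly,15.06,16.99,3.42,3.86,1.82
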