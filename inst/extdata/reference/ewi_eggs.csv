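group,compound,ewi_min,ewi_max
toddlers,PFHpA,0.00,0.03
toddlers,PFHxA,0.00,0.00
toddlers,PFHxS,0.00,0.00
toddlers,PFOA,0.63,0.63
toddlers,PFOS,3.15,3.15
toddlers,PFTrDA,0.00,0.02
toddlers,PFUnDA,0.02,0.02
adolescents,PFHpA,0.00,0.01
adolescents,PFHxA,0.00,0.00
adolescents,PFHxS,0.00,0.00
adolescents,PFOA,0.26,0.26
adolescents,PFOS,1.33,1.33
adolescents,PFTrDA,0.00,0.00
adolescents,PFUnDA,0.01,0.01
adults,PFHpA,0.00,0.01
adults,PFHxA,0.00,0.00
adults,PFHxS,0.00,0.00
adults,PFOA,0.20,0.20
adults,PFOS,1.02,1.02
adults,PFTrDA,0.00,0.00
adults,PFUnDA,0.01,0.01
elderly,PFHpA,0.00,0.01
elderly,PFHxA,0.00,0.00
elderly,PFHxS,0.00,0.00
elderly,PFOA,0.19,0.19
elderly,PFOS,0.96,0.96
elderly,PFTrDA,0.00,0.00
elderly,PFUnDA,0.01,0.01
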