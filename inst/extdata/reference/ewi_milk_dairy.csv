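group,compound,ewi_min,ewi_max
toddlers,PFBS,0.00,0.00
toddlers,PFDA,0.03,0.08
toddlers,PFHxA,0.00,0.00
toddlers,PFHxS,0.00,0.00
toddlers,PFNA,0.07,0.07
toddlers,PFOA,0.12,0.12
toddlers,PFOS,0.29,0.29
toddlers,PFPeA,0.03,0.03
adolescents,PFBS,0.00,0.00
adolescents,PFDA,0.01,0.02
adolescents,PFHxA,0.00,0.00
adolescents,PFHxS,0.00,0.00
adolescents,PFNA,0.02,0.02
adolescents,PFOA,0.03,0.03
adolescents,PFOS,0.08,0.08
adolescents,PFPeA,0.01,0.01
adults,PFBS,0.00,0.00
adults,PFDA,0.00,0.01
adults,PFHxA,0.00,0.00
adults,PFHxS,0.00,0.00
adults,PFNA,0.01,0.01
adults,PFOA,0.02,0.02
adults,PFOS,0.04,0.04
adults,PFPeA,0.00,0.00
elderly,PFBS,0.00,0.00
elderly,PFDA,0.00,0.01
elderly,PFHxA,0.00,0.00
elderly,PFHxS,0.00,0.00
elderly,PFNA,0.01,0.01
elderly,PFOA,0.01,0.01
elderly,PFOS,0.04,0.04
elderly,PFPeA,0.00,0.00
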