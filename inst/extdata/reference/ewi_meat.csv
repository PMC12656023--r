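group,compound,ewi_min,ewi_max
toddlers,PFBA,0.00,0.00
toddlers,PFBS,0.00,0.00
toddlers,PFDA,0.18,0.44
toddlers,PFDS,0.09,0.09
toddlers,PFDoDA,0.32,0.32
toddlers,PFHpA,0.00,0.02
toddlers,PFHpS,0.00,0.01
toddlers,PFHxA,0.00,0.00
toddlers,PFHxS,0.00,0.00
toddlers,PFNA,0.29,0.29
toddlers,PFOA,0.57,0.57
toddlers,PFOS,2.53,2.53
toddlers,PFPeA,0.00,0.00
toddlers,PFTeDA,0.00,0.00
toddlers,PFTrDA,0.01,0.05
toddlers,PFUnDA,0.11,0.11
adolescents,PFBA,0.00,0.00
adolescents,PFBS,0.00,0.00
adolescents,PFDA,0.12,0.31
adolescents,PFDS,0.06,0.06
adolescents,PFDoDA,0.23,0.23
adolescents,PFHpA,0.00,0.01
adolescents,PFHpS,0.00,0.00
adolescents,PFHxA,0.00,0.00
adolescents,PFHxS,0.00,0.00
adolescents,PFNA,0.21,0.21
adolescents,PFOA,0.40,0.40
adolescents,PFOS,1.80,1.80
adolescents,PFPeA,0.00,0.00
adolescents,PFTeDA,0.00,0.00
adolescents,PFTrDA,0.00,0.04
adolescents,PFUnDA,0.07,0.07
adults,PFBA,0.00,0.00
adults,PFBS,0.00,0.00
adults,PFDA,0.09,0.22
adults,PFDS,0.04,0.04
adults,PFDoDA,0.16,0.16
adults,PFHpA,0.00,0.01
adults,PFHpS,0.00,0.00
adults,PFHxA,0.00,0.00
adults,PFHxS,0.00,0.00
adults,PFNA,0.14,0.14
adults,PFOA,0.28,0.28
adults,PFOS,1.26,1.26
adults,PFPeA,0.00,0.00
adults,PFTeDA,0.00,0.00
adults,PFTrDA,0.00,0.03
adults,PFUnDA,0.05,0.05
elderly,PFBA,0.00,0.00
elderly,PFBS,0.00,0.00
elderly,PFDA,0.08,0.19
elderly,PFDS,0.04,0.04
elderly,PFDoDA,0.14,0.14
elderly,PFHpA,0.00,0.01
elderly,PFHpS,0.00,0.00
elderly,PFHxA,0.00,0.00
elderly,PFHxS,0.00,0.00
elderly,PFNA,0.12,0.12
elderly,PFOA,0.25,0.25
elderly,PFOS,1.09,1.09
elderly,PFPeA,0.00,0.00
elderly,PFTeDA,0.00,0.00
elderly,PFTrDA,0.00,0.02
elderly,PFUnDA,0.05,0.05
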