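group,compound,ewi_min,ewi_max
toddlers,PFBS,0.00,0.00
toddlers,PFDA,1.93,4.83
toddlers,PFDS,0.00,0.00
toddlers,PFDoDA,0.35,0.35
toddlers,PFHpA,0.00,0.04
toddlers,PFHxA,0.00,0.00
toddlers,PFHxS,0.01,0.01
toddlers,PFNA,2.56,2.56
toddlers,PFOA,1.38,1.38
toddlers,PFOS,15.59,15.59
toddlers,PFPeA,0.02,0.02
toddlers,PFTeDA,0.00,0.00
toddlers,PFTrDA,0.04,0.41
toddlers,PFUnDA,0.73,0.73
adolescents,PFBS,0.00,0.00
adolescents,PFDA,1.09,2.72
adolescents,PFDS,0.00,0.00
adolescents,PFDoDA,0.20,0.20
adolescents,PFHpA,0.00,0.00
adolescents,PFHxA,0.00,0.00
adolescents,PFHxS,0.01,0.01
adolescents,PFNA,1.44,1.44
adolescents,PFOA,0.77,0.77
adolescents,PFOS,8.78,8.78
adolescents,PFPeA,0.01,0.01
adolescents,PFTeDA,0.00,0.00
adolescents,PFTrDA,0.02,0.23
adolescents,PFUnDA,0.41,0.41
adults,PFBS,0.00,0.00
adults,PFDA,0.96,2.39
adults,PFDS,0.00,0.00
adults,PFDoDA,0.18,0.18
adults,PFHpA,0.00,0.02
adults,PFHxA,0.00,0.00
adults,PFHxS,0.01,0.01
adults,PFNA,1.27,1.27
adults,PFOA,0.68,0.68
adults,PFOS,7.72,7.72
adults,PFPeA,0.01,0.01
adults,PFTeDA,0.00,0.00
adults,PFTrDA,0.02,0.20
adults,PFUnDA,0.36,0.36
elderly,PFBS,0.00,0.00
elderly,PFDA,1.03,2.58
elderly,PFDS,0.00,0.00
elderly,PFDoDA,0.19,0.19
elderly,PFHpA,0.00,0.02
elderly,PFHxA,0.00,0.00
elderly,PFHxS,0.01,0.01
elderly,PFNA,1.37,1.37
elderly,PFOA,0.73,0.73
elderly,PFOS,8.31,8.31
elderly,PFPeA,0.01,0.01
elderly,PFTeDA,0.00,0.00
elderly,PFTrDA,0.02,0.22
elderly,PFUnDA,0.39,0.39
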