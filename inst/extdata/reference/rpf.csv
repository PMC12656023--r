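compound,rpf_min,rpf_max,read_across
PFBA,0.1,0.1,FALSE
PFBS,0,0,FALSE
PFDA,4,10,FALSE
PFDS,2,2,FALSE
PFDoDA,3,3,FALSE
PFHpA,0,1,FALSE
PFHpS,0.6,2,TRUE
PFPeS,0.001,0.6,TRUE
PFHxA,0,0,FALSE
PFHxS,0.6,0.6,FALSE
PFHxDA,0.02,0.02,FALSE
PFNA,10,10,FALSE
PFOA,1,1,FALSE
PFOS,2,2,FALSE
PFODA,0.02,0.02,FALSE
PFPeA,0.03,0.03,FALSE
PFTeDA,0.3,0.3,FALSE
PFTrDA,0.3,3,TRUE
PFUnDA,4,4,FALSE
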