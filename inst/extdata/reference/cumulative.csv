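food_category,group,cumulative_min,cumulative_max
milk_dairy,toddlers,0.54,0.59
milk_dairy,adolescents,0.14,0.15
milk_dairy,adults,0.07,0.08
milk_dairy,elderly,0.07,0.07
meat,toddlers,4.11,4.44
meat,adolescents,2.91,3.15
meat,adults,2.04,2.20
meat,elderly,1.77,1.91
eggs,toddlers,3.80,3.85
eggs,adolescents,1.61,1.63
eggs,adults,1.23,1.24
eggs,elderly,1.16,1.18
fish_seafood,toddlers,22.62,25.93
fish_seafood,adolescents,12.74,14.57
fish_seafood,adults,11.20,12.83
fish_seafood,elderly,12.06,13.83
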