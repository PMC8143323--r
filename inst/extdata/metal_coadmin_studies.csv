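fq,metal,metal_source,pct_cmax,pct_auc,pct_ka,reference_tag
ciprofloxacin,Al,aluminum hydroxide,-81.1,-84.6,-14.3,72
ciprofloxacin,Al,aluminum hydroxide,-84.6,-87.5,-60.6,71
ciprofloxacin,Al,sucralfate,-90.0,-87.5,NA,10
ciprofloxacin,Al/Mg,Maalox,-80.1,-84.9,157.9,9
ciprofloxacin,Al/Mg,didanosine,-92.6,-98.3,49.2,11
ciprofloxacin,Ca,Titralac,-37.9,-41.1,5.9,12
enoxacin,Al,aluminum hydroxide,-78.3,-84.2,NA,71
enoxacin,Al/Mg,Maalox,-70.0,-73.2,-52.1,15
fleroxacin,Al,aluminum hydroxide,-25.0,-17.2,-47.6,71
fleroxacin,Al,sucralfate,-26.4,-24.0,-40.3,24
lomefloxacin,Al,aluminum hydroxide,-54.5,-34.8,-55.1,71
lomefloxacin,Al,Kolantyl,-46.1,-40.8,25.6,16
norfloxacin,Al,aluminum hydroxide,-93.3,-97.0,NA,71
norfloxacin,Al,sucralfate,-92.2,-91.3,-23.8,20
norfloxacin,Al/Mg,Maalox,-95.1,NA,-6.1,21
norfloxacin,Ca,Titralac,-65.9,-62.6,-80.2,21
ofloxacin,Al,aluminum hydroxide,-59.4,-47.9,-65.0,71
ofloxacin,Al,sucralfate,-69.5,-61.0,-46.2,20
pefloxacin,Al/Mg,Maalox,-60.8,-54.3,-57.5,17
rufloxacin,Al/Mg,Maalox,6.1,-15.2,-34.0,18
levofloxacin,Al,aluminum hydroxide,-66.7,-45.2,-55.5,71
sparfloxacin,Al,aluminum hydroxide,-22.2,-35.1,47.1,71
tosufloxacin,Al,aluminum hydroxide,-66.7,-70.8,-67.4,71
gatifloxacin,Al/Mg,Maalox,-68.4,-60.8,-13.5,73
moxifloxacin,Al,sucralfate,-79.5,-59.9,-80.7,74
moxifloxacin,Ca,Calcium-Sandoz,-15.5,-2.4,-74.1,75
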