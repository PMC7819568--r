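"site_id","region_id","x","y","transect_offset_m","longitude","latitude"
"R01_0","R01",2827.10764538683,1570.7469840534,0,-97.6704922303856,30.5141260474902
"R01_300","R01",3127.10764538683,1570.7469840534,300,-97.6673609980468,30.5141260474902
"R01_600","R01",3427.10764538683,1570.7469840534,600,-97.6642297657081,30.5141260474902
"R01_900","R01",3727.10764538683,1570.7469840534,900,-97.6610985333694,30.5141260474902
"R01_1200","R01",4027.10764538683,1570.7469840534,1200,-97.6579673010306,30.5141260474902
"R02","R02",5152.10261913389,2133.67849003337,NA,-97.6462252322216,30.5191886051573
"R03","R03",3287.97990026325,3974.41013854556,NA,-97.6656819033573,30.5357426797139
"R04","R04",5784.13277643174,5540.18032174185,NA,-97.639628454663,30.5498239698205
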