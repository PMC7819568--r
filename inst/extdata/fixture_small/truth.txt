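hypothesis=B
lambda=5
philopatry=0.5
seed=1
migration=0.95,0.0074719067,0.007334314,0.006874163,0.01704239,0.95,0.020899657,0.020932175,0.017172567,0.021454372,0.95,0.022193662,0.015785043,0.021073721,0.021766029,0.95
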