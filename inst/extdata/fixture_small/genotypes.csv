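4,50,8,5,4,7,6,7,7,7,7
synthetic fixture,,,,,,,,,,
Ind,Pop,L01,,L02,,L03,,L04,,
R01_0_i1,R01_0,24,32,26,28,20,30,18,28,
R01_0_i2,R01_0,24,26,18,22,32,36,32,32,
R01_0_i3,R01_0,28,28,18,22,30,32,32,32,
R01_0_i4,R01_0,26,38,18,36,32,36,18,32,
R01_0_i5,R01_0,24,26,26,28,20,30,18,18,
R01_300_i1,R01_300,24,24,22,22,30,36,32,32,
R01_300_i2,R01_300,24,38,28,36,20,30,32,34,
R01_300_i3,R01_300,32,32,20,36,30,30,28,28,
R01_300_i4,R01_300,28,38,18,34,30,36,32,32,
R01_600_i1,R01_600,24,38,32,38,30,30,18,32,
R01_600_i2,R01_600,24,38,22,36,36,36,32,32,
R01_600_i3,R01_600,26,28,22,30,36,36,32,32,
R01_600_i4,R01_600,24,28,22,28,30,30,18,18,
R01_600_i5,R01_600,26,38,20,30,18,36,28,32,
R01_600_i6,R01_600,26,32,22,28,30,34,32,32,
R01_600_i7,R01_600,24,26,22,28,30,36,32,32,
R01_900_i1,R01_900,28,32,22,26,20,30,18,32,
R01_900_i2,R01_900,24,28,22,30,30,30,32,32,
R01_900_i3,R01_900,28,38,22,22,36,36,18,32,
R01_900_i4,R01_900,28,38,22,22,36,36,18,32,
R01_900_i5,R01_900,24,26,22,22,20,30,18,18,
R01_900_i6,R01_900,26,28,30,36,20,30,18,32,
R01_1200_i1,R01_1200,24,28,22,28,20,32,18,18,
R01_1200_i2,R01_1200,36,38,28,36,20,30,34,34,
R01_1200_i3,R01_1200,24,38,22,38,30,36,18,32,
R01_1200_i4,R01_1200,24,26,36,36,20,30,16,18,
R01_1200_i5,R01_1200,24,28,18,28,30,36,18,32,
R01_1200_i6,R01_1200,32,38,22,36,18,30,22,30,
R01_1200_i7,R01_1200,24,38,28,38,30,32,18,18,
R02_i1,R02,28,38,20,22,30,38,24,34,
R02_i2,R02,24,28,22,22,18,38,16,24,
R02_i3,R02,24,28,28,36,30,30,34,34,
R02_i4,R02,24,26,20,20,30,36,28,32,
R02_i5,R02,24,26,28,28,36,36,34,34,
R02_i6,R02,26,28,22,28,18,36,18,18,
R02_i7,R02,28,38,26,28,30,30,18,28,
R03_i1,R03,28,32,20,36,30,32,22,34,
R03_i2,R03,28,32,22,22,18,30,22,30,
R03_i3,R03,20,36,20,36,32,36,16,22,
R03_i4,R03,26,36,24,36,18,32,16,22,
R03_i5,R03,28,32,20,36,18,30,22,30,
R03_i6,R03,20,36,22,22,18,32,22,30,
R03_i7,R03,20,38,36,36,32,32,16,16,
R04_i1,R04,32,32,20,36,30,30,28,28,
R04_i2,R04,32,38,36,38,18,30,16,16,
R04_i3,R04,32,32,20,26,20,30,16,22,
R04_i4,R04,16,28,20,26,18,30,20,22,
R04_i5,R04,28,32,22,28,18,18,16,28,
R04_i6,R04,30,32,20,20,30,30,16,32,
R04_i7,R04,24,32,28,30,18,30,16,18,
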