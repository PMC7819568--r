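ncols 40
nrows 40
xllcorner 0
yllcorner 0
cellsize 210
NODATA_value -9999
41 41 41 41 41 71 71 71 71 71 41 41 41 41 41 71 71 71 71 71 41 41 41 41 41 71 71 71 71 71 71 71 71 71 71 22 22 22 22 22
41 41 41 41 41 71 71 71 71 71 41 41 41 41 41 71 71 71 71 71 41 41 41 41 41 71 71 71 71 71 71 71 71 71 71 22 22 22 22 22
41 41 41 41 41 71 71 71 71 71 41 41 41 41 41 71 71 71 71 71 41 41 41 41 41 71 71 71 71 71 71 71 71 71 71 22 22 22 22 22
41 41 41 41 41 71 71 71 71 71 41 41 41 41 41 71 71 71 71 71 41 41 41 41 41 71 71 71 71 71 71 71 71 71 71 22 22 22 22 22
41 41 41 41 41 71 71 71 71 71 41 41 41 41 41 71 71 71 71 71 41 41 41 41 41 71 71 71 71 71 71 71 71 71 71 22 22 22 22 22
71 71 71 71 71 11 11 11 11 11 81 81 81 81 81 81 81 81 81 81 22 22 22 22 22 71 71 71 71 71 81 81 81 81 81 71 71 71 71 71
71 71 71 71 71 11 11 11 11 11 81 81 81 81 81 81 81 81 81 81 22 22 22 22 22 71 71 71 71 71 81 81 81 81 81 71 71 71 71 71
71 71 71 71 71 11 11 11 11 11 81 81 81 81 81 81 81 81 81 81 22 22 22 22 22 71 71 71 71 71 81 81 81 81 81 71 71 71 71 71
71 71 71 71 71 11 11 11 11 11 81 81 81 81 81 81 81 81 81 81 22 22 22 22 22 71 71 71 71 71 81 81 81 81 81 71 71 71 71 71
71 71 71 71 71 11 11 11 11 11 81 81 81 81 81 81 81 81 81 81 22 22 22 22 22 71 71 71 71 71 81 81 81 81 81 71 71 71 71 71
22 22 22 22 22 71 71 71 71 71 81 81 81 81 81 71 71 71 71 71 41 41 41 41 41 22 22 22 22 22 71 71 71 71 71 81 81 81 81 81
22 22 22 22 22 71 71 71 71 71 81 81 81 81 81 71 71 71 71 71 41 41 41 41 41 22 22 22 22 22 71 71 71 71 71 81 81 81 81 81
22 22 22 22 22 71 71 71 71 71 81 81 81 81 81 71 71 71 71 71 41 41 41 41 41 22 22 22 22 22 71 71 71 71 71 81 81 81 81 81
22 22 22 22 22 71 71 71 71 71 81 81 81 81 81 71 71 71 71 71 41 41 41 41 41 22 22 22 22 22 71 71 71 71 71 81 81 81 81 81
22 22 22 22 22 71 71 71 71 71 81 81 81 81 81 71 71 71 71 71 41 41 41 41 41 22 22 22 22 22 71 71 71 71 71 81 81 81 81 81
81 81 81 81 81 22 22 22 22 22 81 81 81 81 81 71 71 71 71 71 81 81 81 81 81 41 41 41 41 41 41 41 41 41 41 41 41 41 41 41
81 81 81 81 81 22 22 22 22 22 81 81 81 81 81 71 71 71 71 71 81 81 81 81 81 41 41 41 41 41 41 41 41 41 41 41 41 41 41 41
81 81 81 81 81 22 22 22 22 22 81 81 81 81 81 71 71 71 71 71 81 81 81 81 81 41 41 41 41 41 41 41 41 41 41 41 41 41 41 41
81 81 81 81 81 22 22 22 22 22 81 81 81 81 81 71 71 71 71 71 81 81 81 81 81 41 41 41 41 41 41 41 41 41 41 41 41 41 41 41
81 81 81 81 81 22 22 22 22 22 81 81 81 81 81 71 71 71 71 71 81 81 81 81 81 41 41 41 41 41 41 41 41 41 41 41 41 41 41 41
41 41 41 41 41 11 11 11 11 11 71 71 71 71 71 22 22 22 22 22 22 22 22 22 22 71 71 71 71 71 11 11 11 11 11 41 41 41 41 41
41 41 41 41 41 11 11 11 11 11 71 71 71 71 71 22 22 22 22 22 22 22 22 22 22 71 71 71 71 71 11 11 11 11 11 41 41 41 41 41
41 41 41 41 41 11 11 11 11 11 71 71 71 71 71 22 22 22 22 22 22 22 22 22 22 71 71 71 71 71 11 11 11 11 11 41 41 41 41 41
41 41 41 41 41 11 11 11 11 11 71 71 71 71 71 22 22 22 22 22 22 22 22 22 22 71 71 71 71 71 11 11 11 11 11 41 41 41 41 41
41 41 41 41 41 11 11 11 11 11 71 71 71 71 71 22 22 22 22 22 22 22 22 22 22 71 71 71 71 71 11 11 11 11 11 41 41 41 41 41
71 71 71 71 71 81 81 81 81 81 71 71 71 71 71 71 71 71 71 71 22 22 22 22 22 11 11 11 11 11 22 22 22 22 22 81 81 81 81 81
71 71 71 71 71 81 81 81 81 81 71 71 71 71 71 71 71 71 71 71 22 22 22 22 22 11 11 11 11 11 22 22 22 22 22 81 81 81 81 81
71 71 71 71 71 81 81 81 81 81 71 71 71 71 71 71 71 71 71 71 22 22 22 22 22 11 11 11 11 11 22 22 22 22 22 81 81 81 81 81
71 71 71 71 71 81 81 81 81 81 71 71 71 71 71 71 71 71 71 71 22 22 22 22 22 11 11 11 11 11 22 22 22 22 22 81 81 81 81 81
71 71 71 71 71 81 81 81 81 81 71 71 71 71 71 71 71 71 71 71 22 22 22 22 22 11 11 11 11 11 22 22 22 22 22 81 81 81 81 81
11 11 11 11 11 71 71 71 71 71 71 71 71 71 71 71 71 71 71 71 41 41 41 41 41 71 71 71 71 71 71 71 71 71 71 11 11 11 11 11
11 11 11 11 11 71 71 71 71 71 71 71 71 71 71 71 71 71 71 71 41 41 41 41 41 71 71 71 71 71 71 71 71 71 71 11 11 11 11 11
11 11 11 11 11 71 71 71 71 71 71 71 71 71 71 71 71 71 71 71 41 41 41 41 41 71 71 71 71 71 71 71 71 71 71 11 11 11 11 11
11 11 11 11 11 71 71 71 71 71 71 71 71 71 71 71 71 71 71 71 41 41 41 41 41 71 71 71 71 71 71 71 71 71 71 11 11 11 11 11
11 11 11 11 11 71 71 71 71 71 71 71 71 71 71 71 71 71 71 71 41 41 41 41 41 71 71 71 71 71 71 71 71 71 71 11 11 11 11 11
22 22 22 22 22 41 41 41 41 41 71 71 71 71 71 71 71 71 71 71 71 71 71 71 71 81 81 81 81 81 81 81 81 81 81 41 41 41 41 41
22 22 22 22 22 41 41 41 41 41 71 71 71 71 71 71 71 71 71 71 71 71 71 71 71 81 81 81 81 81 81 81 81 81 81 41 41 41 41 41
22 22 22 22 22 41 41 41 41 41 71 71 71 71 71 71 71 71 71 71 71 71 71 71 71 81 81 81 81 81 81 81 81 81 81 41 41 41 41 41
22 22 22 22 22 41 41 41 41 41 71 71 71 71 71 71 71 71 71 71 71 71 71 71 71 81 81 81 81 81 81 81 81 81 81 41 41 41 41 41
22 22 22 22 22 41 41 41 41 41 71 71 71 71 71 71 71 71 71 71 71 71 71 71 71 81 81 81 81 81 81 81 81 81 81 41 41 41 41 41
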