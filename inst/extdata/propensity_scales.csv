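"residue","parker","chou_fasman_turn","emini","kolaskar"
"A",2.1,0.66,0.49,1.064
"C",1.4,1.19,0.26,1.412
"D",10,1.46,0.81,0.866
"E",7.8,0.74,0.84,0.851
"F",-9.2,0.6,0.42,1.091
"G",5.7,1.56,0.48,0.874
"H",2.1,0.95,0.66,1.105
"I",-8,0.47,0.34,1.152
"K",5.7,1.01,0.97,0.93
"L",-9.2,0.59,0.4,1.25
"M",-4.2,0.6,0.48,0.826
"N",7,1.56,0.78,0.776
"P",2.1,1.52,0.75,1.064
"Q",6,0.98,0.84,1.015
"R",4.2,0.95,0.95,0.873
"S",6.5,1.43,0.65,1.012
"T",5.2,0.96,0.7,0.909
"V",-3.7,0.5,0.36,1.383
"W",-10,0.96,0.51,0.893
"Y",-1.9,1.14,0.76,1.161
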