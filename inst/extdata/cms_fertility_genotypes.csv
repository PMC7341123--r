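population,environment,genotype,theoretical_ratio,grade_I,grade_II,grade_III,grade_IV,grade_V
F2,Chengdu_2018_spring,Rf4Rf4,1:2:1,0,0,4,1,322
F2,Chengdu_2018_spring,Rf4rf4,1:2:1,0,0,3,0,625
F2,Chengdu_2018_spring,rf4rf4,1:2:1,5,28,22,9,227
F2,Jinghong_2018_fall,Rf4Rf4,1:2:1,0,0,0,0,630
F2,Jinghong_2018_fall,Rf4rf4,1:2:1,0,0,2,0,1314
F2,Jinghong_2018_fall,rf4rf4,1:2:1,11,58,36,25,531
BC1F1,Chengdu_2018_spring,Rf4rf4,1:1,0,0,0,1,253
BC1F1,Chengdu_2018_spring,rf4rf4,1:1,45,97,34,13,31
BC1F1,Jinghong_2018_fall,Rf4rf4,1:1,0,0,0,0,130
BC1F1,Jinghong_2018_fall,rf4rf4,1:1,24,46,7,3,28
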