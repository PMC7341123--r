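environment,population,grade_I,grade_II,grade_III,grade_IV,grade_V
Chengdu_2018_spring,F2,5,28,29,10,1174
Chengdu_2018_spring,BC1F1,45,97,34,14,284
Jinghong_2018_fall,F2,11,58,38,25,2475
Jinghong_2018_fall,BC1F1,24,46,7,3,158
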