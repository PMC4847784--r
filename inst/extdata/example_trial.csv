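time,event,treatment,true_class
0.35206307910719598,1,1,0
0.075316941993389855,0,0,0
1.2870888262567046,1,0,1
0.42658858656428411,0,0,0
3.0185564382184036,1,0,1
0.7108439604884812,1,1,1
0.50650522911122875,1,1,1
1.4418790107200676,0,1,1
0.33271672155890686,0,1,1
0.02882586931809783,1,0,1
0.3512145490385592,1,0,1
0.56094264853304165,1,1,1
1.5095919399550228,1,1,0
0.77829363937945384,1,0,1
0.65631697047501802,1,0,1
0.078744232937874525,0,1,0
1.1238824792672772,1,1,0
0.62291027673742339,0,0,1
0.62673096478517576,1,1,1
4.0158192819723855,0,0,1
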