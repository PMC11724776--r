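item,kappa
1,0.491412522953948
2,0.9014399842303974
3,0.8817648302473619
4,0.8997297981930255
5,0.8818438576944004
6,0.9032531638273871
7,0.8525144123783784
8,0.8879430874249528
9,0.860740984561239
10,0.8526521806676457
12,0.7176368375325803
13,0.8094324224950453
14,0.7710117418557431
15,0.6767477108659646
16,0.6465760481198813
17,0.6723254913161365
18,0.8176202774301764
total,0.732577132777593
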