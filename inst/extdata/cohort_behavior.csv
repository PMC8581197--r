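subject_id,total_bci_runs,avg_bci_performance,arat_baseline,arat_change,grip_baseline_lb,grip_change_lb
1,502,6.094,3,-1,0,0
2,651,7.043,3,1,23.33,-10
3,488,5.76,57,0,51,-3
4,381,5.83,23,17,8.33,15.33
5,318,5.23,0,0,0,0
6,514,4.65,56,1,22.33,10
7,464,4.9,7,0,1.33,5
8,471,5.47,3,1,17,8.67
9,372,5.49,0,2,0,0
10,392,6.92,3,1,0,0
11,360,7.92,3,-3,0,0
12,451,5.84,57,0,6.33,8
13,570,5.52,9,2,0,0
14,381,5.83,3,2,0,0.33
15,334,5.83,57,0,49,-7.33
16,355,5.18,0,0,0,0
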