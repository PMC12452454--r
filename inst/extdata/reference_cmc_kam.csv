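participant,trial,condition,segment,cmc
1,1,preferred,early,0.98
1,2,preferred,early,0.99
2,1,preferred,early,0.97
2,2,preferred,early,0.67
3,1,preferred,early,0.83
3,2,preferred,early,0.93
1,1,preferred,late,NaN
1,2,preferred,late,0.29
2,1,preferred,late,0.55
2,2,preferred,late,NaN
3,1,preferred,late,NaN
3,2,preferred,late,NaN
1,1,reduced,early,0.74
1,2,reduced,early,0.86
2,1,reduced,early,0.83
2,2,reduced,early,0.89
3,1,reduced,early,0.66
3,2,reduced,early,0.75
1,1,reduced,late,NaN
1,2,reduced,late,NaN
2,1,reduced,late,NaN
2,2,reduced,late,NaN
3,1,reduced,late,NaN
3,2,reduced,late,NaN
1,1,lowest,early,0.62
1,2,lowest,early,0.80
2,1,lowest,early,0.82
2,2,lowest,early,0.43
3,1,lowest,early,0.52
3,2,lowest,early,0.48
1,1,lowest,late,0.77
1,2,lowest,late,NaN
2,1,lowest,late,NaN
2,2,lowest,late,0.23
3,1,lowest,late,NaN
3,2,lowest,late,NaN
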