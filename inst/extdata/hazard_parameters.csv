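# Type 2 diabetes hazard parameters: relative risk per 100 g/day increment in glycemic
# load and exponential rate at which the effect phases in after an intake change.
parameter,value,lo,hi,units
rr_per_100g_gl,1.45,1.31,1.61,relative risk per 100 g/day glycemic load
effect_rate,0.1315789473684211,0.0680272108843537,0.3571428571428571,per year (1/7.6; 95% CI 1/14.7 to 1/2.8)
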