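# Price elasticities of beverage demand with respect to a 1% change in SSB price,
# by demographic margin (point estimate and 95% CI), national household survey 2009/10.
beverage,cohort,estimate,lo,hi
milk,low,0.055,0.013,0.096
milk,mid,0.046,0.010,0.083
milk,high,0.046,0.010,0.083
milk,urban,0.049,0.010,0.087
milk,rural,0.049,0.012,0.087
milk,overall,0.049,0.011,0.087
ssb,low,-0.90,-0.93,-0.86
ssb,mid,-0.96,-1.00,-0.92
ssb,high,-0.96,-1.00,-0.92
ssb,urban,-0.94,-0.98,-0.90
ssb,rural,-0.94,-0.98,-0.90
ssb,overall,-0.94,-0.98,-0.90
juice,low,0.32,0.31,0.36
juice,mid,0.30,0.25,0.35
juice,high,0.30,0.25,0.35
juice,urban,0.31,0.27,0.35
juice,rural,0.31,0.27,0.35
juice,overall,0.31,0.27,0.35
coffee,low,0.0016,-0.077,0.051
coffee,mid,0.0054,-0.058,0.084
coffee,high,0.0054,-0.058,0.084
coffee,urban,0.0041,-0.064,0.073
coffee,rural,0.0041,-0.064,0.073
coffee,overall,0.0041,-0.064,0.073
tea,low,0.10,0.062,0.131
tea,mid,0.14,0.12,0.18
tea,high,0.14,0.12,0.18
tea,urban,0.13,0.098,0.16
tea,rural,0.13,0.098,0.16
tea,overall,0.13,0.098,0.16
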