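# Population shares of the demographic margins among Indian adults aged 25-65
# (census-style defaults used to weight the 24 simulation cohorts), plus the adult
# population size used to scale relative declines to absolute case counts.
margin,level,share
age,25-44,0.62
age,45-65,0.38
sex,M,0.515
sex,F,0.485
income,low,0.3333333
income,mid,0.3333333
income,high,0.3333334
residence,urban,0.31
residence,rural,0.69
population,adults_25_65,550000000
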