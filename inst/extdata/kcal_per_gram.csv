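# Energy density of beverages as consumed (kcal per gram), from standard nutrient
# tables: milk reflects the whole/toned/skim market mix; coffee and tea are prepared
# cup values including typical added milk and sugar. 95% CIs reflect market-mix spread.
beverage,kcal_per_g,lo,hi
milk,0.60,0.45,0.75
ssb,0.42,0.39,0.45
juice,0.45,0.40,0.50
coffee,0.35,0.28,0.42
tea,0.30,0.24,0.36
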