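# Energy-metabolism parameters of the two-compartment (fat/lean) adult energy-balance
# model. se columns are standard errors used in the outer Monte-Carlo uncertainty loop
# (0 = treated as fixed physical constants).
parameter,value,se,units
rho_fat,9441,0,kcal per kg fat mass
rho_lean,1807,0,kcal per kg lean mass
gamma_fat,3.2,0.16,kcal/kg/day RMR per kg fat mass
gamma_lean,22.0,1.1,kcal/kg/day RMR per kg lean mass
beta_tef,0.10,0,thermic effect of food per kcal intake change
beta_at,0.14,0.035,adaptive thermogenesis per kcal intake change
tau_at,14,0,days adaptive thermogenesis time constant
forbes_c,10.4,0.52,kg Forbes lean-fat partitioning constant
delta_activity,7.1,0.36,kcal/kg/day physical-activity coefficient
rho_glycogen,4200,0,kcal per kg glycogen
glycogen_0,0.5,0,kg initial glycogen store
k_glycogen,0.25,0,kg/day glycogen turnover rate constant
hydration_glycogen,2.7,0,kg water per kg glycogen
pal_default,1.6,0,physical activity level multiplier of RMR
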