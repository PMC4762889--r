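# Yasso07 decomposition parameters: published maximum-a-posteriori point
# estimate (Tuomi et al. 2011, Ecological Modelling 222:709-718).
# Units: alpha_* in 1/yr, beta1 in 1/degC, beta2 in 1/degC^2, gamma in 1/m,
# flow_X_Y = fraction of decomposed mass of pool X routed to pool Y
# (dimensionless), humus_fraction = fraction of decomposed labile mass routed
# to humus, size_phi1/size_phi2 per cm, size_r dimensionless.
alpha_A = 0.73
alpha_W = 5.8
alpha_E = 0.29
alpha_N = 0.031
alpha_H = 0.0017
flow_W_A = 0.48
flow_E_A = 0.01
flow_N_A = 0.83
flow_A_W = 0.99
flow_E_W = 0
flow_N_W = 0.01
flow_A_E = 0
flow_W_E = 0
flow_N_E = 0.03
flow_A_N = 0
flow_W_N = 0.01
flow_E_N = 0.92
humus_fraction = 0.0045
beta1 = 0.096
beta2 = -0.0014
gamma = -1.21
size_phi1 = -1.71
size_phi2 = 0.86
size_r = -0.306
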