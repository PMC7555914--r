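# Normalized two-hour postprandial glucose (OGTT) case study.
# Units: SD of the log-transformed measurand in the non-diseased population.
mu_d: 2.99
sigma_d: 0.75
mu_nd: 0.0
sigma_nd: 1.0
v: 0.067
d: 2.26
u_a: 0.023
u_b: 0.23
l0: 1
l_tn: 0
l_fn: 100
l_tp: 0
l_fp: 76
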