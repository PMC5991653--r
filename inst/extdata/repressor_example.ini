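# Diminishing-repressor example: N = 15 molecules decaying at mu t* = 2.75,
# half-maximal number K = 2.6, Hill coefficient 1; target threshold 15 at
# target time 1. alpha = auto means "calibrate so the mean crossing time
# equals t_star". All rates are per unit of t_star.

[regulator]
k = 0
mu = 2.75
n0 = 15
n0_poisson = false

[regulation]
sign = repressor
alpha = auto
K = 2.6
H = 1

[system]
x_star = 15
t_star = 1

[run]
seed = 1
n_runs = 10000
n_cells = 200
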