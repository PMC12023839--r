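# Large design: 14 sequences (one cluster each), 15 periods, m = 50;
# expensive restart under intervention (as costly as a new cluster).
design: standard_sw
n_sequences: 14
clusters_per_sequence: 1,1,1,1,1,1,1,1,1,1,1,1,1,1
cluster_period_size: 50
structure: discrete_time_decay
icc: 0.15
cac: 0.8
effect_size: 0.26
alpha: 0.05
min_power: 0.8
c: 2500
p: 80
pp: 80
g: 2500
gp: 0
k: 0
kp: 0
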