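# Simulate a heterogeneous 1000-neuron network for two seconds and export
# the raster and mean traces. Units: pA, nS, ms, mV.
command: simulate-network
N: 1000
T_sim: 2000
dt: 0.025
seed: 1
params:
  I_app: 4500
  g_syn: 200
heterogeneity:
  I_app:
    mean: 4500
    sd: 1000
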