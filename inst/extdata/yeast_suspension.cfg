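# UF DEXSY run configuration: hyperpolarized water in a yeast suspension
# on a 0.3 T / 7.28 T m-1 single-sided instrument. All keys carry explicit
# unit suffixes and are converted to SI on read.

instrument.B0_T = 0.3
instrument.G_Tm = 7.28

encoding.bandwidth_kHz = 93       # chirp bandwidth -> 300 um encoding region
encoding.delta_max_us = 160       # effective gradient pulse at the bottom layer
encoding.Delta_ms = 5             # stimulated-echo storage interval
encoding.edge_depth = 1.0         # depth of the chirp-edge Gaussian drops
encoding.edge_width_frac = 0.05   # edge Gaussian width, fraction of the region

cpmg.tE_us = 600
cpmg.n_echoes = 64
cpmg.points_per_echo = 128
cpmg.dwell_us = 4

sample.intra.D_m2s = 1.4e-9       # intracellular water at ~40 C
sample.extra.D_m2s = 3.6e-9       # extracellular water at ~40 C
sample.intra.p = 0.24
sample.k_per_s = 14

scenario.tauM_ms = 10 30 100
scenario.snr = 280
scenario.seed = 1

pipeline.n_z = 128
pipeline.n_substeps = 32
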