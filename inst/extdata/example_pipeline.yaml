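# Example pipeline configuration: simulate the CaV+BK reference response to
# a 25 nM SAP pulse, quantify the spike train, and emulate a fluorescence
# recording of it.  Run with:  run_pipeline(<this file>, out_dir)
stages: [derive, simulate, analyze, synth]
module: cav_bk
S0: 25.0
t_start: -2.0
end_time: 25.0
dt: 0.005
noise_sd: 20.0
seed: 1
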