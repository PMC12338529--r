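seed: 1
method: gamma
n_sources: 2
slot_ms: 10.0
on_ms: 5.2
exposure_ms: 4.0
gain: 0.5
black_level: 25.0
bit_depth: 10
read_noise_e: 2.1
n_detectors: 2
rows: 28
cols: 28
beta: 0.16
tau_c: 1.0e-3
mean_flux: 50.0
active_source: 1
flow_amplitude: 0.5
absorption_amplitude: 0.98
initial_rest: 20.0
n_blocks: 4
stim_duration: 5.0
block_period: 20.0
window: 7
n_dark_frames: 200
ksp: none
flux_threshold: 4.0
motion_z: 5.0
lowpass_cutoff: 1.0
lowpass_order: 5
baseline_interval: [0.0, 18.0]
epoch_window: [-2.0, 10.0]
epoch_baseline: [-2.0, 0.0]
stats_window: [1.0, 4.5]
alpha: 0.05
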