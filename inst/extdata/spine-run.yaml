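# Example run configuration: mock epidural insertion on the spine phantom.
# Load with run_config(file = ...) or pass to the psoctrack CLI --config.
seed: 1
preset: spine
decimation: 5        # sweep-rate decimation of the 50 kHz default
k_samples: 128
tip_pixel: 8
motion:
  style: triangle
  total_time_s: 13
  max_depth_um: 4000
noise:
  detector_noise_rel: 0.05
  jitter_prob: 0.005
  jitter_magnitude_rad: 3.0
  drift_rad_per_s: 0.1
bins: 5
frame_stride: 200
out_dir: spine_run
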