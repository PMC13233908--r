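# Reference pipeline configuration: every detector at its default
# parameters on benchmark-condition recordings. Values shown explicitly so
# that "what ran" is never ambiguous; any field may be overridden.
seed: 1
detectors: [mad, btd, ttd]
recordings:
  - duration: 180          # s, gap-free
    sampling_rate: 20000   # Hz
    rate: 2                # events/s, homogeneous Poisson
    mode: sIPSC            # upward events (holding near +10 mV)
    amplitude_median: 25   # pA, log-normal
    amplitude_sigma_ln: 0.5
    amplitude_floor: 5     # pA
    noise:
      white_sd: 3          # pA
match:
  tolerance: 3             # ms, peak-time matching window
  beta: 0.3                # precision-weighted F-beta
mad:
  band: [0.05, 50]         # Hz, 3rd-order Butterworth band-pass
  noise_highpass: 100      # Hz
  k_sipsc: 3.6             # threshold = median + k * MAD(noise band)
  k_sepsc: 2.5
  baseline_window: [15, 6] # ms before peak
  mad_variant: mean
btd:
  preview_window: [0, 10]  # s
  threshold_multiplier: 3  # x SD of the preview stretch
  smoothing_sigma: 0.25    # ms
  min_amplitude: 5         # pA
ttd:
  n_templates: 3
  detection_multiplier: 5  # x SD beyond the noise band
  correlation_cutoff: 0.6
  min_rise_time: 0.03      # ms (printed value; below one sample at 20 kHz)
  min_amplitude: 5         # pA
  template_length: 60      # ms
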