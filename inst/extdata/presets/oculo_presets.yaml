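# Oculomotor presets. Gains are absolute aVOR gains: the baseline value
# (0.55, a typical mouse dark aVOR gain at 0.2-1 Hz, 30 deg/s) times the
# group's published normalised gain fraction at 0.2 Hz (ttk4h 32.9%,
# ttk24h 66%, uvn24h 14%). MOR bias: baseline 6 deg/s steady slow-phase
# velocity during 50 deg/s OVAR; lesioned groups scale it toward zero
# (ttk4h: the response is abolished). Beat rates are the published
# spontaneous-nystagmus intensities (beats/min).
- label: baseline
  gain: 0.55
  phase_deg: 0.0
  bias_dps: 6.0
  mor_modulation_dps: 3.0
  beat_rate_bpm: 0.0
  slow_phase_vel_dps: 0.0
  quick_phase_amp_deg: 12.0
  noise_sd_deg: 0.1
  drift_side: -1
- label: sham
  gain: 0.55
  phase_deg: 0.0
  bias_dps: 6.0
  mor_modulation_dps: 3.0
  beat_rate_bpm: 0.0
  slow_phase_vel_dps: 0.0
  quick_phase_amp_deg: 12.0
  noise_sd_deg: 0.1
  drift_side: -1
- label: ttk4h
  gain: 0.18095
  phase_deg: 0.0
  bias_dps: 0.0
  mor_modulation_dps: 0.5
  beat_rate_bpm: 18.6
  slow_phase_vel_dps: 4.0
  quick_phase_amp_deg: 12.0
  noise_sd_deg: 0.1
  drift_side: -1
- label: ttk24h
  gain: 0.363
  phase_deg: 0.0
  bias_dps: 1.5
  mor_modulation_dps: 1.0
  beat_rate_bpm: 10.0
  slow_phase_vel_dps: 2.0
  quick_phase_amp_deg: 12.0
  noise_sd_deg: 0.1
  drift_side: -1
- label: uvn24h
  gain: 0.077
  phase_deg: 0.0
  bias_dps: 0.5
  mor_modulation_dps: 0.5
  beat_rate_bpm: 32.2
  slow_phase_vel_dps: 5.0
  quick_phase_amp_deg: 12.0
  noise_sd_deg: 0.1
  drift_side: -1
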