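# Example synthetic-scene configuration: a 10-minute record straddling the
# opening-hours boundary, six calls, default diurnal noise model.
duration: 600
seed: 9
clock_start_hour: 6.9
n_rumbles: 6
noise:
  night_rms_seismic: 0.1
  day_factor_seismic: 7
  machine_line_freqs: [12, 25, 30]
  machine_line_rms: 0.15
  night_rms_infrasound: 0.01
  day_factor_infrasound: 1.5
  burst_rate_day: 20
  opening_hours: [7, 17]
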