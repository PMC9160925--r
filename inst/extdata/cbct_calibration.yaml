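# Calibrated resting drive of the cerebellar input stage. The Pons mossy
# fibers are parrot relays, each driven by an independent Poisson process
# from a single generator; the drive rate below was obtained with
# calibrate_resting_input() against a simulated probe window so that the
# mossy-fiber population fires at its 8 Hz resting target.
pons_drive:
  target_rate_hz: 8.0
  tolerance_hz: 0.5
  drive_rate_hz: 8.0
  delay_ms: 1.0
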