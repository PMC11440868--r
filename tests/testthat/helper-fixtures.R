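# Sampled pure-decay activity curve for a sealed 18F source.
decay_tac <- function(a0 = 1, times_min = seq(0, 240, by = 60),
                      nuclide = f18()) {
  activity_time_course(times_min, activity_at(a0, times_min, nuclide))
}

# The reference vial calibration measurements: administered activity (MBq)
# vs absorbed dose at 1450 min (Gy).
calib <- fdg_fricke_calibration()
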