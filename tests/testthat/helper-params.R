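# shared fixtures: the reference (pwt) three-state parameter set with the
# default lambda-max baselines, and a simple two-state set
pwt_params <- function() {
  three_state_params(transition_thermo(5.7, 6.3),
                     transition_thermo(7.8, 3.9),
                     336, 341, 355)
}

simple_two_state <- function(dg0 = 7.5, m = 5) {
  two_state_params(transition_thermo(dg0, m), 336, 355)
}

# independent Boltzmann-weight oracle for three-state populations
boltzmann_fractions <- function(dg_ni, m_ni, dg_iu, m_iu, conc,
                                temperature = 298.15) {
  rt <- 1.987204e-3 * temperature
  w_n <- 1
  w_i <- exp(-(dg_ni - m_ni * conc) / rt)
  w_u <- exp(-((dg_ni - m_ni * conc) + (dg_iu - m_iu * conc)) / rt)
  z <- w_n + w_i + w_u
  c(f_n = w_n / z, f_i = w_i / z, f_u = w_u / z)
}
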