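# shared fixtures built in code

rates_slow_restart <- function() transition_rates(0.1, 0.001)   # Fig-1-style
rates_symmetric <- function() transition_rates(0.5, 0.5)

square_lattice_turns <- function() {
  # no-reversal lattice turn set: straight on or +/- 90 degrees
  turn_discrete(c(0, pi / 2, -pi / 2), c(1, 1, 1) / 3)
}

# random parameter draw mixing interior values with the 0/1 boundaries
draw_probability <- function() {
  u <- runif(1)
  if (u < 0.15) 0 else if (u < 0.3) 1 else runif(1)
}
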