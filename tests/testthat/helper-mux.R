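# a hand-built 6-4-1 threshold network that solves the 2-select/4-data
# multiplexer exactly: hidden unit j fires iff select value j is addressed
# and the addressed data bit is 1; the output unit ORs the hidden units.
# Feature order: s1, s2 (select, s1 most significant), d0..d3 (data).
perfect_mux_net <- function() {
  W1 <- rbind(
    c(-1.0, -1.0, 1.0, 0.0, 0.0, 0.0),   # addr 0 -> d0
    c(-1.0,  0.3, 0.0, 0.4, 0.0, 0.0),   # addr 1 -> d1
    c( 0.3, -1.0, 0.0, 0.0, 0.4, 0.0),   # addr 2 -> d2
    c( 0.2,  0.2, 0.0, 0.0, 0.0, 0.3)    # addr 3 -> d3
  )
  W2 <- matrix(1, 1, 4)
  angn_network(c(6, 4, 1), activation_spec("threshold", 0.5),
               weights = list(W1, W2))
}

mux_experiment_net <- function() {
  angn_network(c(6, 4, 1), activation_spec("threshold", 0.5),
               weight_limit = 1)
}
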