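# small reusable toy networks (built in code; no fixture files needed)

two_state_toy <- function(k = 1) {
  crn_network(list(crn_species("A"), crn_species("B")),
              list(crn_reaction("A", "B", kf = k, kb = k, label = "ab")))
}

# symmetric 3-species exchange cycle; closed and count-conserving
cycle_toy <- function() {
  crn_network(lapply(c("A", "B", "C"), crn_species),
              list(crn_reaction("A", "B", kf = 1, kb = 1, label = "ab"),
                   crn_reaction("B", "C", kf = 1, kb = 1, label = "bc"),
                   crn_reaction("C", "A", kf = 1, kb = 1, label = "ca")))
}

# all species clamped: propensities never change, handy for frequency checks
clamped_toy <- function() {
  crn_network(list(crn_species("A", chemostat = 5),
                   crn_species("B", chemostat = 3),
                   crn_species("C", chemostat = 2)),
              list(crn_reaction("A", "B", kf = 1, kb = 1, label = "ab"),
                   crn_reaction("B", "C", kf = 2, kb = 2, label = "bc"),
                   crn_reaction("A", "C", kf = 0.5, kb = 0.5, label = "ac")))
}

expected_gibbs <- function(counts) sum(lgamma(counts + 1))
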