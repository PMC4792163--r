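# Small graphs and states built in code for engine/oracle tests.

# path graph 1-2-3-...-n
path_topology <- function(n) {
  edges <- cbind(seq_len(n - 1L), seq.int(2L, n))
  qpdnet:::new_topology(n, edges)
}

# star with center 1
star_topology <- function(n) {
  qpdnet:::new_topology(n, cbind(1L, seq.int(2L, n)))
}

# a tiny config whose validation accepts small n
tiny_config <- function(n, b = 1.5, gamma = 0, alpha = 0, seed = 1, ...) {
  simulation_config(b = b, gamma = gamma, alpha = alpha, n = n, m = 1,
                    mcs_total = 10, window = 5, realizations = 1,
                    seed = seed, ...)
}

# sim_state with fixed topologies/strategies on both layers (identity match)
manual_state <- function(topo1, topo2, s1, s2, config,
                         matching = seq_len(topo1$n_nodes)) {
  coupled <- structure(list(layer1 = topo1, layer2 = topo2,
                            matching = as.integer(matching)),
                       class = "coupled_network")
  structure(list(coupled = coupled, strategies1 = as.integer(s1),
                 strategies2 = as.integer(s2), mcs_index = 0L,
                 config = config),
            class = "sim_state")
}

strategy_code <- function(labels) {
  match(labels, c("C", "D", "Q")) - 1L
}
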