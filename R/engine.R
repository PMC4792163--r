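#' Full parameter set for a coupled-network simulation
#'
#' Collects every knob of the co-evolutionary Monte Carlo model. Defaults are
#' the published study conditions: two BA layers of N = 5000 nodes with
#' attachment m = 2, Fermi noise K = 0.1, 5e4 Monte Carlo steps (MCS) with the
#' stationary average taken over the trailing 1000, and ensembles of 100
#' realizations. Scaled-down profiles for interactive work are available via
#' \code{\link{scale_profile}}.
#'
#' @param b Temptation of defection, in \[1, 2\].
#' @param gamma Entanglement degree of the QPD layer, radians in \[0, pi/2\].
#' @param alpha Inter-layer coupling factor in \[0, 1\]; alpha = 0 makes the
#'   two layers completely independent.
#' @param n Nodes per layer.
#' @param m BA attachment parameter (mean degree about 2 m).
#' @param k_noise Fermi selection noise K > 0.
#' @param mcs_total Number of Monte Carlo steps; each MCS performs n
#'   elementary imitation events per layer.
#' @param window Trailing window (in MCS) for stationary averages.
#' @param realizations Ensemble size for \code{\link{simulate_ensemble}}.
#' @param seed Master seed. Seven named sub-streams (topology of each layer,
#'   matching, two initializations, two per-layer dynamics streams) are
#'   derived from it, so that with alpha = 0 the layer-1 trajectory is
#'   bit-identical across runs that differ only in gamma.
#' @param utility_convention How a player's utility combines its own
#'   accumulated payoff P_own with its inter-layer partner's P_partner:
#'   \code{"additive"} gives P_own + alpha P_partner,
#'   \code{"convex"} gives (1 - alpha) P_own + alpha P_partner. Both reduce
#'   to P_own at alpha = 0. The additive form is the default: it is the one
#'   that reproduces the published stationary fractions, while the convex
#'   form collapses to neutral drift at alpha = 1 (see the methods
#'   vignette).
#' @param topology_mode \code{"copy"} (layer 2 is a structural copy of layer
#'   1's BA realization, the reading of "two identical scale-free networks")
#'   or \code{"independent"} (a fresh BA draw with the same n, m).
#' @param payoff_mode \code{"fresh"} (utilities recomputed from the current
#'   strategy configuration at every elementary event; default) or
#'   \code{"frozen"} (payoffs recomputed once per MCS, for sensitivity
#'   analysis).
#' @param update_order \code{"alternate"} (strict alternation layer 1, layer
#'   2, ... within an MCS; default) or \code{"shuffled"} (random interleaving
#'   of the 2 n events, for robustness checks).
#' @return An object of class \code{"simulation_config"}.
#' @examples
#' simulation_config(b = 1.5, gamma = pi / 2, alpha = 0.8, seed = 1,
#'                   n = 200, mcs_total = 100, window = 50, realizations = 2)
#' @export
simulation_config <- function(b, gamma = 0, alpha = 0, n = 5000, m = 2,
                              k_noise = 0.1, mcs_total = 50000,
                              window = 1000, realizations = 100, seed = 1,
                              utility_convention = c("additive", "convex"),
                              topology_mode = c("copy", "independent"),
                              payoff_mode = c("fresh", "frozen"),
                              update_order = c("alternate", "shuffled")) {
  spec <- game_spec(b, gamma)  # validates b and gamma
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("'alpha' must be in [0, 1]", call. = FALSE)
  if (k_noise <= 0) stop("'k_noise' must be positive", call. = FALSE)
  n <- as.integer(n); m <- as.integer(m)
  if (n <= m || m < 1L) stop("require n > m >= 1", call. = FALSE)
  mcs_total <- as.integer(mcs_total)
  window <- as.integer(window)
  if (mcs_total < 0L) stop("'mcs_total' must be >= 0", call. = FALSE)
  if (window < 1L || window > max(mcs_total, 1L))
    stop("'window' must be in [1, mcs_total]", call. = FALSE)
  if (realizations < 1L) stop("'realizations' must be >= 1", call. = FALSE)
  structure(list(
    n = n, m = m, b = spec$b, gamma = spec$gamma, alpha = alpha,
    k_noise = k_noise, mcs_total = mcs_total, window = window,
    realizations = as.integer(realizations), seed = as.integer(seed),
    utility_convention = match.arg(utility_convention),
    topology_mode = match.arg(topology_mode),
    payoff_mode = match.arg(payoff_mode),
    update_order = match.arg(update_order)
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0(
    "simulation_config: N = %d (m = %d), b = %g, gamma = %.4g, alpha = %g\n",
    "  K = %g, %d MCS (window %d), %d realization(s), seed %d\n",
    "  utility = %s, topology = %s, payoffs = %s, order = %s\n"),
    x$n, x$m, x$b, x$gamma, x$alpha, x$k_noise, x$mcs_total, x$window,
    x$realizations, x$seed, x$utility_convention, x$topology_mode,
    x$payoff_mode, x$update_order))
  invisible(x)
}

#' Apply a named scale profile to a configuration
#'
#' \code{"paper"} is the published scale (N = 5000, 5e4 MCS, window 1000, 100
#' realizations; hours of CPU per sweep). \code{"desk"} is a scaled-down
#' profile for interactive work and testing (N = 1000, 1e4 MCS, window 1000,
#' 10 realizations; minutes per parameter point).
#'
#' @param config A \code{\link{simulation_config}}.
#' @param profile \code{"paper"} or \code{"desk"}.
#' @return The modified configuration.
#' @export
scale_profile <- function(config, profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  p <- if (profile == "paper")
    list(n = 5000L, mcs_total = 50000L, window = 1000L, realizations = 100L)
  else
    list(n = 1000L, mcs_total = 10000L, window = 1000L, realizations = 10L)
  config[names(p)] <- p
  config
}

# Named independent sub-streams derived from the master seed. Separate
# per-layer dynamics streams make the alpha = 0 independence property exact.
derive_stream_seeds <- function(seed) {
  s <- withr_seed(seed, sample.int(2147483646L, 7L))
  names(s) <- c("topology1", "topology2", "matching", "init1", "init2",
                "dyn1", "dyn2")
  s
}

#' Build the coupled network and initial strategies for a configuration
#'
#' Layer 1 starts uniformly over \{C, D\}; layer 2 uniformly over
#' \{C, D, Q\}. Deterministic given \code{config$seed}.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param coupled Optionally, a pre-built \code{coupled_network} to reuse
#'   (e.g. a custom topology from \code{\link{read_edge_list}}).
#' @return A \code{sim_state}: list with \code{coupled}, integer strategy
#'   vectors \code{strategies1} (codes C = 0, D = 1) and \code{strategies2}
#'   (C = 0, D = 1, Q = 2), \code{mcs_index = 0} and the config.
#' @export
init_state <- function(config, coupled = NULL) {
  seeds <- derive_stream_seeds(config$seed)
  if (is.null(coupled)) {
    l1 <- generate_ba(config$n, config$m, seeds[["topology1"]])
    l2 <- if (config$topology_mode == "copy") l1
          else generate_ba(config$n, config$m, seeds[["topology2"]])
    coupled <- couple_layers(l1, l2, seeds[["matching"]])
  }
  n <- coupled$layer1$n_nodes
  s1 <- withr_seed(seeds[["init1"]], sample.int(2L, n, replace = TRUE) - 1L)
  s2 <- withr_seed(seeds[["init2"]], sample.int(3L, n, replace = TRUE) - 1L)
  structure(list(coupled = coupled, strategies1 = s1, strategies2 = s2,
                 mcs_index = 0L, config = config),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  n <- x$coupled$layer1$n_nodes
  cat(sprintf("sim_state at MCS %d (%d nodes/layer)\n", x$mcs_index, n))
  cat(sprintf("  layer 1 (PD):  C %.3f  D %.3f\n",
              mean(x$strategies1 == 0L), mean(x$strategies1 == 1L)))
  cat(sprintf("  layer 2 (QPD): C %.3f  D %.3f  Q %.3f\n",
              mean(x$strategies2 == 0L), mean(x$strategies2 == 1L),
              mean(x$strategies2 == 2L)))
  invisible(x)
}

layer_matrix <- function(config, layer) {
  spec <- game_spec(config$b, config$gamma)
  if (layer == 1L) pd_matrix(spec) else qpd_matrix(spec)
}

#' Accumulated payoff of one node
#'
#' Sum over the node's same-layer neighbours of the row-player payoff of its
#' strategy against theirs — PD payoffs on layer 1, QPD payoffs on layer 2.
#' There is no self-play and no cross-layer game play; an isolated node
#' (possible only in custom graphs) earns 0.
#'
#' @param state A \code{sim_state}.
#' @param layer 1 (PD) or 2 (QPD).
#' @param node Node id (1-based).
#' @return The accumulated payoff (dimensionless).
#' @export
accumulated_payoff <- function(state, layer, node) {
  M <- layer_matrix(state$config, layer)
  topo <- if (layer == 1L) state$coupled$layer1 else state$coupled$layer2
  s <- if (layer == 1L) state$strategies1 else state$strategies2
  nb <- topo$adj[[node]]
  if (!length(nb)) return(0)
  sum(unclass(M)[cbind(s[node] + 1L, s[nb] + 1L)])
}

#' Coupled utility of a payoff pair
#'
#' Combines a player's own accumulated payoff with its inter-layer partner's
#' payoff. Additive convention (default): p_own + alpha p_partner. Convex
#' convention: (1 - alpha) p_own + alpha p_partner. At alpha = 0 both reduce
#' to the own payoff and the layers are completely independent.
#'
#' @param p_own,p_partner Accumulated payoffs (vectorized).
#' @param alpha Coupling factor in \[0, 1\].
#' @param convention \code{"convex"} (default) or \code{"additive"}.
#' @return Utility value(s).
#' @examples
#' utility(2, 4, alpha = 1)                          # 6
#' utility(2, 4, alpha = 0.5, convention = "convex")  # 3
#' @export
utility <- function(p_own, p_partner, alpha,
                    convention = c("additive", "convex")) {
  if (any(alpha < 0) || any(alpha > 1))
    stop("'alpha' must be in [0, 1]", call. = FALSE)
  if (match.arg(convention) == "additive") p_own + alpha * p_partner
  else (1 - alpha) * p_own + alpha * p_partner
}

node_utility <- function(state, layer, node) {
  p_own <- accumulated_payoff(state, layer, node)
  partner <- if (layer == 1L) state$coupled$matching[node]
             else matching_inverse(state$coupled)[node]
  p_part <- accumulated_payoff(state, if (layer == 1L) 2L else 1L, partner)
  utility(p_own, p_part, state$config$alpha, state$config$utility_convention)
}

#' Fermi strategy-adoption probability
#'
#' Probability that a player with utility \code{u_self} adopts the strategy
#' of a neighbour with utility \code{u_neighbor}:
#' \deqn{W = 1 / (1 + \exp((U_x - U_y)/K))}
#' Strictly inside (0, 1) for finite utilities, increasing in the utility
#' advantage of the neighbour, and overflow-safe (saturates to 0/1, never
#' NaN).
#'
#' @param u_self,u_neighbor Utilities (vectorized).
#' @param k_noise Selection noise K > 0.
#' @return Adoption probability.
#' @examples
#' fermi_adopt_prob(1, 1, 0.1)        # 0.5
#' fermi_adopt_prob(0, 0.1, 0.1)      # 1 / (1 + exp(-1))
#' @export
fermi_adopt_prob <- function(u_self, u_neighbor, k_noise = 0.1) {
  if (any(k_noise <= 0)) stop("'k_noise' must be positive", call. = FALSE)
  1 / (1 + exp((u_self - u_neighbor) / k_noise))
}

#' One asynchronous imitation event (reference implementation)
#'
#' Uniformly selects a focal player on the given layer and one of its
#' same-layer neighbours, computes both players' coupled utilities fresh from
#' the current strategy configuration, and lets the focal player adopt the
#' neighbour's strategy with the Fermi probability. At most one node changes.
#' A focal node without neighbours skips its update (counted in the
#' \code{"skips"} attribute).
#'
#' This plain-R implementation defines the elementary event semantics and is
#' the unit the exact enumeration oracle
#' (\code{\link{enumerate_step_distribution}}) checks; \code{\link{simulate_coupled}}
#' runs the same event in compiled code. Randomness comes from R's global
#' RNG.
#'
#' @param state A \code{sim_state}.
#' @param layer 1 or 2.
#' @return The updated \code{sim_state}.
#' @export
elementary_step <- function(state, layer) {
  topo <- if (layer == 1L) state$coupled$layer1 else state$coupled$layer2
  n <- topo$n_nodes
  x <- sample.int(n, 1L)
  nb <- topo$adj[[x]]
  if (!length(nb)) {
    attr(state, "skips") <- c(attr(state, "skips"), x)
    return(state)
  }
  y <- nb[sample.int(length(nb), 1L)]
  p <- fermi_adopt_prob(node_utility(state, layer, x),
                        node_utility(state, layer, y),
                        state$config$k_noise)
  u <- stats::runif(1)  # always drawn: fixed consumption per event
  field <- if (layer == 1L) "strategies1" else "strategies2"
  if (state[[field]][y] != state[[field]][x] && u < p)
    state[[field]][x] <- state[[field]][y]
  state
}

#' One Monte Carlo step (reference implementation)
#'
#' Executes n interleaved pairs of elementary events — one on layer 1 then
#' one on layer 2, n times — so each player on both layers is updated once on
#' average, then increments the MCS index.
#'
#' @param state A \code{sim_state}.
#' @return The updated \code{sim_state}.
#' @export
monte_carlo_step <- function(state) {
  n <- state$coupled$layer1$n_nodes
  for (i in seq_len(n)) {
    state <- elementary_step(state, 1L)
    state <- elementary_step(state, 2L)
  }
  state$mcs_index <- state$mcs_index + 1L
  state
}

#' Run one coupled-network co-evolution
#'
#' Builds the two BA layers and the random matching from seed-derived
#' streams, initializes layer 1 uniformly over \{C, D\} and layer 2 over
#' \{C, D, Q\}, and runs \code{mcs_total} Monte Carlo steps of asynchronous
#' Fermi imitation (compiled fast path). The trajectory records the strategy
#' fractions of both layers after every MCS, including the initial state.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param coupled Optional pre-built \code{coupled_network} (custom
#'   topologies); by default the topology is generated from the seed.
#' @return A data frame of class \code{"coupled_trajectory"} with columns
#'   \code{mcs}, \code{rho_C_1}, \code{rho_D_1}, \code{rho_C_2},
#'   \code{rho_D_2}, \code{rho_Q_2} and \code{mcs_total + 1} rows.
#'   Attributes: \code{config}, \code{final_state} (a \code{sim_state}),
#'   \code{skips}.
#' @examples
#' cfg <- simulation_config(b = 1.5, gamma = pi / 2, alpha = 0.8, seed = 1,
#'                          n = 200, mcs_total = 200, window = 50,
#'                          realizations = 1)
#' traj <- simulate_coupled(cfg)
#' tail(traj, 3)
#' @export
simulate_coupled <- function(config, coupled = NULL) {
  state <- init_state(config, coupled)
  seeds <- derive_stream_seeds(config$seed)
  adj1 <- lapply(state$coupled$layer1$adj, function(v) v - 1L)
  adj2 <- lapply(state$coupled$layer2$adj, function(v) v - 1L)
  res <- run_coupled_sim(
    adj1, adj2, state$coupled$matching,
    unclass(layer_matrix(config, 1L)), unclass(layer_matrix(config, 2L)),
    config$alpha, config$utility_convention == "additive", config$k_noise,
    config$mcs_total, state$strategies1, state$strategies2,
    seeds[["dyn1"]], seeds[["dyn2"]],
    config$payoff_mode == "frozen", config$update_order == "shuffled")
  traj <- as.data.frame(res$traj)
  names(traj) <- c("rho_C_1", "rho_D_1", "rho_C_2", "rho_D_2", "rho_Q_2")
  traj <- cbind(mcs = 0:config$mcs_total, traj)
  final <- state
  final$strategies1 <- res$strategies1
  final$strategies2 <- res$strategies2
  final$mcs_index <- config$mcs_total
  structure(traj, class = c("coupled_trajectory", "data.frame"),
            config = config, final_state = final, skips = res$skips)
}

#' Write a trajectory to CSV
#' @param traj A \code{coupled_trajectory}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Run an ensemble of independent realizations
#'
#' Repeats \code{\link{simulate_coupled}} \code{config$realizations} times
#' with per-realization seeds derived from the master seed; each realization
#' redraws the topology, matching and initial strategies. Stationary
#' fractions are the trailing-window averages of each run.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return An \code{ensemble_result}; see \code{\link{ensemble_average}}.
#' @export
simulate_ensemble <- function(config) {
  rseeds <- withr_seed(config$seed,
                       sample.int(2147483646L, config$realizations))
  stats <- lapply(rseeds, function(s) {
    cfg <- config
    cfg$seed <- s
    stationary_fractions(simulate_coupled(cfg), config$window)
  })
  ensemble_average(stats)
}
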