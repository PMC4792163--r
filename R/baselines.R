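#' Exact one-step transition distribution on a tiny layer
#'
#' Independent oracle for \code{\link{elementary_step}}: enumerates every
#' (focal, neighbour) choice on the given layer, weighting each by
#' 1/N * 1/deg(focal), multiplied by the closed-form Fermi adoption
#' probability computed from fresh coupled utilities. Returns the exact
#' probability of every possible successor, which differs from the current
#' state in at most one node.
#'
#' @param state A \code{sim_state} whose chosen layer has at most
#'   \code{max_nodes} nodes (combinatorial guard).
#' @param layer 1 or 2.
#' @param max_nodes Refusal threshold (default 8).
#' @return Named numeric vector of probabilities summing to 1. Names are
#'   \code{"none"} (no change) and \code{"<node>:<strategy>"} for the state
#'   where \code{node} switched to \code{strategy}.
#' @export
enumerate_step_distribution <- function(state, layer, max_nodes = 8L) {
  topo <- if (layer == 1L) state$coupled$layer1 else state$coupled$layer2
  n <- topo$n_nodes
  if (n > max_nodes)
    stop("layer too large for exact enumeration (", n, " > ", max_nodes, ")",
         call. = FALSE)
  s <- if (layer == 1L) state$strategies1 else state$strategies2
  labels <- strategy_levels()
  out <- c(none = 0)
  u <- vapply(seq_len(n), function(v) node_utility(state, layer, v),
              numeric(1))
  for (x in seq_len(n)) {
    nb <- topo$adj[[x]]
    if (!length(nb)) {           # isolated focal node: update skipped
      out["none"] <- out["none"] + 1 / n
      next
    }
    for (y in nb) {
      w <- (1 / n) * (1 / length(nb))
      p <- fermi_adopt_prob(u[x], u[y], state$config$k_noise)
      if (s[y] != s[x]) {
        key <- paste0(x, ":", labels[s[y] + 1L])
        out[key] <- if (key %in% names(out)) out[key] + w * p else w * p
        out["none"] <- out["none"] + w * (1 - p)
      } else {
        out["none"] <- out["none"] + w
      }
    }
  }
  out
}

#' Empirical one-step outcome frequencies (compiled sampler)
#'
#' Draws \code{n_draws} independent elementary imitation events from the same
#' fixed state (never chaining them) using the compiled engine's event code,
#' and tallies the outcomes in the encoding of
#' \code{\link{enumerate_step_distribution}}. Used to check that the
#' compiled fast path and the exact enumeration agree.
#'
#' @param state A \code{sim_state}.
#' @param layer 1 or 2.
#' @param n_draws Number of independent draws.
#' @param seed Integer seed for the sampler stream.
#' @return Named numeric vector of outcome frequencies summing to 1.
#' @export
sample_step_frequencies <- function(state, layer, n_draws, seed) {
  cfg <- state$config
  adj1 <- lapply(state$coupled$layer1$adj, function(v) v - 1L)
  adj2 <- lapply(state$coupled$layer2$adj, function(v) v - 1L)
  counts <- sample_step_outcomes(
    adj1, adj2, state$coupled$matching,
    unclass(layer_matrix(cfg, 1L)), unclass(layer_matrix(cfg, 2L)),
    cfg$alpha, cfg$utility_convention == "additive", cfg$k_noise,
    state$strategies1, state$strategies2, as.integer(layer),
    as.numeric(n_draws), as.numeric(seed))
  n <- if (layer == 1L) state$coupled$layer1$n_nodes
       else state$coupled$layer2$n_nodes
  labels <- strategy_levels()
  keys <- c(paste0(rep(seq_len(n), each = 3L), ":",
                   rep(labels, times = n)), "none")
  freq <- stats::setNames(as.numeric(counts) / n_draws, keys)
  freq[freq > 0 | names(freq) == "none"]
}

#' Replicator dynamics for a (Q)PD payoff matrix
#'
#' Integrates the standard replicator equation
#' \eqn{\dot x_i = x_i (f_i - \bar f)} with \eqn{f = A x} for a well-mixed
#' population, the reference point against which the structured-population
#' simulator is contrasted: under replicator dynamics with strong
#' entanglement, C and D go extinct and Q takes over, whereas on a scale-free
#' network C and Q coexist.
#'
#' A fixed-step explicit RK4 scheme is used, validated by step-halving: the
#' step is halved (up to \code{max_halvings} times) until the end point moves
#' by less than \code{tol} and the orbit stays on the simplex.
#'
#' @param matrix A square \code{payoff_matrix} (2 or 3 strategies).
#' @param x0 Initial frequencies: non-negative, summing to 1 (tolerance
#'   1e-12), length matching the matrix.
#' @param horizon Total integration time.
#' @param step Initial time step.
#' @param tol End-point tolerance for step-halving validation.
#' @param max_halvings Cap on the number of halvings.
#' @return Matrix with one row per recorded time (including t = 0), columns
#'   named by strategy, attribute \code{"times"}; rows stay on the simplex.
#' @examples
#' A <- qpd_matrix(game_spec(1.5, pi / 2))
#' tail(replicator_trajectory(A, c(0.4, 0.3, 0.3), horizon = 100), 1)
#' @export
replicator_trajectory <- function(matrix, x0, horizon, step = 0.05,
                                  tol = 1e-8, max_halvings = 10L) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("'matrix' must be square", call. = FALSE)
  A <- unclass(matrix)
  k <- nrow(A)
  x0 <- as.numeric(x0)
  if (length(x0) != k || any(x0 < 0) || abs(sum(x0) - 1) > 1e-12)
    stop("'x0' must be a length-", k, " point on the probability simplex",
         call. = FALSE)
  deriv <- function(x) {
    f <- drop(A %*% x)
    x * (f - sum(x * f))
  }
  integrate_fixed <- function(h) {
    n_steps <- ceiling(horizon / h)
    out <- matrix(NA_real_, n_steps + 1L, k)
    out[1L, ] <- x <- x0
    for (i in seq_len(n_steps)) {
      k1 <- deriv(x)
      k2 <- deriv(x + h / 2 * k1)
      k3 <- deriv(x + h / 2 * k2)
      k4 <- deriv(x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(x < -1e-10) || abs(sum(x) - 1) > 1e-9) return(NULL)
      x <- pmax(x, 0)
      out[i + 1L, ] <- x
    }
    out
  }
  h <- step
  sol <- integrate_fixed(h)
  for (i in seq_len(max_halvings)) {
    finer <- integrate_fixed(h / 2)
    if (!is.null(sol) && !is.null(finer) &&
        max(abs(sol[nrow(sol), ] - finer[nrow(finer), ])) < tol) break
    h <- h / 2
    sol <- finer
    if (i == max_halvings && is.null(sol))
      stop("step-halving failed to stabilize the integration", call. = FALSE)
  }
  colnames(sol) <- rownames(A)
  attr(sol, "times") <- seq(0, by = h, length.out = nrow(sol))
  sol
}
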