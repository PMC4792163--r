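#' Strategy labels and their fixed array ordering
#'
#' The three strategies of the coupled game framework are cooperation
#' (\code{"C"}), defection (\code{"D"}) and super cooperation (\code{"Q"},
#' the quantum strategy). The integer coding used throughout the package
#' (and in the compiled engine) is fixed: C = 0, D = 1, Q = 2. The classical
#' PD layer only ever holds C and D; Q is legal on the QPD layer alone.
#'
#' @return Character vector \code{c("C", "D", "Q")} in index order.
#' @export
strategy_levels <- function() c("C", "D", "Q")

#' Game parameters for the PD/QPD pair
#'
#' Bundles the temptation of defection \code{b} and the entanglement degree
#' \code{gamma} with domain validation. The PD payoffs are the standard weak
#' dilemma T = b, R = 1, P = S = 0; the QPD additionally depends on gamma.
#'
#' @param b Temptation of defection, in \[1, 2\]. The dilemma requires b > 1,
#'   but both endpoints are accepted because sweeps evaluate b = 1 and b = 2.
#' @param gamma Entanglement degree in radians, in \[0, pi/2\]. At gamma = 0
#'   the quantum strategy collapses onto C and the QPD degenerates to the PD.
#' @return An object of class \code{"game_spec"}: a list with elements
#'   \code{b} and \code{gamma}.
#' @examples
#' game_spec(b = 1.5, gamma = pi / 4)
#' @export
game_spec <- function(b, gamma = 0) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b < 1 || b > 2)
    stop("'b' must be a single number in [1, 2]", call. = FALSE)
  # rounded radian inputs like 1.571 are clamped to the pi/2 endpoint
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0 || gamma > pi / 2 + 1e-3)
    stop("'gamma' must be a single number in [0, pi/2]", call. = FALSE)
  structure(list(b = b, gamma = min(gamma, pi / 2)), class = "game_spec")
}

as_game_spec <- function(spec) {
  if (inherits(spec, "game_spec")) return(spec)
  stop("expected a 'game_spec' object; see game_spec()", call. = FALSE)
}

#' @export
print.game_spec <- function(x, ...) {
  cat(sprintf("game_spec: b = %g, gamma = %g rad (%.3g * pi/2)\n",
              x$b, x$gamma, x$gamma / (pi / 2)))
  invisible(x)
}

new_payoff_matrix <- function(values, strategies) {
  dimnames(values) <- list(strategies, strategies)
  structure(values, class = c("payoff_matrix", "matrix"))
}

#' Classical prisoner's dilemma payoff matrix
#'
#' Row-player payoffs over strategies (C, D): mutual cooperation pays R = 1,
#' defecting on a cooperator pays T = b, and both the sucker's payoff and the
#' punishment are 0. Defection strictly dominates for b > 1. The entanglement
#' degree in \code{spec} is ignored.
#'
#' @param spec A \code{\link{game_spec}}.
#' @return A 2x2 \code{payoff_matrix} with rows/columns labelled C, D.
#' @examples
#' pd_matrix(game_spec(b = 1.5))
#' @seealso [qpd_matrix()], [pairwise_subgame()]
#' @export
pd_matrix <- function(spec) {
  spec <- as_game_spec(spec)
  m <- matrix(c(1, 0,
                spec$b, 0), nrow = 2, byrow = TRUE)
  new_payoff_matrix(m, c("C", "D"))
}

#' Simplified three-strategy quantum prisoner's dilemma payoff matrix
#'
#' Row-player payoffs over strategies (C, D, Q), where Q is the quantum
#' "super cooperation" strategy and gamma the entanglement degree:
#' \deqn{A = \begin{pmatrix} 1 & 0 & \cos^2\gamma \\
#'                           b & 0 & b\cos^2\gamma \\
#'                \cos^2\gamma & b\sin^2\gamma & 1 \end{pmatrix}}
#' Key structural features: at gamma = 0 the Q row/column coincides with C
#' (the game degenerates to the PD); Q and C meeting each other both earn
#' cos^2(gamma) ("equal status"); against D, Q earns b sin^2(gamma) while D
#' earns b cos^2(gamma), so rising entanglement starves defectors; at
#' gamma = pi/2, Q is the unique strict Nash equilibrium whenever b cos^2
#' gamma < 1.
#'
#' @inheritParams pd_matrix
#' @return A 3x3 \code{payoff_matrix} with rows/columns labelled C, D, Q.
#' @examples
#' qpd_matrix(game_spec(b = 2, gamma = pi / 4))
#' @export
qpd_matrix <- function(spec) {
  spec <- as_game_spec(spec)
  b <- spec$b
  c2 <- cos(spec$gamma)^2
  s2 <- sin(spec$gamma)^2
  m <- matrix(c(1,  0,      c2,
                b,  0,      b * c2,
                c2, b * s2, 1), nrow = 3, byrow = TRUE)
  new_payoff_matrix(m, c("C", "D", "Q"))
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat(sprintf("payoff_matrix (%d strategies: %s), row-player payoffs\n",
              nrow(x), paste(rownames(x), collapse = ", ")))
  print(unclass(x), ...)
  invisible(x)
}

#' Restrict a payoff matrix to a two-strategy subgame
#'
#' Extracts the 2x2 restriction of a (Q)PD payoff matrix to an ordered pair of
#' strategies. Applied to the QPD matrix this reproduces the pairwise
#' decomposition into G_CD (a classical PD), G_CQ (a coordination-flavoured
#' game in which C and Q have equal status) and G_DQ (where growing
#' entanglement transfers the advantage from D to Q).
#'
#' @param matrix A \code{payoff_matrix}.
#' @param s1,s2 Distinct strategy labels present in \code{matrix}.
#' @return A 2x2 \code{payoff_matrix} over \code{c(s1, s2)}.
#' @examples
#' pairwise_subgame(qpd_matrix(game_spec(2, pi / 2)), "D", "Q")
#' @export
pairwise_subgame <- function(matrix, s1, s2) {
  if (!inherits(matrix, "payoff_matrix"))
    stop("'matrix' must be a payoff_matrix", call. = FALSE)
  if (identical(s1, s2)) stop("'s1' and 's2' must differ", call. = FALSE)
  missing <- setdiff(c(s1, s2), rownames(matrix))
  if (length(missing))
    stop("strategy not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  new_payoff_matrix(unclass(matrix)[c(s1, s2), c(s1, s2), drop = FALSE],
                    c(s1, s2))
}

#' Nash/ESS analysis of the quantum strategy
#'
#' Determines whether super cooperation Q is a strict Nash equilibrium (and
#' hence an ESS) of the simplified QPD. Against a Q opponent the three
#' strategies earn cos^2(gamma) (C), b cos^2(gamma) (D) and 1 (Q), so Q is a
#' strict best response to itself iff \eqn{1 > b\cos^2\gamma}. The boundary
#' \eqn{b\cos^2\gamma = 1} is classified as not strict (strictness is what
#' guarantees evolutionary stability). The gamma threshold solving the
#' boundary for a given b is \eqn{\arccos(b^{-1/2})}.
#'
#' @inheritParams pd_matrix
#' @return A list of class \code{"q_equilibrium"} with elements
#'   \code{q_strict_ne} (logical), \code{gamma_threshold} (radians; the gamma
#'   at which b cos^2 gamma = 1) and \code{q_dominates_d_in_subgame}
#'   (logical: in the D-Q subgame Q earns strictly more than D against both).
#' @examples
#' q_equilibrium_analysis(game_spec(b = 1.5, gamma = pi / 2))
#' @export
q_equilibrium_analysis <- function(spec) {
  spec <- as_game_spec(spec)
  b <- spec$b
  c2 <- cos(spec$gamma)^2
  s2 <- sin(spec$gamma)^2
  strict <- 1 > b * c2
  structure(list(
    q_strict_ne = strict,
    gamma_threshold = acos(1 / sqrt(b)),
    q_dominates_d_in_subgame = (b * s2 > 0) && strict
  ), class = "q_equilibrium")
}

#' @export
print.q_equilibrium <- function(x, ...) {
  cat("Q (super cooperation) equilibrium analysis\n")
  cat(sprintf("  strict NE / ESS:          %s\n", x$q_strict_ne))
  cat(sprintf("  gamma threshold (rad):    %.6f\n", x$gamma_threshold))
  cat(sprintf("  Q dominates D in subgame: %s\n", x$q_dominates_d_in_subgame))
  invisible(x)
}

#' Write a payoff matrix as labelled CSV
#'
#' @param matrix A \code{payoff_matrix}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_payoff_csv <- function(matrix, path) {
  if (!inherits(matrix, "payoff_matrix"))
    stop("'matrix' must be a payoff_matrix", call. = FALSE)
  utils::write.csv(as.data.frame(unclass(matrix)), path, row.names = TRUE)
  invisible(path)
}

#' Read a labelled payoff matrix from CSV
#'
#' @param path CSV written by \code{\link{write_payoff_csv}}.
#' @return A \code{payoff_matrix}.
#' @export
read_payoff_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  new_payoff_matrix(as.matrix(d), rownames(d))
}
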