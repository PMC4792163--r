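#' Stationary strategy fractions of a trajectory
#'
#' Arithmetic mean of each per-layer strategy fraction over the final
#' \code{window} MCS records of a trajectory — the fixed-horizon stationary
#' estimate (no burn-in detection is attempted; the horizon is part of the
#' study design).
#'
#' @param traj A \code{coupled_trajectory} (or any data frame with the
#'   fraction columns \code{rho_C_1}, \code{rho_D_1}, \code{rho_C_2},
#'   \code{rho_D_2}, \code{rho_Q_2}).
#' @param window Number of trailing records to average, in
#'   \[1, nrow(traj)\].
#' @return Named numeric vector of the five mean fractions, carrying the
#'   trajectory's parameters as the \code{"params"} attribute when known.
#' @export
stationary_fractions <- function(traj, window) {
  cols <- c("rho_C_1", "rho_D_1", "rho_C_2", "rho_D_2", "rho_Q_2")
  if (!all(cols %in% names(traj)))
    stop("'traj' lacks the strategy-fraction columns", call. = FALSE)
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window > nrow(traj))
    stop("'window' must be in [1, nrow(traj)]", call. = FALSE)
  tail_rows <- seq.int(nrow(traj) - window + 1L, nrow(traj))
  out <- colMeans(as.data.frame(traj)[tail_rows, cols])
  cfg <- attr(traj, "config")
  if (!is.null(cfg))
    attr(out, "params") <- cfg[c("b", "gamma", "alpha", "n", "m", "k_noise")]
  out
}

#' Ensemble mean and standard error of stationary fractions
#'
#' Averages the stationary fractions of independent realizations run at
#' identical parameters. The standard error is the sample standard deviation
#' over realizations divided by sqrt(n); with a single realization it is
#' reported as 0 and flagged.
#'
#' @param results Non-empty list of stationary-fraction vectors (as returned
#'   by \code{\link{stationary_fractions}}) with consistent parameters.
#' @return An object of class \code{"ensemble_result"}: list with
#'   \code{parameters}, \code{mean}, \code{se}, \code{n_realizations} and
#'   \code{se_defined}.
#' @export
ensemble_average <- function(results) {
  if (!length(results)) stop("'results' is empty", call. = FALSE)
  params <- lapply(results, attr, "params")
  known <- params[!vapply(params, is.null, logical(1))]
  if (length(known) > 1L &&
      !all(vapply(known, identical, logical(1), y = known[[1]])))
    stop("realizations were run at different parameters", call. = FALSE)
  m <- do.call(rbind, lapply(results, as.numeric))
  colnames(m) <- names(results[[1]])
  n <- nrow(m)
  se <- if (n > 1L) apply(m, 2L, stats::sd) / sqrt(n)
        else stats::setNames(rep(0, ncol(m)), colnames(m))
  structure(list(parameters = if (length(known)) known[[1]] else NULL,
                 mean = colMeans(m), se = se, n_realizations = n,
                 se_defined = n > 1L),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble_result over %d realization(s)%s\n", x$n_realizations,
              if (!x$se_defined) " (SE undefined, reported as 0)" else ""))
  if (!is.null(x$parameters))
    cat("  ", paste(names(x$parameters), unlist(x$parameters), sep = " = ",
                    collapse = ", "), "\n", sep = "")
  tab <- rbind(mean = x$mean, se = x$se)
  print(round(tab, 4))
  invisible(x)
}

#' Cooperation level of the whole two-layer system
#'
#' Fraction of cooperating players — C on the PD layer plus C and Q on the
#' QPD layer — among all 2 N players of the coupled network:
#' (rho_C_1 + rho_C_2 + rho_Q_2) / 2. Equals
#' 1 - (rho_D_1 + rho_D_2) / 2.
#'
#' @param stationary Named fractions including \code{rho_C_1},
#'   \code{rho_C_2}, \code{rho_Q_2} (e.g. from
#'   \code{\link{stationary_fractions}} or an ensemble mean).
#' @return A single fraction in \[0, 1\].
#' @examples
#' whole_network_cooperation(c(rho_C_1 = 0.4, rho_D_1 = 0.6,
#'                             rho_C_2 = 0.2, rho_D_2 = 0.2, rho_Q_2 = 0.6))
#' @export
whole_network_cooperation <- function(stationary) {
  need <- c("rho_C_1", "rho_C_2", "rho_Q_2")
  if (!all(need %in% names(stationary)))
    stop("'stationary' must name ", paste(need, collapse = ", "),
         call. = FALSE)
  unname((stationary[["rho_C_1"]] + stationary[["rho_C_2"]] +
            stationary[["rho_Q_2"]]) / 2)
}
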