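#' Specify a parameter sweep
#'
#' The Cartesian product of the supplied b, gamma and alpha grids, each point
#' run as an ensemble under a shared base configuration. Per-point seeds are
#' derived deterministically from the base seed and the point's position in
#' the canonical grid ordering, so partial re-runs and re-orderings
#' reproduce identical rows.
#'
#' @param b,gamma,alpha Numeric grids (each within its parameter domain).
#' @param base_config A \code{\link{simulation_config}} providing every
#'   other parameter (n, m, K, MCS, window, realizations, seed, conventions).
#' @param output Optional CSV path; rows are appended as each grid point
#'   completes and a \code{# complete} marker line ends a finished sweep, so
#'   interrupted sweeps resume from the finished rows.
#' @return A \code{sweep_spec}.
#' @export
sweep_spec <- function(b, gamma, alpha, base_config, output = NULL) {
  for (v in b) game_spec(v, 0)
  for (g in gamma) game_spec(1, g)
  if (any(alpha < 0 | alpha > 1)) stop("'alpha' grid outside [0, 1]",
                                       call. = FALSE)
  grid <- expand.grid(b = b, gamma = gamma, alpha = alpha,
                      KEEP.OUT.ATTRS = FALSE)
  message(sprintf("sweep grid: %d point(s) (%d b x %d gamma x %d alpha)",
                  nrow(grid), length(b), length(gamma), length(alpha)))
  structure(list(grid = grid, base_config = base_config, output = output),
            class = "sweep_spec")
}

sweep_row <- function(base, b, gamma, alpha, point_seed) {
  cfg <- base
  cfg$b <- b; cfg$gamma <- gamma; cfg$alpha <- alpha
  cfg$seed <- point_seed
  ens <- simulate_ensemble(cfg)
  stat <- ens$mean
  data.frame(b = b, gamma = gamma, alpha = alpha, n = cfg$n, m = cfg$m,
             k_noise = cfg$k_noise, mcs_total = cfg$mcs_total,
             window = cfg$window, n_real = ens$n_realizations,
             seed = point_seed,
             rho_C_1 = stat[["rho_C_1"]], rho_D_1 = stat[["rho_D_1"]],
             rho_C_2 = stat[["rho_C_2"]], rho_D_2 = stat[["rho_D_2"]],
             rho_Q_2 = stat[["rho_Q_2"]],
             se_rho_C_1 = ens$se[["rho_C_1"]],
             se_rho_C_2 = ens$se[["rho_C_2"]],
             se_rho_Q_2 = ens$se[["rho_Q_2"]],
             rho_coop_all = whole_network_cooperation(stat))
}

#' Run a parameter sweep
#'
#' One ensemble per grid point; a single-point grid is exactly equivalent to
#' calling \code{\link{simulate_ensemble}} directly with the point's seed.
#' Results are returned as a data frame (and optionally streamed to CSV with
#' resume support).
#'
#' @param spec A \code{\link{sweep_spec}}.
#' @return Data frame with one row per grid point: the parameters, ensemble
#'   means and standard errors of the stationary fractions, and the
#'   whole-network cooperation level.
#' @export
run_sweep <- function(spec) {
  grid <- spec$grid
  base <- spec$base_config
  point_seeds <- withr_seed(base$seed, sample.int(2147483646L, nrow(grid)))
  done <- NULL
  if (!is.null(spec$output) && file.exists(spec$output)) {
    done <- utils::read.csv(spec$output, comment.char = "#")
  } else if (!is.null(spec$output)) {
    dir.create(dirname(spec$output), recursive = TRUE, showWarnings = FALSE)
    if (file.access(dirname(spec$output), 2L) != 0L)
      stop("output location is not writable: ", spec$output, call. = FALSE)
  }
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    prior <- NULL
    if (!is.null(done) && nrow(done)) {
      hit <- which(abs(done$b - grid$b[i]) < 1e-12 &
                   abs(done$gamma - grid$gamma[i]) < 1e-12 &
                   abs(done$alpha - grid$alpha[i]) < 1e-12)
      if (length(hit)) prior <- done[hit[1L], ]
    }
    row <- if (!is.null(prior)) prior
           else sweep_row(base, grid$b[i], grid$gamma[i], grid$alpha[i],
                          point_seeds[i])
    rows[[i]] <- row
    if (!is.null(spec$output) && is.null(prior)) {
      utils::write.table(row, spec$output, sep = ",", append = file.exists(spec$output),
                         col.names = !file.exists(spec$output),
                         row.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(spec$output)) cat("# complete\n", file = spec$output,
                                 append = TRUE)
  out
}

#' Preset sweeps for the published figure layouts
#'
#' Returns the parameter grid matching each published figure: b-sweeps at
#' gamma = 0 under several couplings (fig1), gamma-sweeps at alpha = 0.8
#' (fig2), the b-gamma phase maps at alpha in \{0, 0.2, 1\} (fig3), the
#' alpha dependence of PD cooperation (fig4) and QPD strategies (fig5), the
#' four-corner summary (fig6), the alpha-effect at six entanglement levels
#' gamma = \{0, 0.2, ..., 1\} * pi/2 (fig7), and the whole-network
#' cooperation versus alpha (fig8). The scale profile sets n, MCS and
#' realizations (see \code{\link{scale_profile}}).
#'
#' @param figure_id One of \code{"fig1"} ... \code{"fig8"}.
#' @param profile \code{"desk"} (default) or \code{"paper"}.
#' @param seed Master seed for the sweep.
#' @param output Optional CSV path, as in \code{\link{sweep_spec}}.
#' @return A \code{sweep_spec}.
#' @export
figure_preset <- function(figure_id, profile = c("desk", "paper"), seed = 1,
                          output = NULL) {
  profile <- match.arg(profile)
  base <- scale_profile(simulation_config(b = 1.5, seed = seed), profile)
  g2 <- pi / 2
  b_curve <- seq(1, 2, by = 0.05)
  b_map <- seq(1, 2, by = 0.1)
  alpha_named <- c(0, 0.2, 0.8, 1)
  grids <- switch(figure_id,
    fig1 = list(b = b_curve, gamma = 0, alpha = c(0, 0.2, 0.5, 0.8, 1)),
    fig2 = list(b = b_curve, gamma = seq(0, 1, by = 0.2) * g2, alpha = 0.8),
    fig3 = list(b = b_map, gamma = seq(0, 1, by = 0.1) * g2,
                alpha = c(0, 0.2, 1)),
    fig4 = list(b = b_curve, gamma = c(0, 0.5, 1) * g2, alpha = alpha_named),
    fig5 = list(b = b_curve, gamma = c(0, 1) * g2, alpha = alpha_named),
    fig6 = list(b = b_curve, gamma = c(0, 1) * g2, alpha = c(0, 1)),
    fig7 = list(b = b_curve, gamma = seq(0, 1, by = 0.2) * g2,
                alpha = alpha_named),
    fig8 = list(b = c(1, 1.2, 1.4, 1.6, 1.8, 2),
                gamma = seq(0, 1, by = 0.2) * g2,
                alpha = seq(0, 1, by = 0.1)),
    stop("unknown figure id: ", figure_id, call. = FALSE))
  sweep_spec(grids$b, grids$gamma, grids$alpha, base, output = output)
}
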