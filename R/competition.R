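#' Simulate two labelled subpopulations competing in a shared medium
#'
#' Both subpopulations experience the same instantaneous killing at exposure
#' and then grow against the shared carrying cap:
#' `dL_X/dt = r_X L_X (1 - (L_A + L_B + dead_A + dead_B)/K)` once past each
#' lag. Integrated with `deSolve`, piecewise across the lag breakpoints.
#'
#' @param params_A,params_B [growth_params()] of the two subpopulations
#'   (their `a0` fields set each inoculum scale).
#' @param d_A,d_B Kill fractions at exposure.
#' @param inoculum_ratio Length-2 non-negative weights; each subpopulation is
#'   inoculated at `a0 * ratio / sum(ratio)`.
#' @param K Shared carrying cap (OD); defaults to `params_A$K`.
#' @param horizon Simulation horizon (h).
#' @param step Output step (h).
#' @return A data frame with columns `t`, `living_A`, `living_B`, `dead_A`,
#'   `dead_B`.
#' @export
simulate_competition <- function(params_A, params_B, d_A = 0, d_B = 0,
                                 inoculum_ratio = c(1, 1), K = params_A$K,
                                 horizon = 100, step = 0.1) {
  stopifnot(inherits(params_A, "growth_params"),
            inherits(params_B, "growth_params"))
  if (length(inoculum_ratio) != 2L || any(inoculum_ratio < 0) ||
      sum(inoculum_ratio) <= 0)
    stop("'inoculum_ratio' must be two non-negative weights, not both zero")
  for (d in c(d_A, d_B))
    if (!is.numeric(d) || is.na(d) || d < 0 || d > 1)
      stop("kill fractions must lie in [0, 1]")
  w <- inoculum_ratio / sum(inoculum_ratio)
  N0 <- c(params_A$a0 * w[1], params_B$a0 * w[2])
  dead <- c(N0[1] * d_A, N0[2] * d_B)
  L0 <- c(N0[1] * (1 - d_A), N0[2] * (1 - d_B))
  lags <- c(params_A$lag, params_B$lag)
  rates <- c(params_A$r, params_B$r)
  deriv <- function(t, y, parms) {
    tot <- sum(y) + sum(dead)
    grow <- rates * as.numeric(t >= lags) * y * (1 - tot / K)
    list(grow)
  }
  times <- seq(0, horizon, by = step)
  breaks <- sort(unique(c(0, lags[lags > 0 & lags < horizon], horizon)))
  segs <- list()
  y <- L0
  for (i in seq_len(length(breaks) - 1L)) {
    seg_times <- sort(unique(c(breaks[i], times[times >= breaks[i] &
                                                  times <= breaks[i + 1L]],
                               breaks[i + 1L])))
    sol <- deSolve::ode(y = y, times = seg_times, func = deriv, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    y <- as.numeric(sol[nrow(sol), -1])
    keep <- sol[, 1] %in% times
    if (i > 1L) keep[1L] <- FALSE   # breakpoint already emitted
    segs[[i]] <- sol[keep, , drop = FALSE]
  }
  sol <- do.call(rbind, segs)
  sol <- sol[!duplicated(sol[, 1]), , drop = FALSE]
  data.frame(t = sol[, 1], living_A = sol[, 2], living_B = sol[, 3],
             dead_A = dead[1], dead_B = dead[2])
}

#' Predict the steady-state outcome of a two-label competition
#'
#' Forward-simulates both subpopulations in the shared condition and reports
#' the long-time fraction of population A among living cells. For equal
#' growth rates the steady-state fraction has the closed form
#' `f_inf = w_A / (w_A + w_B)` with `w_X = N0_X (1 - d_X) exp(-r lag_X)`:
#' the shared logistic slowing cancels from the ratio, so only the kills and
#' lags shift the outcome. With unequal rates the faster population takes
#' over entirely; the prediction is then flagged `degenerate` and `f_inf`
#' is 0 or 1.
#'
#' @inheritParams simulate_competition
#' @param count_dead Include retained dead cells in the counted fractions?
#'   Default FALSE: dead cells are assumed to drop out of the label gates.
#' @param horizon Simulation horizon (h); long enough to reach saturation
#'   under the defaults.
#' @return An object of class `competition_prediction` with fields `f_inf`,
#'   `f_t` (data frame `t`, `fraction_A`), `t_ss` (first time within 0.01 of
#'   `f_inf`), `degenerate`.
#' @examples
#' adapted <- growth_params()
#' predict_steady_state(adapted, adapted)$f_inf        # 0.5 exactly
#' predict_steady_state(adapted, adapted, d_B = 2/3)$f_inf  # 0.75
#' @export
predict_steady_state <- function(params_A, params_B, d_A = 0, d_B = 0,
                                 inoculum_ratio = c(1, 1), K = params_A$K,
                                 count_dead = FALSE, horizon = 150,
                                 step = 0.25) {
  traj <- simulate_competition(params_A, params_B, d_A, d_B, inoculum_ratio,
                               K = K, horizon = horizon, step = step)
  num <- traj$living_A + if (count_dead) traj$dead_A else 0
  den <- num + traj$living_B + if (count_dead) traj$dead_B else 0
  f_t <- data.frame(t = traj$t, fraction_A = ifelse(den > 0, num / den, NA))
  w <- inoculum_ratio / sum(inoculum_ratio)
  degenerate <- FALSE
  wA <- params_A$a0 * w[1] * (1 - d_A) * exp(-params_A$r * params_A$lag)
  wB <- params_B$a0 * w[2] * (1 - d_B) * exp(-params_B$r * params_B$lag)
  if (wA + wB <= 0) {
    f_inf <- NA_real_
  } else if (abs(params_A$r - params_B$r) < 1e-12 || wA == 0 || wB == 0) {
    f_inf <- wA / (wA + wB)
  } else {
    degenerate <- TRUE
    f_inf <- if (params_A$r > params_B$r) 1 else 0
  }
  close_enough <- which(abs(f_t$fraction_A - f_inf) < 0.01)
  t_ss <- if (length(close_enough)) f_t$t[close_enough[1L]] else Inf
  structure(list(f_inf = f_inf, f_t = f_t, t_ss = t_ss,
                 degenerate = degenerate, count_dead = count_dead),
            class = "competition_prediction")
}

#' @export
print.competition_prediction <- function(x, ...) {
  cat(sprintf("<competition_prediction> f_inf = %.4f%s, t_ss = %s\n",
              x$f_inf, if (x$degenerate) " (degenerate: unequal rates)" else "",
              if (is.infinite(x$t_ss)) "not reached" else
                sprintf("%.1f h", x$t_ss)))
  invisible(x)
}

#' Label-fraction time course from flow samples
#'
#' Per-time fraction of each label among counted events, with binomial
#' standard errors. Labels are the gate-name prefixes before `_live` /
#' `_dead`.
#'
#' @param samples List of [flow_sample()]s, time-ordered or not (sorted by
#'   `t` on output).
#' @param living_only Count only `_live` gates (default), matching the
#'   assumption that dead cells drop out of the label gates.
#' @return A data frame with columns `t`, `label`, `fraction`, `se`, `n`.
#' @export
fraction_timecourse <- function(samples, living_only = TRUE) {
  if (!length(samples)) stop("no flow samples given")
  rows <- lapply(samples, function(s) {
    stopifnot(inherits(s, "flow_sample"))
    counts <- s$counts
    if (living_only) counts <- counts[grepl("_live$", names(counts))]
    labels <- sub("_(live|dead)$", "", names(counts))
    tot <- sum(counts)
    if (tot <= 0) stop(sprintf("sample '%s' has zero counted events",
                               s$sample_id))
    agg <- tapply(counts, labels, sum)
    f <- as.numeric(agg) / tot
    data.frame(t = s$t, label = names(agg), fraction = f,
               se = sqrt(f * (1 - f) / tot), n = tot,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$t, out$label), , drop = FALSE]
}

#' Compare a competition prediction with an observed fraction trajectory
#'
#' Interpolates the predicted fraction at the observed time points and
#' reports the maximum absolute deviation, with an agreement flag at
#' `3 * se + slack` per point.
#'
#' @param pred A `competition_prediction`.
#' @param observed Data frame with columns `t`, `fraction` and (optionally)
#'   `se` for the population the prediction tracks.
#' @param slack Additive agreement slack beyond 3 binomial standard errors.
#' @return A list with `max_deviation`, `agree`, and the per-point
#'   comparison table.
#' @export
compare_prediction <- function(pred, observed, slack = 0.02) {
  stopifnot(inherits(pred, "competition_prediction"))
  if (!all(c("t", "fraction") %in% names(observed)))
    stop("'observed' needs columns 't' and 'fraction'")
  tmin <- min(pred$f_t$t); tmax <- max(pred$f_t$t)
  obs <- observed[observed$t >= tmin & observed$t <= tmax, , drop = FALSE]
  if (!nrow(obs)) stop("no overlapping time support")
  pred_f <- stats::approx(pred$f_t$t, pred$f_t$fraction_A, xout = obs$t)$y
  dev <- abs(obs$fraction - pred_f)
  se <- if ("se" %in% names(obs)) obs$se else 0
  tab <- data.frame(t = obs$t, observed = obs$fraction, predicted = pred_f,
                    deviation = dev, tolerance = 3 * se + slack)
  list(max_deviation = max(dev), agree = all(dev <= tab$tolerance),
       comparison = tab)
}
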