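#' Analyse a panel of dose traces
#'
#' Runs [measure_tau()] on each trace of a dose panel (as produced by
#' [generate_dose_panel()]) and returns the per-dose delay results.
#'
#' @param traces List of [od_trace()] objects carrying `dose_mM` metadata.
#' @param baseline_tau Optional baseline tau (h) used to classify delay
#'   presence per dose.
#' @param margin Delay-classification margin (h).
#' @param estimate_rate Estimate `r_hat` per trace (slower)?
#' @return A named list of `delay_result`s keyed by dose.
#' @export
analyze_dose_panel <- function(traces, baseline_tau = NULL, margin = 5,
                               estimate_rate = FALSE) {
  doses <- vapply(traces, function(tr) {
    d <- tr$metadata$dose_mM
    if (is.null(d)) stop("trace missing 'dose_mM' metadata")
    as.numeric(d)
  }, numeric(1))
  results <- lapply(traces, measure_tau, estimate_rate = estimate_rate)
  if (!is.null(baseline_tau)) {
    for (i in seq_along(results)) {
      results[[i]]$baseline_tau <- baseline_tau
      results[[i]]$delay_present <- classify_delay(results[[i]], baseline_tau,
                                                   margin)
    }
  }
  names(results) <- as.character(doses)
  results
}

#' Order delay results by dose and check tau monotonicity
#'
#' @param results Named list of `delay_result`s keyed by dose (as from
#'   [analyze_dose_panel()]), or unnamed with `doses` given.
#' @param doses Doses (mM) matching `results`; defaults to the list names.
#' @return An object of class `dose_panel_result` with fields `doses`
#'   (increasing), `taus` (h, `Inf` = censored), `delay_present`,
#'   `monotone_ok` (tau non-decreasing in dose, censored treated as +Inf)
#'   and `c_crit_hat` (NA until [estimate_critical_concentration()]).
#' @export
tau_dose_profile <- function(results, doses = as.numeric(names(results))) {
  if (length(results) < 2L || !any(doses == 0))
    stop("a dose panel needs at least two doses including 0")
  if (anyDuplicated(doses)) stop("duplicate doses in panel")
  if (any(is.na(doses))) stop("doses must be numeric")
  ord <- order(doses)
  taus <- unname(vapply(results, function(x) x$tau, numeric(1))[ord])
  delay <- unname(vapply(results, function(x) {
    if (is.null(x$delay_present) || is.na(x$delay_present)) NA else
      isTRUE(x$delay_present)
  }, logical(1))[ord])
  structure(list(doses = doses[ord], taus = taus, delay_present = delay,
                 monotone_ok = !is.unsorted(taus),
                 c_crit_hat = NA_real_),
            class = "dose_panel_result")
}

#' @export
print.dose_panel_result <- function(x, ...) {
  cat(sprintf("<dose_panel_result> %d doses (%g .. %g mM), %d censored, monotone: %s\n",
              length(x$doses), min(x$doses), max(x$doses),
              sum(is.infinite(x$taus)), x$monotone_ok))
  if (!is.na(x$c_crit_hat)) cat(sprintf("  c_crit_hat = %g mM\n", x$c_crit_hat))
  invisible(x)
}

#' Estimate the critical concentration from a dose panel
#'
#' The critical concentration is operationalised as the smallest tested dose
#' whose tau is censored within the observation horizon (growth fully
#' suppressed, no doubling). If censoring is not monotone across doses a
#' warning is raised and the smallest censored dose is still returned, with
#' the `inconsistent` attribute set.
#'
#' @param panel A `dose_panel_result`.
#' @param horizon Observation horizon (h); taus beyond it count as censored.
#' @return The estimated critical concentration (mM), or `NA` if no tested
#'   dose is censored; carries attribute `inconsistent`.
#' @export
estimate_critical_concentration <- function(panel, horizon = 75) {
  stopifnot(inherits(panel, "dose_panel_result"))
  censored <- is.infinite(panel$taus) | panel$taus > horizon
  if (!any(censored)) {
    out <- NA_real_
    attr(out, "inconsistent") <- FALSE
    return(out)
  }
  first <- which(censored)[1L]
  inconsistent <- !all(censored[first:length(censored)])
  if (inconsistent)
    warning("censoring is not monotone across doses")
  out <- panel$doses[first]
  attr(out, "inconsistent") <- inconsistent
  out
}

#' Potency shift between a standalone and a background dose panel
#'
#' Ratio of the standalone effect-threshold dose (smallest dose with a delay
#' phase) to the background effect-threshold dose. Values above 1 mean the
#' background potentiates the toxin; the conditioned-medium background
#' shifts the effective dose by roughly three orders of magnitude.
#'
#' @param standalone_panel,background_panel `dose_panel_result`s whose
#'   `delay_present` flags are populated.
#' @return The dose ratio (standalone / background).
#' @export
potency_shift <- function(standalone_panel, background_panel) {
  thr <- function(panel, what) {
    stopifnot(inherits(panel, "dose_panel_result"))
    if (any(is.na(panel$delay_present)))
      stop("panel lacks delay classifications (supply baseline_tau when analysing)")
    i <- which(panel$delay_present)
    if (!length(i)) stop(sprintf("no delay-inducing dose in the %s panel", what))
    panel$doses[i[1L]]
  }
  thr(standalone_panel, "standalone") / thr(background_panel, "background")
}
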