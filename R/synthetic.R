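#' Construct an OD trace
#'
#' The unit every analysis consumes: a time-stamped optical-density series
#' with condition metadata, sampled (by default) once per minute.
#'
#' @param sample_id Sample identifier.
#' @param time_min Times in minutes since inoculation, strictly increasing.
#' @param od Optical densities, non-negative, same length as `time_min`.
#' @param metadata Named list of condition metadata (e.g. `medium`, `strain`,
#'   `dose_mM`, `preculture`).
#' @return An object of class `od_trace`.
#' @export
od_trace <- function(sample_id, time_min, od, metadata = list()) {
  if (length(time_min) != length(od))
    stop("'time_min' and 'od' must have equal lengths")
  if (length(od) == 0L) stop("empty trace")
  if (any(!is.finite(time_min)) || any(diff(time_min) <= 0))
    stop("'time_min' must be finite and strictly increasing")
  if (any(!is.finite(od)) || any(od < 0))
    stop("'od' must be finite and non-negative")
  structure(list(sample_id = as.character(sample_id)[1L],
                 time_min = as.numeric(time_min), od = as.numeric(od),
                 metadata = metadata),
            class = "od_trace")
}

#' @export
print.od_trace <- function(x, ...) {
  cat(sprintf(
    "<od_trace> %s: %d samples over %.1f h, OD %.4g .. %.4g\n",
    x$sample_id, length(x$od), max(x$time_min) / 60, min(x$od), max(x$od)
  ))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Construct a flow-cytometry count sample
#'
#' Event counts per (label x viability) gate at one time point, e.g.
#' `green_live`, `green_dead`, `red_live`, `red_dead`, or `cells_live` /
#' `cells_dead` for single-population viability staining.
#'
#' @param sample_id Sample identifier.
#' @param t Time point (h).
#' @param counts Named non-negative integer vector of per-gate counts.
#' @return An object of class `flow_sample`.
#' @export
flow_sample <- function(sample_id, t, counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("'counts' must be a named vector of gate counts")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("'counts' must be non-negative integers")
  structure(list(sample_id = as.character(sample_id)[1L], t = as.numeric(t)[1L],
                 counts = stats::setNames(as.integer(round(counts)),
                                          names(counts))),
            class = "flow_sample")
}

#' @export
print.flow_sample <- function(x, ...) {
  cat(sprintf("<flow_sample> %s at t = %g h, %d events: %s\n",
              x$sample_id, x$t, sum(x$counts),
              paste(names(x$counts), x$counts, sep = "=", collapse = ", ")))
  invisible(x)
}

# Turbidimeter measurement noise: multiplicative log-normal component plus an
# additive Gaussian floor, clamped at zero.
.apply_od_noise <- function(od, noise_sd, noise_floor) {
  n <- length(od)
  noisy <- od * exp(stats::rnorm(n, 0, noise_sd)) +
    stats::rnorm(n, 0, noise_floor)
  pmax(noisy, 0)
}

#' Generate a noisy 1-minute OD trace from the forward model
#'
#' Samples [simulate_culture()] at the trace resolution and applies the
#' turbidimeter noise model: multiplicative log-normal noise of standard
#' deviation `noise_sd` plus an additive Gaussian floor of standard deviation
#' `noise_floor` OD units. Deterministic given `seed`; with both noise terms
#' zero the trace equals the forward model exactly.
#'
#' @param p A [growth_params()].
#' @param cond A [culture_condition()].
#' @param resp A [toxin_response()] translating `cond$effective_dose` into a
#'   kill fraction.
#' @param horizon Trace length (h); default 75 h, the span of a typical
#'   multi-day turbidimeter run.
#' @param noise_sd Multiplicative log-normal noise sd (fraction).
#' @param noise_floor Additive noise floor sd (OD units).
#' @param seed Integer seed; required for reproducibility.
#' @param sample_id Sample identifier.
#' @param step Sampling step (h); default one minute.
#' @return An [od_trace()].
#' @export
generate_od_trace <- function(p, cond = culture_condition(),
                              resp = hica_response(), horizon = 75,
                              noise_sd = 0.02, noise_floor = 0.002,
                              seed, sample_id = "sample",
                              step = 1 / 60) {
  stopifnot(inherits(p, "growth_params"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("an integer 'seed' is required")
  if (noise_sd < 0 || noise_floor < 0)
    stop("noise magnitudes must be non-negative")
  d <- kill_fraction(cond$effective_dose, resp, cond)
  traj <- simulate_culture(p, d, horizon = horizon, step = step)
  od <- withr::with_seed(as.integer(seed),
                         .apply_od_noise(traj$od, noise_sd, noise_floor))
  od_trace(sample_id, time_min = round(traj$t * 60, 6), od = od,
           metadata = list(medium = cond$medium_label,
                           dose_mM = cond$effective_dose,
                           kill_fraction = d,
                           glucose = cond$glucose_present,
                           adapted = cond$adapted))
}

#' Generate a dose panel of OD traces
#'
#' One trace per dose of a single toxin, sharing a seed stream. With
#' `background = TRUE` the panel emulates doses added on a conditioned-medium
#' background, where cofactors multiply the effective dose by the toxin's
#' potency factor `resp$s`.
#'
#' @param doses Non-negative doses (mM), typically including 0.
#' @param toxin A [toxin_response()].
#' @param p A [growth_params()].
#' @param seed Integer seed.
#' @param background Apply the conditioned-medium potency multiplier?
#' @inheritParams generate_od_trace
#' @return A list of [od_trace()], one per dose, each carrying `dose_mM`
#'   (the nominal dose) in its metadata.
#' @export
generate_dose_panel <- function(doses, toxin, p = growth_params(), seed,
                                background = FALSE, horizon = 75,
                                noise_sd = 0.02, noise_floor = 0.002) {
  if (any(doses < 0)) stop("doses must be non-negative")
  if (anyDuplicated(doses)) stop("duplicate doses in panel")
  out <- vector("list", length(doses))
  for (i in seq_along(doses)) {
    eff <- doses[i] * if (background) toxin$s else 1
    cond <- culture_condition(effective_dose = eff,
                              medium_label = sprintf("%s %g mM%s", toxin$name,
                                                     doses[i],
                                                     if (background) " + CM" else ""))
    out[[i]] <- generate_od_trace(p, cond, toxin, horizon = horizon,
                                  noise_sd = noise_sd,
                                  noise_floor = noise_floor,
                                  seed = as.integer(seed) + i - 1L,
                                  sample_id = sprintf("dose_%g", doses[i]))
    out[[i]]$metadata$dose_mM <- doses[i]
  }
  out
}

#' Generate recipient traces for a panel of conditioned-medium incubations
#'
#' For each incubation time, accumulates the secretion signal
#' ([secrete_toxin()]), calibrates it to an effective dose
#' ([cm_condition()]), and generates the OD trace of an unadapted recipient
#' culture inoculated into that medium.
#'
#' @param incubation_times Conditioned-medium incubation times (h).
#' @param sp A [secretion_params()].
#' @param p Recipient (and producer) [growth_params()].
#' @param resp The [toxin_response()] used by the calibration.
#' @param seed Integer seed.
#' @inheritParams generate_od_trace
#' @return A list of [od_trace()], each with `incubation_h` in its metadata.
#' @export
generate_cm_series <- function(incubation_times, sp = secretion_params(),
                               p = growth_params(), resp = hica_response(),
                               seed, horizon = 75, noise_sd = 0.02,
                               noise_floor = 0.002) {
  if (any(incubation_times < 0)) stop("incubation times must be non-negative")
  out <- vector("list", length(incubation_times))
  for (i in seq_along(incubation_times)) {
    sig <- secrete_toxin(p, sp, incubation_times[i])
    cond <- cm_condition(sig, sp, resp, growth = p)
    cond$medium_label <- sprintf("CM %g h", incubation_times[i])
    out[[i]] <- generate_od_trace(p, cond, resp, horizon = horizon,
                                  noise_sd = noise_sd,
                                  noise_floor = noise_floor,
                                  seed = as.integer(seed) + i - 1L,
                                  sample_id = sprintf("cm_%gh",
                                                      incubation_times[i]))
    out[[i]]$metadata$incubation_h <- incubation_times[i]
    out[[i]]$metadata$signal <- sig
  }
  out
}

#' Draw flow-cytometry counts from subpopulation states
#'
#' Multinomial sampling of gate counts with probabilities proportional to the
#' optical masses of the subpopulations' living (and, when `count_dead` is
#' TRUE, dead) compartments. Gate names are `<label>_live` and
#' `<label>_dead`.
#'
#' @param states Named list of subpopulation states, each a list with
#'   elements `living` and `dead` (OD units), e.g. one row of a
#'   [simulate_culture()] trajectory.
#' @param total_events Total number of events to draw (default 100000, the
#'   standard viability-staining depth; competition assays use 500000).
#' @param count_dead Should dead cells be gated (dyed) rather than dropped?
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @param t Time point (h) recorded in the sample.
#' @return A [flow_sample()].
#' @export
generate_flow_counts <- function(states, total_events = 100000,
                                 count_dead = TRUE, seed,
                                 sample_id = "flow", t = NA_real_) {
  if (is.null(names(states)) || any(!nzchar(names(states))))
    stop("'states' must be a named list of subpopulations")
  if (total_events < 1) stop("'total_events' must be positive")
  masses <- numeric(0)
  for (nm in names(states)) {
    st <- states[[nm]]
    m <- c(st$living, if (count_dead) st$dead)
    names(m) <- c(paste0(nm, "_live"), if (count_dead) paste0(nm, "_dead"))
    masses <- c(masses, m)
  }
  if (any(masses < 0) || any(!is.finite(masses)))
    stop("subpopulation masses must be finite and non-negative")
  if (sum(masses) <= 0) stop("all subpopulation masses are zero")
  counts <- withr::with_seed(
    as.integer(seed),
    as.vector(stats::rmultinom(1, size = as.integer(total_events),
                               prob = masses / sum(masses)))
  )
  flow_sample(sample_id, t, stats::setNames(counts, names(masses)))
}

#' Generate a Venn-structured compound presence table
#'
#' Emulates the metabolite-detection table behind the inhibitor screen:
#' `n_shared` compounds detected in both wild-type and fbp1-delta conditioned
#' media, of which `n_also_in_mm` are also present in fresh 0% MM (and hence
#' excluded from the candidate region), plus `n_noncm` compounds scattered
#' over the remaining Venn regions. Candidate-criterion flags are assigned so
#' that exactly `n_candidates` compounds of the candidate region survive
#' [candidate_filter()] (fewer if the region is smaller).
#'
#' @param n_shared Compounds detected in both conditioned media.
#' @param n_also_in_mm How many of those are also in fresh 0% MM
#'   (`<= n_shared`).
#' @param n_noncm Compounds outside the both-CM intersection.
#' @param seed Integer seed.
#' @param n_candidates Number of candidate-region compounds that pass all
#'   three candidate criteria.
#' @return A data frame of compound records with logical membership and
#'   criterion columns.
#' @export
generate_compound_table <- function(n_shared, n_also_in_mm, n_noncm, seed,
                                    n_candidates = 2) {
  if (n_also_in_mm > n_shared)
    stop("'n_also_in_mm' cannot exceed 'n_shared'")
  if (any(c(n_shared, n_also_in_mm, n_noncm, n_candidates) < 0))
    stop("counts must be non-negative")
  n <- n_shared + n_noncm
  withr::with_seed(as.integer(seed), {
    tab <- data.frame(
      compound = sprintf("cmpd_%03d", seq_len(max(n, 1))[seq_len(n)]),
      in_mm = logical(n), in_wt_cm = logical(n), in_fbp1_cm = logical(n),
      changes_postdelay_growth = logical(n),
      affects_growth_with_glucose = logical(n),
      delays_adapted_cells = logical(n),
      stringsAsFactors = FALSE
    )
    if (n_shared > 0) {
      shared <- seq_len(n_shared)
      tab$in_wt_cm[shared] <- TRUE
      tab$in_fbp1_cm[shared] <- TRUE
      if (n_also_in_mm > 0)
        tab$in_mm[sample(shared, n_also_in_mm)] <- TRUE
    }
    if (n_noncm > 0) {
      # regions outside the both-CM intersection
      regions <- list(c(TRUE, FALSE, FALSE),   # MM only
                      c(FALSE, TRUE, FALSE),   # WT CM only
                      c(FALSE, FALSE, TRUE),   # fbp1 CM only
                      c(TRUE, TRUE, FALSE),    # MM + WT CM
                      c(TRUE, FALSE, TRUE))    # MM + fbp1 CM
      pick <- sample(length(regions), n_noncm, replace = TRUE)
      for (j in seq_len(n_noncm)) {
        i <- n_shared + j
        memb <- regions[[pick[j]]]
        tab$in_mm[i] <- memb[1]; tab$in_wt_cm[i] <- memb[2]
        tab$in_fbp1_cm[i] <- memb[3]
      }
    }
    cand_region <- which(tab$in_wt_cm & tab$in_fbp1_cm & !tab$in_mm)
    n_pass <- min(n_candidates, length(cand_region))
    pass <- if (n_pass > 0) sample(cand_region, n_pass) else integer(0)
    fail <- setdiff(seq_len(n), pass)
    # each non-passing compound fails at least one criterion
    for (i in fail) {
      flags <- stats::runif(3) < 0.5
      if (!any(flags)) flags[sample.int(3, 1)] <- TRUE
      tab$changes_postdelay_growth[i] <- flags[1]
      tab$affects_growth_with_glucose[i] <- flags[2]
      tab$delays_adapted_cells[i] <- flags[3]
    }
    tab
  })
}
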