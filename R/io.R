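#' Write OD traces to a long-format CSV table
#'
#' Columns: `sample_id`, `time_min` (integer minutes), `od` (6 decimals),
#' plus the optional metadata columns `medium`, `strain`, `dose_mM`,
#' `preculture` when present in the traces.
#'
#' @param traces An [od_trace()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_od_table <- function(traces, path) {
  if (inherits(traces, "od_trace")) traces <- list(traces)
  meta_cols <- c("medium", "strain", "dose_mM", "preculture")
  rows <- lapply(traces, function(tr) {
    df <- data.frame(sample_id = tr$sample_id,
                     time_min = as.integer(round(tr$time_min)),
                     od = round(tr$od, 6), stringsAsFactors = FALSE)
    for (mc in meta_cols)
      if (!is.null(tr$metadata[[mc]])) df[[mc]] <- tr$metadata[[mc]]
    df
  })
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(df) {
    for (mc in setdiff(all_cols, names(df))) df[[mc]] <- NA
    df[all_cols]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read OD traces from a long-format CSV table
#'
#' Expects columns `sample_id`, `time_min`, `od` and accepts the optional
#' metadata columns `medium`, `strain`, `dose_mM`, `preculture`. Rows are
#' sorted by time within each sample; validation failures report the
#' offending row numbers of the file.
#'
#' @param path CSV path.
#' @return A named list of [od_trace()] objects, one per `sample_id`.
#' @export
read_od_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_min", "od")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  for (col in c("time_min", "od")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric '%s' at row(s) %s", col,
                   paste(utils::head(bad + 1L, 5), collapse = ", ")))
    df[[col]] <- v
  }
  neg <- which(df$od < 0)
  if (length(neg))
    stop(sprintf("negative OD at row(s) %s",
                 paste(utils::head(neg + 1L, 5), collapse = ", ")))
  meta_cols <- intersect(c("medium", "strain", "dose_mM", "preculture"),
                         names(df))
  ids <- unique(df$sample_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$sample_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_min), , drop = FALSE]
    if (anyDuplicated(sub$time_min))
      stop(sprintf("duplicate time points in sample '%s'", id))
    meta <- lapply(meta_cols, function(mc) sub[[mc]][1L])
    names(meta) <- meta_cols
    od_trace(id, sub$time_min, sub$od, metadata = meta)
  })
  stats::setNames(out, ids)
}

#' Write flow samples to CSV
#' @param samples A [flow_sample()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flow_table <- function(samples, path) {
  if (inherits(samples, "flow_sample")) samples <- list(samples)
  rows <- lapply(samples, function(s)
    data.frame(sample_id = s$sample_id, t_h = s$t, gate = names(s$counts),
               count = as.integer(s$counts), stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read flow samples from CSV
#' @param path CSV path with columns `sample_id`, `t_h`, `gate`, `count`.
#' @return A named list of [flow_sample()]s.
#' @export
read_flow_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "t_h", "gate", "count")
  if (!all(need %in% names(df)))
    stop("missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  ids <- unique(df$sample_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$sample_id == id, , drop = FALSE]
    flow_sample(id, sub$t_h[1L],
                stats::setNames(sub$count, sub$gate))
  })
  stats::setNames(out, ids)
}

#' Write a compound table to CSV
#' @param records Compound data frame (see [generate_compound_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a compound table from CSV
#' @param path CSV path.
#' @return Compound data frame with logical flag columns.
#' @export
read_compound_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"compound" %in% names(df)) stop("missing 'compound' column")
  flag_cols <- setdiff(names(df), "compound")
  for (fc in flag_cols) df[[fc]] <- as.logical(df[[fc]])
  df
}

#' Default pipeline configuration
#'
#' Nested list of generator and analysis settings used by [run_pipeline()].
#' `seed` has no default and must be supplied (in the config or as the
#' `seed` argument).
#'
#' @return A named list of configuration sections.
#' @export
default_config <- function() {
  list(
    seed = NULL,
    growth = list(r = log(2) / 10, lag = 0, K = 1.0, a0 = 0.02),
    noise = list(sd = 0.02, floor = 0.002),
    horizon = 75,
    cm = list(incubation_times = c(5, 10, 15, 20, 25, 30),
              anchor_incubation = 30),
    dose = list(doses = seq(0, 40, by = 2.5)),
    competition = list(total_events = 500000,
                       timepoints = c(0, 8, 16, 24, 32, 40, 48),
                       d_unadapted = 2 / 3),
    viability = list(total_events = 100000, sample_time = 8,
                     kill_fraction = 0.9),
    screen = list(n_shared = 20, n_also_in_mm = 8, n_noncm = 5,
                  n_candidates = 2)
  )
}

.merge_config <- function(base, user) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the end-to-end synthetic pipeline
#'
#' Generates synthetic data at the configured parameters, analyses it, and
#' returns (and optionally writes) a summary: baseline doubling time, the
#' conditioned-medium tau and inferred kill fraction, the critical
#' concentrations of both autotoxins, the smallest delay-inducing incubation
#' time, the competition steady-state prediction and its agreement with
#' simulated flow counts, the 8-h dyed fraction under a near-critical dose,
#' and the Venn screen counts. Fully reproducible: the same `(config, seed)`
#' yields byte-identical summaries.
#'
#' @param config Configuration list (see [default_config()]) or path to a
#'   YAML file with the same structure. Unknown keys raise an error before
#'   any computation.
#' @param out_dir Optional output directory; when given, intermediate tables
#'   (OD, flow, compound CSVs) and `summary.json` are written there.
#' @param seed Overrides `config$seed` when given.
#' @param verbose Emit one progress line per stage?
#' @return The summary as a named list (invisibly the same content as
#'   `summary.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL,
                         verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a list or a YAML path")
  cfg <- .merge_config(default_config(), config)
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) stop("config is missing 'seed'")
  seed <- as.integer(cfg$seed)
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  p <- growth_params(r = cfg$growth$r, lag = cfg$growth$lag, K = cfg$growth$K,
                     a0 = cfg$growth$a0)
  hica <- hica_response(); mva <- mva_response()
  sp <- secretion_params(growth = p)
  noise <- cfg$noise

  say("stage=baseline seed=%d medium='0%% MM'", seed)
  baseline <- generate_od_trace(p, culture_condition(), hica,
                                horizon = cfg$horizon, noise_sd = noise$sd,
                                noise_floor = noise$floor, seed = seed + 1L,
                                sample_id = "baseline_0mm")
  base_res <- measure_tau(baseline)
  doubling <- log(2) / base_res$r_hat

  say("stage=cm_series incubations=%s",
      paste(cfg$cm$incubation_times, collapse = ","))
  cm_traces <- generate_cm_series(cfg$cm$incubation_times, sp, p, hica,
                                  seed = seed + 10L, horizon = cfg$horizon,
                                  noise_sd = noise$sd,
                                  noise_floor = noise$floor)
  cm_res <- lapply(cm_traces, measure_tau, estimate_rate = FALSE)
  cm_delay <- vapply(cm_res, classify_delay, logical(1),
                     baseline_tau = base_res$tau)
  inducing <- cfg$cm$incubation_times[cm_delay]
  min_inducing <- if (length(inducing)) min(inducing) else NA_real_
  anchor_i <- match(cfg$cm$anchor_incubation, cfg$cm$incubation_times)
  tau_cm <- cm_res[[anchor_i]]$tau
  d_hat_cm <- estimate_death_from_curve(tau_cm, base_res$r_hat)$d_hat

  say("stage=dose_panels doses=%g..%g", min(cfg$dose$doses),
      max(cfg$dose$doses))
  crit <- lapply(list(HICA = hica, `2K3MVA` = mva), function(tox) {
    traces <- generate_dose_panel(cfg$dose$doses, tox, p,
                                  seed = seed + 100L +
                                    as.integer(tox$c_crit),
                                  horizon = cfg$horizon,
                                  noise_sd = noise$sd,
                                  noise_floor = noise$floor)
    panel <- tau_dose_profile(analyze_dose_panel(traces,
                                                 baseline_tau = base_res$tau))
    as.numeric(estimate_critical_concentration(panel, horizon = cfg$horizon))
  })

  say("stage=competition events=%d", cfg$competition$total_events)
  d_un <- cfg$competition$d_unadapted
  pred <- predict_steady_state(p, p, d_A = 0, d_B = d_un, count_dead = TRUE)
  comp_traj <- simulate_competition(p, p, d_A = 0, d_B = d_un)
  flow_samples <- lapply(seq_along(cfg$competition$timepoints), function(i) {
    tp <- cfg$competition$timepoints[i]
    row <- comp_traj[which.min(abs(comp_traj$t - tp)), ]
    generate_flow_counts(
      list(adapted = list(living = row$living_A, dead = row$dead_A),
           unadapted = list(living = row$living_B, dead = row$dead_B)),
      total_events = cfg$competition$total_events, count_dead = TRUE,
      seed = seed + 300L + i, sample_id = sprintf("comp_t%g", tp), t = tp)
  })
  frac <- fraction_timecourse(flow_samples, living_only = FALSE)
  obs_adapted <- frac[frac$label == "adapted", ]
  comp_check <- compare_prediction(pred, obs_adapted)

  say("stage=viability kill=%g t=%g h", cfg$viability$kill_fraction,
      cfg$viability$sample_time)
  vtraj <- simulate_culture(p, cfg$viability$kill_fraction,
                            horizon = cfg$viability$sample_time)
  vrow <- vtraj[nrow(vtraj), ]
  vflow <- generate_flow_counts(
    list(cells = list(living = vrow$living, dead = vrow$dead)),
    total_events = cfg$viability$total_events, count_dead = TRUE,
    seed = seed + 400L, sample_id = "viability_8h",
    t = cfg$viability$sample_time)
  dyed <- dyed_fraction(vflow)

  say("stage=screen shared=%d in_mm=%d", cfg$screen$n_shared,
      cfg$screen$n_also_in_mm)
  compounds <- generate_compound_table(cfg$screen$n_shared,
                                       cfg$screen$n_also_in_mm,
                                       cfg$screen$n_noncm,
                                       seed = seed + 500L,
                                       n_candidates = cfg$screen$n_candidates)
  venn <- venn_partition(compounds)
  candidates <- candidate_filter(
    compounds[compounds$compound %in% venn$candidates, , drop = FALSE])

  summary <- list(
    seed = seed,
    doubling_time_h = doubling,
    r_hat = base_res$r_hat,
    baseline_tau_h = base_res$tau,
    tau_cm_h = tau_cm,
    d_hat_cm = d_hat_cm,
    c_crit_hica_mM = crit$HICA,
    c_crit_mva_mM = crit$`2K3MVA`,
    min_delay_incubation_h = min_inducing,
    f_inf = pred$f_inf,
    competition_max_deviation = comp_check$max_deviation,
    dyed_fraction = dyed,
    venn_candidate_region = unname(venn$counts[["wt_cm&fbp1_cm"]]),
    n_candidates_pass = nrow(candidates),
    checks = list(
      doubling_within_2pct = abs(doubling - 10) / 10 <= 0.02,
      tau_cm_within_15pct = abs(tau_cm - 20) / 20 <= 0.15,
      c_crit_recovered = identical(crit$HICA, 30) && identical(crit$`2K3MVA`, 25),
      delay_threshold_ge_15h = !is.na(min_inducing) && min_inducing >= 15,
      competition_agrees = comp_check$agree,
      dyed_ge_80pct = dyed >= 0.8
    )
  )

  if (!is.null(out_dir)) {
    write_od_table(c(list(baseline), cm_traces),
                   file.path(out_dir, "od_traces.csv"))
    write_flow_table(c(flow_samples, list(vflow)),
                     file.path(out_dir, "flow_counts.csv"))
    write_compound_table(compounds, file.path(out_dir, "compounds.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    say("stage=write out_dir=%s", out_dir)
  }
  invisible(summary)
}
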