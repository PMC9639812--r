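#' Kinetic growth parameters for one strain/condition
#'
#' Bundles the per-strain, per-condition parameters of the two-compartment
#' culture model: the exponential growth rate at the steady growth phase, the
#' survivor lag, the OD carrying cap and the inoculum OD.
#'
#' @param r Exponential growth rate of living cells (1/h). The default,
#'   `log(2)/10`, corresponds to the ~10 h doubling time of fission yeast in
#'   glucose-free minimal medium with glycerol (0% MM).
#' @param lag Survivor lag before growth resumes (h). Default 0: the delay
#'   phase in this model arises from dead-cell optical masking, not from a
#'   physiological lag of the survivors.
#' @param K Carrying cap of the culture in OD units. Total optical mass
#'   (living + dead) saturates at this value.
#' @param a0 Inoculum OD at time zero.
#'
#' @return An object of class `growth_params`.
#' @examples
#' p <- growth_params()            # 0% MM defaults, 10 h doubling
#' growth_params(r = log(2) / 4)   # a glucose-fed culture doubling in 4 h
#' @export
growth_params <- function(r = log(2) / 10, lag = 0, K = 1.0, a0 = 0.02) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("'r' must be a single positive finite number (1/h)")
  if (!is.numeric(lag) || length(lag) != 1L || !is.finite(lag) || lag < 0)
    stop("'lag' must be a single non-negative number (h)")
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("'K' must be a single positive finite OD value")
  if (!is.numeric(a0) || length(a0) != 1L || !is.finite(a0) || a0 <= 0 || a0 >= K)
    stop("'a0' must satisfy 0 < a0 < K")
  structure(list(r = r, lag = lag, K = K, a0 = a0), class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "<growth_params> r = %.4g /h (doubling %.3g h), lag = %.3g h, K = %.3g OD, a0 = %.3g OD\n",
    x$r, log(2) / x$r, x$lag, x$K, x$a0
  ))
  invisible(x)
}

#' Dose-response parameters of an autotoxin
#'
#' Describes how the kill fraction of an unadapted inoculum depends on the
#' toxin dose: a Hill curve saturating at `d_max` below the critical
#' concentration, and complete killing (kill fraction 1) at or above it.
#' `s` is the background-potency multiplier: on a conditioned-medium
#' background, cofactors potentiate the added toxin so that its effective
#' dose is `s` times the nominal one.
#'
#' @param c_crit Critical concentration (mM): at or above it growth is fully
#'   suppressed.
#' @param h Half-effect concentration of the sub-critical Hill response (mM);
#'   must be below `c_crit`.
#' @param n Hill steepness (dimensionless, >= 1).
#' @param d_max Maximal sub-critical kill fraction, in [0, 1).
#' @param s Background potency multiplier (>= 1) applied to doses added on a
#'   conditioned-medium background.
#' @param name Optional toxin label.
#'
#' @return An object of class `toxin_response`.
#' @seealso [hica_response()], [mva_response()] for the two identified
#'   autotoxins' default parameter sets.
#' @export
toxin_response <- function(c_crit, h, n = 4, d_max = 0.97, s = 1000,
                           name = "toxin") {
  if (!is.numeric(c_crit) || length(c_crit) != 1L || c_crit <= 0)
    stop("'c_crit' must be a single positive concentration (mM)")
  if (!is.numeric(h) || length(h) != 1L || h <= 0 || h >= c_crit)
    stop("'h' must satisfy 0 < h < c_crit")
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be >= 1")
  if (!is.numeric(d_max) || length(d_max) != 1L || d_max < 0 || d_max >= 1)
    stop("'d_max' must lie in [0, 1)")
  if (!is.numeric(s) || length(s) != 1L || s < 1)
    stop("'s' must be >= 1")
  structure(list(c_crit = c_crit, h = h, n = n, d_max = d_max, s = s,
                 name = as.character(name)[1L]),
            class = "toxin_response")
}

#' @export
print.toxin_response <- function(x, ...) {
  cat(sprintf(
    "<toxin_response> %s: c_crit = %g mM, h = %g mM, n = %g, d_max = %g, s = %g\n",
    x$name, x$c_crit, x$h, x$n, x$d_max, x$s
  ))
  invisible(x)
}

#' Default response of HICA (leucic acid)
#'
#' Critical concentration 30 mM; sub-critical Hill response with half-effect
#' 20 mM and steepness 4.
#' @return A [toxin_response()].
#' @export
hica_response <- function() {
  toxin_response(c_crit = 30, h = 20, n = 4, d_max = 0.97, s = 1000,
                 name = "HICA")
}

#' Default response of 2K3MVA (L-2-keto-3-methylvalerate)
#'
#' Critical concentration 25 mM; sub-critical Hill response with half-effect
#' 16 mM and steepness 4.
#' @return A [toxin_response()].
#' @export
mva_response <- function() {
  toxin_response(c_crit = 25, h = 16, n = 4, d_max = 0.97, s = 1000,
                 name = "2K3MVA")
}

#' Culture condition metadata
#'
#' The context in which an inoculum meets the medium. Glucose and prior
#' adaptation each fully protect cells from the autotoxins, so either flag
#' forces the kill fraction to zero regardless of dose.
#'
#' @param glucose_present Is glucose present in the medium?
#' @param adapted Were the cells precultured under glucose depletion (or
#'   toxin preexposure), i.e. already adapted?
#' @param effective_dose Toxin-equivalent dose after any potency scaling (mM).
#' @param medium_label Free-text medium description.
#'
#' @return An object of class `culture_condition`.
#' @export
culture_condition <- function(glucose_present = FALSE, adapted = FALSE,
                              effective_dose = 0, medium_label = "0% MM") {
  if (!is.logical(glucose_present) || length(glucose_present) != 1L ||
      is.na(glucose_present))
    stop("'glucose_present' must be TRUE or FALSE")
  if (!is.logical(adapted) || length(adapted) != 1L || is.na(adapted))
    stop("'adapted' must be TRUE or FALSE")
  if (!is.numeric(effective_dose) || length(effective_dose) != 1L ||
      is.na(effective_dose) || effective_dose < 0)
    stop("'effective_dose' must be a single non-negative dose (mM)")
  structure(list(glucose_present = glucose_present, adapted = adapted,
                 effective_dose = effective_dose,
                 medium_label = as.character(medium_label)[1L]),
            class = "culture_condition")
}

#' @export
print.culture_condition <- function(x, ...) {
  cat(sprintf(
    "<culture_condition> %s: glucose %s, adapted %s, effective dose %g mM\n",
    x$medium_label, x$glucose_present, x$adapted, x$effective_dose
  ))
  invisible(x)
}

# Accumulated toxin signal of an exponentially growing producer culture,
# with per-culture secretion rate proportional to N(u)^2 (closed form).
.toxin_signal <- function(t, r, a0, t_ind, k) {
  out <- numeric(length(t))
  past <- t > t_ind
  out[past] <- k * a0^2 / (2 * r) *
    (exp(2 * r * t[past]) - exp(2 * r * t_ind))
  out
}

#' Toxin secretion parameters for conditioned-medium preparation
#'
#' During conditioned-medium (CM) preparation the producer culture secretes
#' autotoxins at a density-dependent per-cell rate, so the per-culture rate
#' is proportional to the squared cell density. Secretion starts after an
#' induction delay `t_ind`. `E_thresh` is the accumulated-signal threshold
#' above which the resulting CM induces a delay phase in a recipient culture;
#' by default it is placed at the geometric mean of the signals accumulated
#' by 15 h and 20 h of incubation (under `growth`), i.e. strictly between
#' them, so that media incubated 15 h or less do not induce a delay while
#' longer-incubated media do.
#'
#' @param t_ind Induction delay before secretion starts (h).
#' @param k Secretion coefficient (signal units per OD^2 per h).
#' @param E_thresh Delay-inducing accumulated-signal threshold; `NULL` (the
#'   default) places it between the 15-h and 20-h signals.
#' @param growth [growth_params()] of the producer culture used to position
#'   the default threshold.
#'
#' @return An object of class `secretion_params`.
#' @export
secretion_params <- function(t_ind = 2, k = 1, E_thresh = NULL,
                             growth = growth_params()) {
  if (!is.numeric(t_ind) || length(t_ind) != 1L || t_ind < 0)
    stop("'t_ind' must be a single non-negative time (h)")
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("'k' must be a single positive secretion coefficient")
  if (is.null(E_thresh)) {
    s15 <- .toxin_signal(15, growth$r, growth$a0, t_ind, k)
    s20 <- .toxin_signal(20, growth$r, growth$a0, t_ind, k)
    E_thresh <- sqrt(s15 * s20)
  }
  if (!is.numeric(E_thresh) || length(E_thresh) != 1L || E_thresh <= 0)
    stop("'E_thresh' must be a single positive signal value")
  structure(list(t_ind = t_ind, k = k, E_thresh = E_thresh),
            class = "secretion_params")
}

#' @export
print.secretion_params <- function(x, ...) {
  cat(sprintf(
    "<secretion_params> t_ind = %g h, k = %g, E_thresh = %.4g\n",
    x$t_ind, x$k, x$E_thresh
  ))
  invisible(x)
}
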