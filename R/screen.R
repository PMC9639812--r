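#' Venn partition of compound detections across three media
#'
#' Partitions compound records into the seven membership regions of the
#' (0% MM, WT CM, fbp1-delta CM) Venn diagram. The candidate region for the
#' inhibitor screen is the set detected in both conditioned media but not in
#' fresh medium: compounds that appear only because cells conditioned the
#' medium.
#'
#' @param records Data frame of compound records with columns `compound`,
#'   `in_mm`, `in_wt_cm`, `in_fbp1_cm` (as from
#'   [generate_compound_table()]).
#' @return A list with `counts` (named integer vector over the 7 regions),
#'   `members` (named list of compound names), and `candidates` (the
#'   `wt_cm&fbp1_cm` region members).
#' @export
venn_partition <- function(records) {
  need <- c("compound", "in_mm", "in_wt_cm", "in_fbp1_cm")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(records$compound))
    stop("duplicate compound names")
  mm <- as.logical(records$in_mm)
  wt <- as.logical(records$in_wt_cm)
  fb <- as.logical(records$in_fbp1_cm)
  if (any(is.na(mm) | is.na(wt) | is.na(fb)))
    stop("membership flags must be TRUE/FALSE")
  region <- list(
    "mm_only"            = mm & !wt & !fb,
    "wt_cm_only"         = !mm & wt & !fb,
    "fbp1_cm_only"       = !mm & !wt & fb,
    "mm&wt_cm"           = mm & wt & !fb,
    "mm&fbp1_cm"         = mm & !wt & fb,
    "wt_cm&fbp1_cm"      = !mm & wt & fb,
    "mm&wt_cm&fbp1_cm"   = mm & wt & fb
  )
  members <- lapply(region, function(sel) records$compound[sel])
  counts <- vapply(members, length, integer(1))
  list(counts = counts, members = members,
       candidates = members[["wt_cm&fbp1_cm"]])
}

#' Filter candidate inhibitors by the three screening criteria
#'
#' A genuine growth-inhibitor candidate (1) does not change the growth rate
#' after the delay phase, (2) has little effect on growth in the presence of
#' glucose, and (3) causes a shorter delay phase in already-adapted cells.
#' Records failing any criterion are dropped; order is preserved and the
#' filter is idempotent.
#'
#' @param candidates Data frame of compound records carrying the logical
#'   columns `changes_postdelay_growth`, `affects_growth_with_glucose` and
#'   `delays_adapted_cells` (TRUE = the compound fails that criterion).
#' @return The filtered data frame.
#' @export
candidate_filter <- function(candidates) {
  need <- c("changes_postdelay_growth", "affects_growth_with_glucose",
            "delays_adapted_cells")
  if (!all(need %in% names(candidates)))
    stop("records must carry criterion flags: ", paste(need, collapse = ", "))
  flags <- candidates[need]
  if (any(vapply(flags, function(x) any(is.na(x)), logical(1))))
    stop("criterion flags must not be missing")
  keep <- !candidates$changes_postdelay_growth &
    !candidates$affects_growth_with_glucose &
    !candidates$delays_adapted_cells
  candidates[keep, , drop = FALSE]
}
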