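#' Head-to-head uptake ratio
#'
#' Mean ROI uptake of the affected femoral head divided by that of the
#' contralateral (unaffected) head. Because both operands come from the same
#' scan, the ratio cancels dose, timing and clearance variability, which is
#' the point of relative quantification.
#'
#' @param affected_mean,unaffected_mean Positive mean ROI uptakes.
#' @return `affected_mean / unaffected_mean`. Vectorized.
#' @export
#' @examples
#' head_to_head_ratio(66.3, 201.3)  # 0.329, an avascular head
head_to_head_ratio <- function(affected_mean, unaffected_mean) {
  if (any(!is.finite(unaffected_mean)) || any(unaffected_mean <= 0))
    stop("unaffected-head mean uptake must be > 0: ratio undefined",
         call. = FALSE)
  if (any(!is.finite(affected_mean)) || any(affected_mean <= 0))
    stop("affected-head mean uptake must be > 0", call. = FALSE)
  affected_mean / unaffected_mean
}

#' Head-to-acetabulum uptake ratio
#'
#' Affected femoral-head uptake divided by the uptake of the ipsilateral
#' acetabular dome — the reference used when the contralateral hip cannot
#' serve as comparison.
#'
#' @param head_mean,dome_mean Positive mean ROI uptakes.
#' @return `head_mean / dome_mean`. Vectorized.
#' @export
head_to_acetabulum_ratio <- function(head_mean, dome_mean) {
  if (any(!is.finite(dome_mean)) || any(dome_mean <= 0))
    stop("acetabular-dome mean uptake must be > 0: ratio undefined",
         call. = FALSE)
  if (any(!is.finite(head_mean)) || any(head_mean <= 0))
    stop("affected-head mean uptake must be > 0", call. = FALSE)
  head_mean / dome_mean
}

#' Select the reference site for a patient
#'
#' A healthy contralateral hip serves as the reference (head-to-head
#' ratio); a contralateral hip carrying an implant, osteonecrosis or
#' osteoarthritis is incomparable, and the analysis substitutes the
#' ipsilateral acetabular dome.
#'
#' @param record A patient record (list or one-row data frame) with a
#'   `contralateral_status` field, or a character vector of statuses.
#' @return `"contralateral_head"` or `"ipsilateral_acetabulum"` per patient.
#' @export
#' @examples
#' select_reference("healthy")  # contralateral_head
#' select_reference("implant")  # ipsilateral_acetabulum
select_reference <- function(record) {
  status <- if (is.character(record)) record else record[["contralateral_status"]]
  if (is.null(status))
    stop("record has no `contralateral_status`", call. = FALSE)
  bad <- setdiff(unique(status), c("healthy", "implant", "onfh", "oa"))
  if (length(bad))
    stop("unknown contralateral status: ", paste(bad, collapse = ", "),
         call. = FALSE)
  ifelse(status == "healthy", "contralateral_head", "ipsilateral_acetabulum")
}

#' Classify perfusion status from an uptake ratio
#'
#' Lower uptake in the affected head signals a perfusion deficit, so a
#' ratio at or below the cutoff is called `predicted_onfh` and a ratio
#' above it `predicted_viable`. A ratio exactly at the cutoff is classified
#' as `predicted_onfh` (conservative toward detecting necrosis).
#'
#' @param ratio Positive uptake ratio(s).
#' @param cutoff Positive classification cutoff (0.5 for the head-to-head
#'   ratio, 0.3 for the head-to-acetabulum ratio).
#' @return Character vector of `"predicted_onfh"` / `"predicted_viable"`.
#' @export
#' @examples
#' classify_perfusion(c(0.33, 1.30), cutoff = 0.5)
classify_perfusion <- function(ratio, cutoff) {
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("`ratio` must be positive and finite", call. = FALSE)
  if (!is.finite(cutoff) || cutoff <= 0)
    stop("`cutoff` must be positive", call. = FALSE)
  ifelse(ratio <= cutoff, "predicted_onfh", "predicted_viable")
}

#' Score a cohort: ratios, reference selection and cutoff classification
#'
#' Adds to a cohort the reference site used per patient, the primary ratio
#' that reference implies, and the predicted perfusion class at each
#' requested cutoff. Both ratios are kept for every patient (reference
#' selection only controls which one feeds the primary classification).
#'
#' @param records Cohort data frame with `head_to_head_ratio`,
#'   `head_to_acetabulum_ratio` and `contralateral_status` columns.
#' @param cutoff Classification cutoff applied to the chosen ratio.
#' @param ratio Which ratio to classify on: `"auto"` applies
#'   [select_reference()] per patient; `"head_to_head"` or
#'   `"head_to_acetabulum"` force one column for the whole cohort.
#' @return The cohort with `reference_used`, `primary_ratio` and
#'   `prediction` columns added.
#' @export
score_cohort <- function(records, cutoff,
                         ratio = c("auto", "head_to_head",
                                   "head_to_acetabulum")) {
  ratio <- match.arg(ratio)
  stopifnot(is.data.frame(records))
  records$reference_used <- switch(
    ratio,
    auto = select_reference(records$contralateral_status),
    head_to_head = "contralateral_head",
    head_to_acetabulum = "ipsilateral_acetabulum"
  )
  records$primary_ratio <- ifelse(
    records$reference_used == "contralateral_head",
    records$head_to_head_ratio,
    records$head_to_acetabulum_ratio
  )
  records$prediction <- classify_perfusion(records$primary_ratio, cutoff)
  records
}
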