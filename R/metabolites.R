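#' Summarise a metabolite time course
#'
#' Descriptive summary of one transformation-product series: when it was
#' first detected, when and how high it peaked, what was left at the end of
#' the observation horizon, and whether it persisted. Two quantification
#' modes are supported: `quantified_ug_per_L` (absolute concentrations with
#' a limit of quantification, LOQ) and `peak_area` (semi-quantitative
#' chromatographic areas, where any positive area counts as detection).
#' Values below the LOQ are treated as non-detections for the detection and
#' persistence flags but are retained numerically.
#'
#' @param times Sampling times in days, strictly increasing.
#' @param values Measured values (ug/L or peak-area units), `>= 0`.
#' @param mode `"quantified_ug_per_L"` or `"peak_area"`.
#' @param loq Limit of quantification (ug/L); required for (and only
#'   allowed in) quantified mode.
#' @param horizon End of the assessment window in days (default: last
#'   observed time). The final value is the last observation at or before
#'   the horizon.
#' @param analyte_id Label carried into the output.
#' @return A one-row tibble: `analyte_id`, `mode`, `first_detection_time`,
#'   `t_max`, `max_value`, `final_value`, `persistent`. Detection-derived
#'   fields are `NA` when the analyte was never detected.
#' @examples
#' summarize_analyte(c(0, 0.5, 28), c(0, 73.8, 29),
#'                   mode = "quantified_ug_per_L", loq = 0.1)
#' @export
summarize_analyte <- function(times, values, mode = c("quantified_ug_per_L",
                                                      "peak_area"),
                              loq = NULL, horizon = NULL,
                              analyte_id = "analyte") {
  mode <- match.arg(mode)
  if (length(times) == 0) abort("Empty series.")
  if (length(times) != length(values)) {
    abort("`times` and `values` must have the same length.")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing.")
  }
  check_nonneg(times, "times"); check_nonneg(values, "values")
  if (mode == "quantified_ug_per_L") {
    if (is.null(loq)) abort("Quantified mode requires `loq`.")
    check_scalar_num(loq, "loq")
    detect_lim <- loq
  } else {
    if (!is.null(loq)) abort("`loq` only applies to quantified mode.")
    detect_lim <- 0
  }
  horizon <- horizon %||% max(times)

  detected <- if (detect_lim > 0) values >= detect_lim else values > 0
  in_window <- times <= horizon
  if (!any(in_window)) abort("No observations at or before `horizon`.")
  final_idx <- max(which(in_window))
  final_value <- values[final_idx]

  if (any(detected)) {
    first_detection <- times[which(detected)[1]]
    t_max <- times[which.max(values)]
    max_value <- max(values)
  } else {
    first_detection <- NA_real_
    t_max <- NA_real_
    max_value <- NA_real_
  }
  persistent <- if (detect_lim > 0) final_value >= detect_lim else final_value > 0
  tibble::tibble(
    analyte_id = analyte_id, mode = mode,
    first_detection_time = first_detection,
    t_max = t_max, max_value = max_value,
    final_value = final_value, persistent = persistent
  )
}

#' Summarise several analytes from a long table
#'
#' Applies [summarize_analyte()] per analyte of a long time-course table.
#'
#' @param data A data frame with columns `analyte_id`, `mode`, `time_days`,
#'   `value` and (for quantified analytes) `loq`.
#' @param horizon Assessment horizon in days, passed through.
#' @return A tibble with one summary row per analyte.
#' @export
summarize_analytes <- function(data, horizon = NULL) {
  need <- c("analyte_id", "mode", "time_days", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  data |>
    dplyr::group_by(.data$analyte_id) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$time_days)
      mode <- unique(d$mode)
      if (length(mode) != 1) abort("Mixed modes within one analyte.")
      loq <- if (mode == "quantified_ug_per_L") unique(d$loq) else NULL
      summarize_analyte(d$time_days, d$value, mode = mode, loq = loq,
                        horizon = horizon, analyte_id = key$analyte_id)[-1]
    }) |>
    dplyr::ungroup()
}
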