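# Animal-level drug-response labeling under three published standards, and
# arm-level response indices (response rate, disease control rate).

.response_levels <- c("CR", "PR", "SD", "PD")

#' Default thresholds for a response-labeling standard
#'
#' Returns the adjustable cutoffs of one of the three labeling standards,
#' optionally overriding individual values.
#'
#' * `npdxe` (mouse-RECIST style, from the Novartis PDX encyclopedia):
#'   levels from BestResponse (minimum percent volume change from baseline
#'   on or after `min_day`) and BestAvgResponse (minimum running mean of the
#'   percent change): CR when best < `cr_best` and average < `cr_avg`;
#'   PR when best < `pr_best` and average < `pr_avg`; SD when best <
#'   `sd_best` and average < `sd_avg`; otherwise PD.
#' * `pptp` (Pediatric Preclinical Testing Program, solid tumors): CR when
#'   the volume ever drops below `measurable_mm3`; else PR when the minimum
#'   relative tumor volume `V_t / V_0` is at most `pr_rtv`; else PD when the
#'   final relative volume exceeds `pd_rtv`; else SD.
#' * `rc` (volume-adapted relative-change criteria): judged on the percent
#'   change at the last day: CR at or below `cr_pct`, PR at or below
#'   `pr_pct`, PD at or above `pd_pct`, SD in between.
#'
#' @param standard `"npdxe"`, `"pptp"` or `"rc"`.
#' @param ... Named overrides of individual cutoffs.
#' @return A named list of cutoffs with class `response_thresholds`.
#' @export
response_thresholds <- function(standard = c("npdxe", "pptp", "rc"), ...) {
  standard <- match.arg(standard)
  th <- switch(standard,
    npdxe = list(min_day = 10,
                 cr_best = -95, cr_avg = -40,
                 pr_best = -50, pr_avg = -20,
                 sd_best = 35, sd_avg = 30),
    pptp = list(measurable_mm3 = 100, pr_rtv = 0.5, pd_rtv = 1.25),
    rc = list(cr_pct = -95, pr_pct = -65, pd_pct = 73))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(th))
  if (length(unknown) > 0L) {
    stop("unknown threshold(s) for standard '", standard, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  th[names(dots)] <- dots
  if (standard == "npdxe" &&
      !(th$cr_best < th$pr_best && th$pr_best < th$sd_best)) {
    stop("thresholds must satisfy cr_best < pr_best < sd_best", call. = FALSE)
  }
  if (standard == "rc" && !(th$cr_pct < th$pr_pct && th$pr_pct < th$pd_pct)) {
    stop("thresholds must satisfy cr_pct < pr_pct < pd_pct", call. = FALSE)
  }
  structure(c(list(standard = standard), th), class = "response_thresholds")
}

check_trajectory <- function(days, volumes) {
  if (length(days) != length(volumes)) {
    stop("days and volumes must have the same length", call. = FALSE)
  }
  o <- order(days)
  days <- days[o]; volumes <- volumes[o]
  if (days[1L] != 0) stop("trajectory must start at day 0", call. = FALSE)
  if (is.na(volumes[1L]) || volumes[1L] <= 0) {
    stop("baseline volume must be positive", call. = FALSE)
  }
  list(days = days, volumes = volumes)
}

#' Percent tumor-volume change from baseline
#'
#' `100 * (V_t - V_0) / V_0` for every post-baseline day of one animal.
#'
#' @param days Measurement days, including 0.
#' @param volumes Volumes aligned to `days`; baseline must be positive.
#' @return A tibble `(day, delta_pct)` excluding day 0.
#' @export
delta_volume_pct <- function(days, volumes) {
  tr <- check_trajectory(days, volumes)
  keep <- tr$days > 0
  tibble::tibble(day = tr$days[keep],
                 delta_pct = 100 * (tr$volumes[keep] - tr$volumes[1L]) /
                   tr$volumes[1L])
}

#' Best response of one animal
#'
#' The minimum percent volume change from baseline over days at or after
#' `min_day` (the measurement-eligibility window of the NPDXE standard).
#'
#' @param days,volumes One animal's trajectory (day 0 first).
#' @param min_day First eligible day (inclusive), default 10.
#' @return The best (most negative) percent change, or `NA` when no day is
#'   eligible.
#' @export
best_response <- function(days, volumes, min_day = 10) {
  dv <- delta_volume_pct(days, volumes)
  dv <- dv[dv$day >= min_day, ]
  if (nrow(dv) == 0L) return(NA_real_)
  min(dv$delta_pct)
}

#' Best average response of one animal
#'
#' For every eligible day `t >= min_day`, the running mean of the percent
#' volume change over all post-baseline days up to and including `t`; the
#' minimum of those running means. Day 0 (whose change is identically zero)
#' is excluded from the average.
#'
#' @inheritParams best_response
#' @return The best (most negative) running-mean percent change, or `NA`
#'   when no day is eligible.
#' @export
best_avg_response <- function(days, volumes, min_day = 10) {
  dv <- delta_volume_pct(days, volumes)
  if (nrow(dv) == 0L) return(NA_real_)
  run_mean <- cumsum(dv$delta_pct) / seq_along(dv$delta_pct)
  eligible <- dv$day >= min_day
  if (!any(eligible)) return(NA_real_)
  min(run_mean[eligible])
}

#' Label one animal's drug response
#'
#' Applies one of the three labeling standards (see
#' [response_thresholds()]) to a single trajectory and returns the level
#' (`CR`, `PR`, `SD` or `PD`) together with the intermediate metrics. Under
#' `npdxe`, a trajectory that ends before the eligibility day cannot be
#' scored and is labeled PD with the note `"insufficient follow-up"`.
#'
#' @param days,volumes One animal's trajectory (day 0 first, positive
#'   baseline).
#' @param standard `"npdxe"`, `"pptp"` or `"rc"`.
#' @param thresholds A [response_thresholds()] object; defaults for the
#'   chosen standard when `NULL`.
#' @return A list `(standard, level, best_response, best_avg_response,
#'   metrics, note)`.
#' @export
label_response <- function(days, volumes,
                           standard = c("npdxe", "pptp", "rc"),
                           thresholds = NULL) {
  standard <- match.arg(standard)
  th <- thresholds %||% response_thresholds(standard)
  stopifnot(inherits(th, "response_thresholds"))
  if (th$standard != standard) {
    stop(sprintf("thresholds are for standard '%s', not '%s'", th$standard,
                 standard), call. = FALSE)
  }
  tr <- check_trajectory(days, volumes)
  dv <- delta_volume_pct(tr$days, tr$volumes)
  note <- NA_character_
  best <- NA_real_; best_avg <- NA_real_
  metrics <- list()
  if (standard == "npdxe") {
    best <- best_response(tr$days, tr$volumes, th$min_day)
    best_avg <- best_avg_response(tr$days, tr$volumes, th$min_day)
    if (is.na(best) || is.na(best_avg)) {
      level <- "PD"
      note <- "insufficient follow-up"
    } else if (best < th$cr_best && best_avg < th$cr_avg) {
      level <- "CR"
    } else if (best < th$pr_best && best_avg < th$pr_avg) {
      level <- "PR"
    } else if (best < th$sd_best && best_avg < th$sd_avg) {
      level <- "SD"
    } else {
      level <- "PD"
    }
  } else if (standard == "pptp") {
    rtv <- tr$volumes / tr$volumes[1L]
    metrics <- list(min_volume = min(tr$volumes),
                    min_rtv = min(rtv), end_rtv = rtv[length(rtv)])
    level <- if (min(tr$volumes) < th$measurable_mm3) {
      "CR"
    } else if (min(rtv) <= th$pr_rtv) {
      "PR"
    } else if (rtv[length(rtv)] > th$pd_rtv) {
      "PD"
    } else {
      "SD"
    }
  } else {
    end_pct <- dv$delta_pct[nrow(dv)]
    metrics <- list(end_delta_pct = end_pct)
    level <- if (end_pct <= th$cr_pct) {
      "CR"
    } else if (end_pct <= th$pr_pct) {
      "PR"
    } else if (end_pct >= th$pd_pct) {
      "PD"
    } else {
      "SD"
    }
  }
  list(standard = standard, level = level,
       best_response = best, best_avg_response = best_avg,
       end_delta_pct = if (nrow(dv) > 0L) dv$delta_pct[nrow(dv)] else NA_real_,
       metrics = metrics, note = note)
}

#' Label every animal of a trial
#'
#' Applies [label_response()] to each animal's trajectory.
#'
#' @param ds A [trial_dataset()].
#' @param standard `"npdxe"`, `"pptp"` or `"rc"`.
#' @param thresholds Optional [response_thresholds()].
#' @return A tibble `(tumor_id, arm, animal_id, standard, level,
#'   best_response, best_avg_response, end_delta_pct, note)`; `level` is a
#'   factor with levels CR, PR, SD, PD.
#' @export
label_responses <- function(ds, standard = c("npdxe", "pptp", "rc"),
                            thresholds = NULL) {
  standard <- match.arg(standard)
  stopifnot(inherits(ds, "trial_dataset"))
  tab <- as_tbl(ds) |> dplyr::filter(!is.na(.data$volume))
  out <- tab |>
    dplyr::group_by(.data$tumor_id, .data$arm, .data$animal_id) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      call <- label_response(d$day, d$volume, standard, thresholds)
      tibble::tibble(standard = call$standard, level = call$level,
                     best_response = call$best_response,
                     best_avg_response = call$best_avg_response,
                     end_delta_pct = call$end_delta_pct,
                     note = call$note)
    }) |>
    dplyr::ungroup()
  out$level <- factor(out$level, levels = .response_levels)
  out
}

#' Arm-level response indices
#'
#' Counts response levels within each (tumor, arm) and computes the
#' response rate `RR = (nCR + nPR) / n` and disease control rate
#' `DCR = (nCR + nPR + nSD) / n`.
#'
#' @param calls A tibble of per-animal calls from [label_responses()].
#' @return A tibble `(tumor_id, arm, n, n_cr, n_pr, n_sd, n_pd, rr, dcr,
#'   rr_pct, dcr_pct)` with the percentages rounded half-up to 2 decimals.
#' @export
arm_indices <- function(calls) {
  if (nrow(calls) == 0L) stop("no response calls", call. = FALSE)
  calls |>
    dplyr::group_by(.data$tumor_id, .data$arm) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_cr = sum(.data$level == "CR"),
      n_pr = sum(.data$level == "PR"),
      n_sd = sum(.data$level == "SD"),
      n_pd = sum(.data$level == "PD"),
      .groups = "drop") |>
    dplyr::mutate(
      rr = (.data$n_cr + .data$n_pr) / .data$n,
      dcr = (.data$n_cr + .data$n_pr + .data$n_sd) / .data$n,
      rr_pct = round_half_up(100 * .data$rr, 2L),
      dcr_pct = round_half_up(100 * .data$dcr, 2L))
}

# round-half-up (base round() uses banker's rounding)
round_half_up <- function(x, digits = 0L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Rank arms by response indices
#'
#' Stable descending sort of arm summaries by disease control rate then
#' response rate (or the reverse priority), with ties broken by arm name.
#'
#' @param summaries An [arm_indices()] tibble.
#' @param by `"dcr_then_rr"` (default) or `"rr_then_dcr"`.
#' @return The summaries, reordered.
#' @export
rank_arms <- function(summaries, by = c("dcr_then_rr", "rr_then_dcr")) {
  by <- match.arg(by)
  keys <- if (by == "dcr_then_rr") {
    list(-summaries$dcr, -summaries$rr)
  } else {
    list(-summaries$rr, -summaries$dcr)
  }
  summaries[order(keys[[1L]], keys[[2L]], summaries$arm), , drop = FALSE]
}
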