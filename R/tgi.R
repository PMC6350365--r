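# Tumor growth inhibition: TGI = (1 - F(V_T) / F(V_C)) * 100, where F
# reduces an arm's center (mean or median) volume curve to a scalar at each
# evaluation day.

#' Center volume series of one arm
#'
#' Per-day mean (or median) tumor volume over the animals of one arm
#' measured on that day.
#'
#' @param ds A [trial_dataset()].
#' @param tumor_id Tumor of interest.
#' @param arm Arm label.
#' @param center `"mean"` or `"median"`.
#' @return A tibble `(day, value, n)` ordered by day.
#' @export
arm_center_series <- function(ds, tumor_id, arm, center = c("mean", "median")) {
  stopifnot(inherits(ds, "trial_dataset"))
  center <- match.arg(center)
  fun <- if (center == "mean") mean else median
  tab <- as_tbl(ds)
  d <- tab[tab$tumor_id == tumor_id & tab$arm == arm & !is.na(tab$volume), ]
  if (nrow(d) == 0L) {
    stop(sprintf("no measurements for tumor '%s', arm '%s'", tumor_id, arm),
         call. = FALSE)
  }
  d |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(value = fun(.data$volume), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$day)
}

#' Trapezoidal area under a volume curve
#'
#' @param days Strictly increasing measurement days.
#' @param volumes Volumes aligned to `days`.
#' @return The trapezoidal integral from the first to the last day.
#' @export
auc_trapezoid <- function(days, volumes) {
  if (length(days) < 2L) stop("need at least 2 points", call. = FALSE)
  if (length(days) != length(volumes)) {
    stop("days and volumes must have the same length", call. = FALSE)
  }
  if (any(diff(days) <= 0)) stop("days must be strictly increasing", call. = FALSE)
  sum(diff(days) * (head(volumes, -1L) + volumes[-1L]) / 2)
}

#' Tumor growth inhibition per arm and day
#'
#' Computes `TGI = (1 - F(V_T) / F(V_C)) * 100` for each treatment arm
#' against the control, per evaluation day, for one or more choices of the
#' volume functional `F` evaluated on the arm's center curve:
#' `diff` is `V_t - V_0`, `ratio` is `V_t / V_0`, and `auc` is the
#' trapezoidal area under the center curve from day 0 to day t. Each
#' treatment arm is compared on the post-baseline days it shares with the
#' control. Days where the control functional is non-positive (a shrinking
#' control under `diff`/`auc`) are reported with `defined = FALSE` and the
#' note `"control not growing"` rather than a sign-flipped value; TGI above
#' 100% (regression below baseline) is reported as is.
#'
#' @param ds A [trial_dataset()].
#' @param control_arm Control arm; defaults to the dataset's control arm.
#' @param f_kind Character vector among `"diff"`, `"ratio"`, `"auc"`.
#' @param center `"mean"` or `"median"`.
#' @param at `"all_days"` or `"end"` (last shared day only).
#' @param tumor_ids Tumors to include; defaults to all.
#' @return A tibble `(tumor_id, arm, control_arm, f_kind, center, day,
#'   tgi_percent, defined, note)`.
#' @export
compute_tgi <- function(ds, control_arm = NULL,
                        f_kind = c("diff", "ratio", "auc"),
                        center = c("mean", "median"),
                        at = c("all_days", "end"),
                        tumor_ids = NULL) {
  stopifnot(inherits(ds, "trial_dataset"))
  f_kind <- match.arg(f_kind, several.ok = TRUE)
  center <- match.arg(center)
  at <- match.arg(at)
  ctrl <- control_arm %||% control_arm(ds)
  if (is.null(ctrl)) {
    stop("TGI needs a control arm; none set or detected", call. = FALSE)
  }
  tab <- as_tbl(ds)
  if (!ctrl %in% unique(tab$arm)) {
    stop(sprintf("control arm '%s' not present in data", ctrl), call. = FALSE)
  }
  tumor_ids <- tumor_ids %||% unique(tab$tumor_id)
  rows <- list()
  for (tid in tumor_ids) {
    arms_here <- unique(tab$arm[tab$tumor_id == tid])
    if (!ctrl %in% arms_here) {
      stop(sprintf("tumor '%s' has no control arm '%s'", tid, ctrl),
           call. = FALSE)
    }
    c_series <- arm_center_series(ds, tid, ctrl, center)
    if (!0 %in% c_series$day) {
      stop(sprintf("control arm of tumor '%s' has no day-0 baseline", tid),
           call. = FALSE)
    }
    for (arm in setdiff(arms_here, ctrl)) {
      t_series <- arm_center_series(ds, tid, arm, center)
      if (!0 %in% t_series$day) {
        stop(sprintf("arm '%s' of tumor '%s' has no day-0 baseline", arm, tid),
             call. = FALSE)
      }
      common <- sort(intersect(c_series$day, t_series$day))
      eval_days <- setdiff(common, 0)
      if (length(eval_days) == 0L) {
        stop(sprintf("arms '%s' and '%s' share no post-baseline days", arm, ctrl),
             call. = FALSE)
      }
      if (at == "end") eval_days <- max(eval_days)
      cs <- c_series[c_series$day %in% common, ]
      ts <- t_series[t_series$day %in% common, ]
      for (fk in f_kind) {
        f_c <- f_eval(cs$day, cs$value, eval_days, fk)
        f_t <- f_eval(ts$day, ts$value, eval_days, fk)
        bad <- if (fk == "ratio") f_c <= 0 else f_c <= 0
        tgi <- ifelse(bad, NA_real_, (1 - f_t / f_c) * 100)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          tumor_id = tid, arm = arm, control_arm = ctrl, f_kind = fk,
          center = center, day = eval_days, tgi_percent = tgi,
          defined = !bad,
          note = ifelse(bad, "control not growing", NA_character_))
      }
    }
  }
  dplyr::bind_rows(rows)
}

# F(day t) for a center curve (days include 0), vectorised over eval_days.
f_eval <- function(days, values, eval_days, f_kind) {
  v0 <- values[days == 0][1L]
  vt <- values[match(eval_days, days)]
  switch(f_kind,
    diff = vt - v0,
    ratio = vt / v0,
    auc = vapply(eval_days, function(t) {
      keep <- days <= t
      auc_trapezoid(days[keep], values[keep])
    }, numeric(1L))
  )
}
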