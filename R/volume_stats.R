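# Between-arm comparison of tumor volumes: endpoint tests on final volume or
# growth rate, rank tests, repeated-measures models, and the growth-curve
# permutation test.

new_test_result <- function(method, statistic = NA_real_, df = NA_real_,
                            p_value = NA_real_, terms = NULL, notes = character(0)) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, terms = terms, notes = notes),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s\n", x$method))
  if (!is.null(x$terms)) {
    print(x$terms, ...)
  } else {
    cat(sprintf("  statistic = %.6g, df = %s, p = %.4g\n", x$statistic,
                paste(signif(x$df, 6), collapse = ", "), x$p_value))
  }
  if (length(x$notes) > 0L) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Per-animal analysis endpoints
#'
#' Reduces each animal's trajectory to a single value for endpoint tests:
#' either the tumor volume at the last day shared by all animals of a tumor
#' (`end_volume`), or a growth rate (`growth_rate`). Growth rates come in
#' three flavours: `slope_log`, the least-squares slope of `ln(volume)`
#' against day (uses every timepoint; exact for exponential growth);
#' `ratio_log`, `ln(V_end / V_0) / (t_end - t_0)`; and `diff`,
#' `(V_end - V_0) / (t_end - t_0)` in mm^3 per day. Log-based rates exclude
#' animals with any non-positive volume, with a warning.
#'
#' @param ds A [trial_dataset()].
#' @param endpoint `"growth_rate"` (default) or `"end_volume"`.
#' @param growth_method `"slope_log"` (default), `"ratio_log"` or `"diff"`.
#' @return A tibble `(tumor_id, arm, animal_id, value)`.
#' @export
endpoint_values <- function(ds,
                            endpoint = c("growth_rate", "end_volume"),
                            growth_method = c("slope_log", "ratio_log", "diff")) {
  stopifnot(inherits(ds, "trial_dataset"))
  endpoint <- match.arg(endpoint)
  growth_method <- match.arg(growth_method)
  tab <- as_tbl(ds) |> dplyr::filter(!is.na(.data$volume))

  if (endpoint == "end_volume") {
    out <- tab |>
      dplyr::group_by(.data$tumor_id) |>
      dplyr::group_modify(function(d, key) {
        common <- Reduce(intersect, split(d$day, paste(d$arm, d$animal_id)))
        if (length(common) == 0L) return(d[0, c("arm", "animal_id", "volume")])
        last_day <- max(common)
        d |>
          dplyr::filter(.data$day == last_day) |>
          dplyr::select("arm", "animal_id", "volume")
      }) |>
      dplyr::ungroup() |>
      dplyr::rename(value = "volume")
    return(out[, c("tumor_id", "arm", "animal_id", "value")])
  }

  per_animal <- tab |>
    dplyr::group_by(.data$tumor_id, .data$arm, .data$animal_id) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      n_days = dplyr::n_distinct(.data$day),
      any_nonpos = any(.data$volume <= 0),
      value = growth_rate_one(.data$day, .data$volume, growth_method),
      .groups = "drop")
  too_few <- per_animal$n_days < 2L
  bad_log <- growth_method %in% c("slope_log", "ratio_log") & per_animal$any_nonpos
  if (any(too_few)) {
    warning(sprintf("%d animal(s) excluded (fewer than 2 timepoints)",
                    sum(too_few)), call. = FALSE)
  }
  if (any(bad_log & !too_few)) {
    warning(sprintf("%d animal(s) excluded (non-positive volume, log growth method)",
                    sum(bad_log & !too_few)), call. = FALSE)
  }
  per_animal |>
    dplyr::filter(!too_few, !bad_log) |>
    dplyr::select("tumor_id", "arm", "animal_id", "value")
}

growth_rate_one <- function(day, volume, method) {
  o <- order(day)
  day <- day[o]; volume <- volume[o]
  if (length(unique(day)) < 2L) return(NA_real_)
  switch(method,
    slope_log = {
      if (any(volume <= 0)) return(NA_real_)
      y <- log(volume)
      sum((day - mean(day)) * (y - mean(y))) / sum((day - mean(day))^2)
    },
    ratio_log = {
      if (any(volume <= 0)) return(NA_real_)
      log(volume[length(volume)] / volume[1L]) / (day[length(day)] - day[1L])
    },
    diff = (volume[length(volume)] - volume[1L]) / (day[length(day)] - day[1L])
  )
}

#' One-way between-arm test on an endpoint
#'
#' Fixed-effects one-way ANOVA (`parametric = TRUE`) or the Kruskal-Wallis
#' rank test on per-animal endpoint values grouped by arm. Kruskal-Wallis
#' uses mid-ranks and the usual tie correction; with all values identical it
#' returns `H = 0, p = 1`, whereas the parametric F is undefined and errors.
#'
#' @param values Numeric endpoint values.
#' @param arm Arm label per value.
#' @param parametric Use ANOVA (`TRUE`) or Kruskal-Wallis (`FALSE`).
#' @return A `test_result`.
#' @export
one_way_test <- function(values, arm, parametric = TRUE) {
  keep <- !is.na(values) & !is.na(arm)
  values <- values[keep]; arm <- factor(arm[keep])
  if (nlevels(arm) < 2L) stop("need at least 2 arms", call. = FALSE)
  if (parametric) {
    if (any(table(arm) < 2L)) {
      stop("parametric one-way test needs >= 2 values per arm", call. = FALSE)
    }
    if (var(values) == 0) {
      stop("all values identical: ANOVA F undefined (0/0)", call. = FALSE)
    }
    a <- anova(lm(values ~ arm))
    new_test_result("one-way ANOVA",
                    statistic = a$`F value`[1L],
                    df = c(a$Df[1L], a$Df[2L]),
                    p_value = a$`Pr(>F)`[1L])
  } else {
    notes <- character(0)
    if (any(table(arm) < 3L)) notes <- "some arm(s) have fewer than 3 values"
    if (var(values) == 0) {
      return(new_test_result("Kruskal-Wallis", statistic = 0,
                             df = nlevels(arm) - 1L, p_value = 1,
                             notes = c(notes, "all values tied")))
    }
    k <- kruskal.test(values, arm)
    new_test_result("Kruskal-Wallis",
                    statistic = unname(k$statistic),
                    df = unname(k$parameter),
                    p_value = k$p.value,
                    notes = notes)
  }
}

#' Scheirer-Ray-Hare rank test for two crossed factors
#'
#' Nonparametric two-way analysis on ranks: all observations are mid-ranked
#' together, two-way ANOVA sums of squares are computed on the ranks, and
#' each term's `H = SS_term / MS_total` with `MS_total = SS_total / (N - 1)`
#' is referred to a chi-square distribution on the term's usual degrees of
#' freedom. With a single-level second factor the first factor's `H`
#' collapses exactly to the tie-corrected Kruskal-Wallis statistic.
#'
#' @param values Numeric observations.
#' @param factor_a,factor_b The two crossed factors.
#' @return A `test_result` with a per-term table (`term`, `df`, `ss`, `h`,
#'   `p_value`).
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b) {
  keep <- !is.na(values)
  values <- values[keep]
  fa <- factor(factor_a[keep]); fb <- factor(factor_b[keep])
  n <- length(values)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (nlevels(fa) > 1L && nlevels(fb) > 1L &&
      any(table(fa, fb) == 0L)) {
    stop("empty cell(s) in the factor_a x factor_b grid", call. = FALSE)
  }
  r <- rank(values)
  ss_total <- sum((r - mean(r))^2)
  ms_total <- ss_total / (n - 1)
  if (ms_total == 0) {
    terms <- tibble::tibble(
      term = c("factor_a", "factor_b", "factor_a:factor_b"),
      df = c(nlevels(fa) - 1L, nlevels(fb) - 1L,
             (nlevels(fa) - 1L) * (nlevels(fb) - 1L)),
      ss = 0, h = 0, p_value = 1)
    return(new_test_result("Scheirer-Ray-Hare", terms = terms,
                           notes = "all values tied"))
  }
  if (nlevels(fb) == 1L || nlevels(fa) == 1L) {
    f1 <- if (nlevels(fb) == 1L) fa else fb
    nm <- if (nlevels(fb) == 1L) "factor_a" else "factor_b"
    ss_a <- sum(tapply(r, f1, function(g) length(g) * (mean(g) - mean(r))^2))
    h <- ss_a / ms_total
    df <- nlevels(f1) - 1L
    terms <- tibble::tibble(term = nm, df = df, ss = ss_a, h = h,
                            p_value = pchisq(h, df, lower.tail = FALSE))
    return(new_test_result("Scheirer-Ray-Hare", terms = terms,
                           notes = "second factor has a single level; equals Kruskal-Wallis"))
  }
  a <- anova(lm(r ~ fa * fb))
  rows <- c("fa", "fb", "fa:fb")
  terms <- tibble::tibble(
    term = c("factor_a", "factor_b", "factor_a:factor_b"),
    df = a[rows, "Df"],
    ss = a[rows, "Sum Sq"],
    h = a[rows, "Sum Sq"] / ms_total,
    p_value = pchisq(a[rows, "Sum Sq"] / ms_total, a[rows, "Df"],
                     lower.tail = FALSE))
  new_test_result("Scheirer-Ray-Hare", terms = terms)
}

#' Mixed-design (split-plot) ANOVA on repeated tumor volumes
#'
#' Treats arm as the between-subject factor and measurement day as the
#' within-subject factor, with animals as subjects. The design is restricted
#' to the days common to every included animal of the tumor; the arm effect
#' is tested against subjects-within-arm, day and the arm-by-day interaction
#' against the day-by-subject residual. Greenhouse-Geisser corrected
#' p-values for the within-subject terms are reported alongside the
#' sphericity-assuming ones.
#'
#' @param ds A [trial_dataset()].
#' @param tumor_id Tumor to analyse; defaults to the only tumor present.
#' @return A `test_result` with a per-term table (`term`, `df1`, `df2`,
#'   `statistic`, `p_value`, `p_gg`).
#' @export
mixed_anova <- function(ds, tumor_id = NULL) {
  d <- single_tumor(ds, tumor_id)
  common <- Reduce(intersect, split(d$day, paste(d$arm, d$animal_id)))
  if (length(common) < 2L) {
    stop("fewer than 2 measurement days common to all animals", call. = FALSE)
  }
  d <- d[d$day %in% common, ]
  n_per_arm <- table(unique(d[, c("arm", "animal_id")])$arm)
  if (any(n_per_arm < 2L)) {
    stop("every arm needs >= 2 animals for a mixed-design ANOVA", call. = FALSE)
  }
  d$arm <- factor(d$arm)
  d$fday <- factor(d$day)
  d$subject <- factor(paste(d$arm, d$animal_id, sep = "\r"))
  fit <- aov(volume ~ arm * fday + Error(subject), data = d)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1L]]
  within <- s[["Error: Within"]][[1L]]
  rn <- function(tab) trimws(rownames(tab))
  b_i <- match("arm", rn(between))
  w_day <- match("fday", rn(within))
  w_int <- match("arm:fday", rn(within))
  w_res <- match("Residuals", rn(within))
  eps <- gg_epsilon(d)
  gg_p <- function(f, df1, df2) pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
  terms <- tibble::tibble(
    term = c("arm", "day", "arm:day"),
    df1 = c(between$Df[b_i], within$Df[w_day], within$Df[w_int]),
    df2 = c(between$Df[match("Residuals", rn(between))],
            within$Df[w_res], within$Df[w_res]),
    statistic = c(between$`F value`[b_i], within$`F value`[w_day],
                  within$`F value`[w_int]),
    p_value = c(between$`Pr(>F)`[b_i], within$`Pr(>F)`[w_day],
                within$`Pr(>F)`[w_int]))
  # a term whose sum of squares is numerically nil (e.g. identical arms) has
  # F = 0/0 in floating point; report it as no effect
  ss <- c(between$`Sum Sq`[b_i], within$`Sum Sq`[w_day], within$`Sum Sq`[w_int])
  ss_total <- sum(between$`Sum Sq`, within$`Sum Sq`)
  nil <- ss <= 1e-10 * ss_total
  terms$statistic[nil] <- 0
  terms$p_value[nil] <- 1
  terms$p_gg <- c(NA_real_,
                  gg_p(terms$statistic[2L], terms$df1[2L], terms$df2[2L]),
                  gg_p(terms$statistic[3L], terms$df1[3L], terms$df2[3L]))
  new_test_result("mixed-design ANOVA", terms = terms,
                  notes = sprintf("Greenhouse-Geisser epsilon = %.4f; %d common day(s)",
                                  eps, length(common)))
}

# Greenhouse-Geisser epsilon from the pooled within-arm covariance of the
# subject-by-day response matrix, via orthonormal contrasts.
gg_epsilon <- function(d) {
  wide <- tidyr::pivot_wider(d[, c("subject", "arm", "fday", "volume")],
                             names_from = "fday", values_from = "volume")
  m <- as.matrix(wide[, setdiff(names(wide), c("subject", "arm"))])
  grp <- wide$arm
  centered <- m - apply(m, 2L, function(col) tapply(col, grp, mean))[grp, , drop = FALSE]
  s_mat <- crossprod(centered) / (nrow(m) - length(unique(grp)))
  k <- ncol(m)
  cm <- stats::contr.helmert(k)
  cm <- sweep(cm, 2L, sqrt(colSums(cm^2)), "/")
  a <- t(cm) %*% s_mat %*% cm
  tr <- sum(diag(a))
  if (sum(a^2) == 0) return(1)
  min(1, (tr^2) / ((k - 1) * sum(a^2)))
}

single_tumor <- function(ds, tumor_id) {
  stopifnot(inherits(ds, "trial_dataset"))
  tab <- as_tbl(ds) |> dplyr::filter(!is.na(.data$volume))
  tumors <- unique(tab$tumor_id)
  if (is.null(tumor_id)) {
    if (length(tumors) > 1L) {
      stop("multiple tumors present; specify tumor_id", call. = FALSE)
    }
    tumor_id <- tumors
  }
  if (!tumor_id %in% tumors) {
    stop(sprintf("tumor '%s' not present in data", tumor_id), call. = FALSE)
  }
  d <- tab[tab$tumor_id == tumor_id, ]
  attr(d, "control_arm") <- control_arm(ds)
  d
}

#' Linear mixed model for longitudinal tumor volumes
#'
#' Fits `lme4::lmer` with fixed effects for day, arm and their interaction
#' (the vehicle arm as reference level) and a per-animal random intercept,
#' optionally with a random day slope. The default response scale is
#' `ln(volume + 1)`, so the day-by-arm coefficients are differences in
#' per-day log growth versus vehicle. Contrasts are summarised by Wald z
#' statistics; the omnibus p-value for all arm terms comes from a
#' likelihood-ratio test of ML refits with and without them. A singular
#' random-slope fit is automatically downgraded to a random intercept, with
#' a note.
#'
#' @param ds A [trial_dataset()].
#' @param tumor_id Tumor to analyse; defaults to the only tumor present.
#' @param response_scale `"log"` (default) or `"raw"`.
#' @param random `"intercept_slope"` (default) or `"intercept"`.
#' @return A `test_result` whose `terms` table lists every fixed effect
#'   (`term`, `estimate`, `se`, `statistic` = Wald z, `p_value`);
#'   `p_value` on the result is the omnibus arm p-value, and the fitted
#'   model is attached as attribute `"fit"`.
#' @export
fit_lmm <- function(ds, tumor_id = NULL,
                    response_scale = c("log", "raw"),
                    random = c("intercept_slope", "intercept")) {
  response_scale <- match.arg(response_scale)
  random <- match.arg(random)
  d <- single_tumor(ds, tumor_id)
  ctrl <- attr(d, "control_arm")
  if (length(unique(d$arm)) < 2L) stop("need at least 2 arms", call. = FALSE)
  d$y <- if (response_scale == "log") log(d$volume + 1) else d$volume
  d$arm <- factor(d$arm)
  if (!is.null(ctrl) && ctrl %in% levels(d$arm)) {
    d$arm <- stats::relevel(d$arm, ref = ctrl)
  }
  d$subject <- factor(paste(d$arm, d$animal_id, sep = "\r"))
  notes <- character(0)
  if (length(unique(d$day)) < 3L) {
    notes <- c(notes, "fewer than 3 timepoints; slope terms weakly identified")
  }
  form <- if (random == "intercept_slope") {
    y ~ day * arm + (1 + day | subject)
  } else {
    y ~ day * arm + (1 | subject)
  }
  fit <- suppressMessages(lme4::lmer(form, data = d, REML = TRUE))
  if (random == "intercept_slope" && lme4::isSingular(fit, tol = 1e-4)) {
    fit <- suppressMessages(lme4::lmer(y ~ day * arm + (1 | subject),
                                       data = d, REML = TRUE))
    notes <- c(notes, "singular random-slope fit; downgraded to random intercept")
  }
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$code) && conv$code != 0) {
    stop("linear mixed model did not converge: ",
         paste(unlist(conv$messages), collapse = "; "), call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  terms <- tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    se = cf[, "Std. Error"],
    statistic = cf[, "Estimate"] / cf[, "Std. Error"])
  terms$p_value <- 2 * pnorm(-abs(terms$statistic))
  # omnibus LRT for every term involving arm, on ML fits
  full_ml <- suppressMessages(stats::update(fit, REML = FALSE))
  red_form <- if (random == "intercept_slope" &&
                  !any(grepl("downgraded", notes))) {
    y ~ day + (1 + day | subject)
  } else {
    y ~ day + (1 | subject)
  }
  red_ml <- suppressMessages(lme4::lmer(red_form, data = d, REML = FALSE))
  lr <- 2 * (as.numeric(logLik(full_ml)) - as.numeric(logLik(red_ml)))
  df_lr <- attr(logLik(full_ml), "df") - attr(logLik(red_ml), "df")
  res <- new_test_result("linear mixed model",
                         statistic = lr, df = df_lr,
                         p_value = pchisq(lr, df_lr, lower.tail = FALSE),
                         terms = terms, notes = notes)
  attr(res, "fit") <- fit
  res
}

#' Growth-curve permutation test between arm pairs
#'
#' For each pair of arms, computes a per-day two-sample statistic (pooled-
#' variance t, or a tie-corrected rank-sum z for `stat = "mean_wilcox"`) on
#' the days shared by every animal of the pair, averages it over days into a
#' summary `S`, and permutes whole animals between the two arms. The p-value
#' is the proportion of permutations with `|S_perm| >= |S_obs|`. When the
#' number of distinct label assignments is at most `exhaustive_limit`, every
#' assignment is enumerated and the p-value is exact; otherwise `n_perm`
#' random reassignments are drawn. Days where both groups have zero
#' within-group variance are skipped with a note. Pairwise p-values are
#' adjusted across all pairs.
#'
#' @param ds A [trial_dataset()].
#' @param tumor_id Tumor to analyse; defaults to the only tumor present.
#' @param stat `"mean_t"` (default) or `"mean_wilcox"`.
#' @param n_perm Number of random permutations in Monte-Carlo mode.
#' @param seed Integer seed for reproducibility (optional).
#' @param adjust Multiplicity adjustment across pairs: `"holm"` (default),
#'   `"bonferroni"` or `"BH"`.
#' @param exhaustive_limit Enumerate exhaustively when the number of
#'   distinct assignments does not exceed this.
#' @return A `pairwise_result`: a tibble `(tumor_id, arm_a, arm_b,
#'   statistic, n_days, mode, n_assignments, p_raw, p_adjusted)` with
#'   attributes `n_perm`, `seed`, `adjust_method`, `stat`.
#' @export
permutation_curve_test <- function(ds, tumor_id = NULL,
                                   stat = c("mean_t", "mean_wilcox"),
                                   n_perm = 1000L, seed = NULL,
                                   adjust = c("holm", "bonferroni", "BH"),
                                   exhaustive_limit = 20000L) {
  stat <- match.arg(stat)
  adjust <- match.arg(adjust)
  d <- single_tumor(ds, tumor_id)
  if (!is.null(seed)) set.seed(seed)
  arms <- sort(unique(d$arm))
  if (length(arms) < 2L) stop("need at least 2 arms", call. = FALSE)
  pairs <- utils::combn(arms, 2L)
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    rows[[j]] <- perm_pair(d, pairs[1L, j], pairs[2L, j], stat, n_perm,
                           exhaustive_limit)
  }
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- adjust_pvalues(out$p_raw, adjust)
  structure(out, n_perm = n_perm, seed = seed, adjust_method = adjust,
            stat = stat,
            class = c("pairwise_result", class(tibble::tibble())))
}

perm_pair <- function(d, arm_a, arm_b, stat, n_perm, exhaustive_limit) {
  dd <- d[d$arm %in% c(arm_a, arm_b), ]
  dd$.animal <- paste(dd$arm, dd$animal_id, sep = "\r")
  common <- Reduce(intersect, split(dd$day, dd$.animal))
  if (length(common) == 0L) {
    stop(sprintf("arms '%s' and '%s' share no measurement days", arm_a, arm_b),
         call. = FALSE)
  }
  dd <- dd[dd$day %in% common, ]
  wide <- tidyr::pivot_wider(dd[, c(".animal", "arm", "day", "volume")],
                             names_from = "day", values_from = "volume")
  x <- as.matrix(wide[, setdiff(names(wide), c(".animal", "arm"))])
  in_a <- wide$arm == arm_a
  n1 <- sum(in_a); n2 <- sum(!in_a); n <- n1 + n2
  if (n1 < 2L || n2 < 2L) {
    stop(sprintf("arms '%s'/'%s' need >= 2 animals each", arm_a, arm_b),
         call. = FALSE)
  }
  if (stat == "mean_wilcox") {
    # per-day mid-ranks are label-free, so the rank matrix is permuted as-is
    r <- apply(x, 2L, rank)
    ties_var <- apply(x, 2L, function(col) {
      tt <- table(col)
      n1 * n2 / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
    })
    usable <- ties_var > 0
    note <- if (!all(usable)) {
      sprintf("%d day(s) skipped (all values tied)", sum(!usable))
    } else NA_character_
    if (!any(usable)) stop("all days skipped (no variation)", call. = FALSE)
    r <- r[, usable, drop = FALSE]
    n_days_used <- ncol(r)
    mu <- n1 * (n + 1) / 2
    sdv <- sqrt(ties_var[usable])
    stat_fun <- function(g_mat) {
      w <- crossprod(r, g_mat)                       # days x perms rank sums
      colMeans((w - mu) / sdv)
    }
  } else {
    # pooled-variance t per day, vectorised over label assignments
    x2 <- x^2
    tot <- colSums(x); tot2 <- colSums(x2)
    stat_fun <- function(g_mat) {
      s1 <- crossprod(x, g_mat)                      # days x perms group-A sums
      q1 <- crossprod(x2, g_mat)
      s2 <- tot - s1; q2 <- tot2 - q1
      pooled <- (q1 - s1^2 / n1 + q2 - s2^2 / n2) / (n - 2)
      diff <- s1 / n1 - s2 / n2
      tt <- diff / sqrt(pmax(pooled, 0) * (1 / n1 + 1 / n2))
      tt[pooled <= 0 & diff == 0] <- 0               # degenerate day: no signal
      colMeans(tt)
    }
    n_days_used <- ncol(x)
  }
  g_obs <- matrix(as.numeric(in_a), ncol = 1L)
  if (stat == "mean_t") {
    # days degenerate in the observed data are dropped up front
    pooled_obs_ok <- {
      s1 <- crossprod(x, g_obs); q1 <- crossprod(x^2, g_obs)
      s2 <- colSums(x) - s1; q2 <- colSums(x^2) - q1
      drop((q1 - s1^2 / n1 + q2 - s2^2 / n2) / (n - 2)) > 0
    }
    if (!any(pooled_obs_ok)) stop("all days skipped (no within-group variance)",
                                  call. = FALSE)
    note <- if (!all(pooled_obs_ok)) {
      sprintf("%d day(s) skipped (zero within-group variance)",
              sum(!pooled_obs_ok))
    } else NA_character_
    if (!all(pooled_obs_ok)) {
      x <- x[, pooled_obs_ok, drop = FALSE]
      x2 <- x^2
      tot <- colSums(x); tot2 <- colSums(x2)
      stat_fun <- local({
        x <- x; x2 <- x2; tot <- tot; tot2 <- tot2
        function(g_mat) {
          s1 <- crossprod(x, g_mat); q1 <- crossprod(x2, g_mat)
          s2 <- tot - s1; q2 <- tot2 - q1
          pooled <- (q1 - s1^2 / n1 + q2 - s2^2 / n2) / (n - 2)
          diff <- s1 / n1 - s2 / n2
          tt <- diff / sqrt(pmax(pooled, 0) * (1 / n1 + 1 / n2))
          tt[pooled <= 0 & diff == 0] <- 0
          colMeans(tt)
        }
      })
      n_days_used <- ncol(x)
    }
  }
  s_obs <- stat_fun(g_obs)
  n_assign <- choose(n, n1)
  if (n_assign <= exhaustive_limit) {
    idx <- utils::combn(n, n1)
    g_all <- matrix(0, nrow = n, ncol = ncol(idx))
    g_all[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n1))] <- 1
    s_all <- stat_fun(g_all)
    p_raw <- mean(abs(s_all) >= abs(s_obs) - 1e-12)
    mode <- "exhaustive"
    n_used <- ncol(idx)
  } else {
    g_mc <- matrix(0, nrow = n, ncol = n_perm)
    picks <- vapply(seq_len(n_perm), function(i) sample.int(n, n1),
                    integer(n1))
    g_mc[cbind(as.vector(picks), rep(seq_len(n_perm), each = n1))] <- 1
    s_mc <- stat_fun(g_mc)
    p_raw <- mean(abs(s_mc) >= abs(s_obs) - 1e-12)
    mode <- "monte-carlo"
    n_used <- n_perm
  }
  tibble::tibble(tumor_id = d$tumor_id[1L], arm_a = arm_a, arm_b = arm_b,
                 statistic = as.numeric(s_obs),
                 n_days = n_days_used, mode = mode, n_assignments = n_used,
                 p_raw = p_raw, note = note)
}

#' Adjust p-values for multiple comparisons
#'
#' Thin, validating wrapper around [stats::p.adjust()] for the adjustment
#' methods used across arm pairs. The mapping back to input positions is
#' order-preserving.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param method `"holm"`, `"bonferroni"` or `"BH"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bonferroni", "BH")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = method)
}
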