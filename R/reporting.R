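# Figures (ggplot2) and the top-level per-pattern analysis pipeline.

.level_colors <- c(CR = "#1a9850", PR = "#91cf60", SD = "#bdbdbd",
                   PD = "#d73027")

save_figure <- function(p, out, width = 7, height = 4.5) {
  if (!is.null(out)) {
    ggplot2::ggsave(out, plot = p, width = width, height = height)
  }
  p
}

#' Arm-level growth curves (center +/- SEM)
#'
#' One line per arm of the per-day center volume, with SEM whiskers where
#' at least two animals were measured.
#'
#' @param summaries A tibble from [summarize_arms()].
#' @param out Optional output path (format from the extension).
#' @return The ggplot object, invisibly saved to `out` when given.
#' @export
plot_growth_curves <- function(summaries, out = NULL) {
  p <- ggplot2::ggplot(summaries,
                       ggplot2::aes(x = .data$day, y = .data$center,
                                    color = .data$arm, group = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::geom_errorbar(
      data = summaries[!is.na(summaries$sem), ],
      ggplot2::aes(ymin = .data$center - .data$sem,
                   ymax = .data$center + .data$sem),
      width = 0.6) +
    ggplot2::labs(x = "Days post T0", y = "Tumor volume (mm^3)",
                  color = "Arm") +
    ggplot2::theme_bw()
  if (length(unique(summaries$tumor_id)) > 1L) {
    p <- p + ggplot2::facet_wrap(~tumor_id)
  }
  save_figure(p, out)
}

#' Animal-level growth curves
#'
#' Spaghetti plot of every animal's volume trajectory, colored by arm.
#'
#' @param ds A [trial_dataset()].
#' @param out Optional output path.
#' @return The ggplot object.
#' @export
plot_animal_curves <- function(ds, out = NULL) {
  tab <- as_tbl(ds) |> dplyr::filter(!is.na(.data$volume))
  p <- ggplot2::ggplot(tab,
                       ggplot2::aes(x = .data$day, y = .data$volume,
                                    group = interaction(.data$tumor_id,
                                                        .data$arm,
                                                        .data$animal_id),
                                    color = .data$arm)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "Days post T0", y = "Tumor volume (mm^3)",
                  color = "Arm") +
    ggplot2::theme_bw()
  if (length(unique(tab$tumor_id)) > 1L) {
    p <- p + ggplot2::facet_wrap(~tumor_id)
  }
  save_figure(p, out)
}

#' TGI over time per arm
#'
#' Lines of tumor growth inhibition against day, one per arm, faceted by
#' the F functional when more than one was computed. Undefined rows
#' (non-growing control) are not drawn.
#'
#' @param series A tibble from [compute_tgi()].
#' @param out Optional output path.
#' @return The ggplot object.
#' @export
plot_tgi_series <- function(series, out = NULL) {
  d <- series[series$defined, ]
  p <- ggplot2::ggplot(d,
                       ggplot2::aes(x = .data$day, y = .data$tgi_percent,
                                    color = .data$arm, group = .data$arm)) +
    ggplot2::geom_hline(yintercept = c(0, 100), linetype = "dotted",
                        color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "Days post T0", y = "TGI (%)", color = "Arm") +
    ggplot2::theme_bw()
  facets <- c(if (length(unique(d$tumor_id)) > 1L) "tumor_id",
              if (length(unique(d$f_kind)) > 1L) "f_kind")
  if (length(facets) > 0L) {
    p <- p + ggplot2::facet_wrap(facets)
  }
  save_figure(p, out)
}

#' Stacked response-level counts per arm
#'
#' Bar chart of CR/PR/SD/PD counts per arm, arms ordered by [rank_arms()].
#'
#' @param summaries An [arm_indices()] tibble.
#' @param calls The matching per-animal calls from [label_responses()].
#' @param out Optional output path.
#' @return The ggplot object.
#' @export
plot_response_bar <- function(summaries, calls, out = NULL) {
  ranked <- rank_arms(summaries)
  counts <- calls |>
    dplyr::count(.data$tumor_id, .data$arm, .data$level, .drop = FALSE)
  counts$arm <- factor(counts$arm, levels = unique(ranked$arm))
  p <- ggplot2::ggplot(counts,
                       ggplot2::aes(x = .data$arm, y = .data$n,
                                    fill = .data$level)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = .level_colors, drop = FALSE) +
    ggplot2::labs(x = "Arm", y = "Animals", fill = "Level") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (length(unique(counts$tumor_id)) > 1L) {
    p <- p + ggplot2::facet_wrap(~tumor_id)
  }
  save_figure(p, out)
}

#' Waterfall plot of per-animal response
#'
#' One bar per animal, sorted descending by the chosen metric and colored
#' by response level; ties are broken by animal id.
#'
#' @param calls Per-animal calls from [label_responses()].
#' @param metric `"best_avg_response"` (NPDXE) or `"end_delta_pct"`.
#' @param out Optional output path.
#' @return The ggplot object.
#' @export
plot_waterfall <- function(calls,
                           metric = c("best_avg_response", "end_delta_pct"),
                           out = NULL) {
  metric <- match.arg(metric)
  if (nrow(calls) == 0L) stop("no response calls to plot", call. = FALSE)
  d <- calls
  d$.metric <- d[[metric]]
  d <- d[order(-d$.metric, d$animal_id), ]
  d$.pos <- factor(seq_len(nrow(d)))
  ylab <- if (metric == "best_avg_response") {
    "Best average response (% from baseline)"
  } else {
    "Volume change at last day (% from baseline)"
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$.pos, y = .data$.metric,
                                       fill = .data$level)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = .level_colors, drop = FALSE) +
    ggplot2::labs(x = "Animal", y = ylab, fill = "Level") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
  save_figure(p, out)
}

#' Run the per-pattern analysis pipeline
#'
#' Validates the dataset, infers (or accepts) the trial-design pattern and
#' routes the analyses accordingly: `1AN` and `TAN` get between-arm
#' statistics, TGI and response labeling (per tumor for `TAN`); `T1N` gets
#' TGI and labeling; `TA1`, with a single animal per arm, gets labeling and
#' arm rankings only. Tables are written as TSV, figures as PDF, and a JSON
#' manifest names every artifact produced.
#'
#' @param ds A [trial_dataset()].
#' @param out_dir Output directory (created if needed).
#' @param pattern `"auto"` (default) or an explicit pattern code.
#' @param standard Response-labeling standard, default `"npdxe"`.
#' @param center `"mean"` or `"median"` for TGI and arm summaries.
#' @param f_kind TGI functionals to compute.
#' @param methods Between-arm test methods to run among `"anova"`, `"kw"`,
#'   `"mixed"`, `"lmm"`, `"perm"`; `NULL` runs all (where the pattern
#'   allows statistics).
#' @param n_perm,seed Permutation-test settings.
#' @return Invisibly, a list with the result tables, figure paths and the
#'   manifest path.
#' @export
run_pipeline <- function(ds, out_dir, pattern = "auto",
                         standard = c("npdxe", "pptp", "rc"),
                         center = c("mean", "median"),
                         f_kind = c("diff", "ratio", "auc"),
                         methods = NULL,
                         n_perm = 1000L, seed = 1L) {
  standard <- match.arg(standard)
  center <- match.arg(center)
  stopifnot(inherits(ds, "trial_dataset"))
  report <- validate_trial(ds)
  if (!is_valid(report)) {
    stop("dataset has fatal validation issues; see validate_trial()",
         call. = FALSE)
  }
  pat <- if (identical(pattern, "auto")) {
    infer_pattern(ds)$code
  } else {
    match.arg(pattern, c("1AN", "T1N", "TA1", "TAN"))
  }
  if (pat == "TAN" && length(unique(as_tbl(ds)$tumor_id)) > 1L) {
    # one bundle per tumor: each tumor is analysed like a 1AN trial
    tumors <- unique(as_tbl(ds)$tumor_id)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    sub_results <- list()
    files <- character(0)
    for (tid in tumors) {
      tab <- as_tbl(ds)
      sub <- trial_dataset(tab[tab$tumor_id == tid, ],
                           control_arm = intersect_control(
                             tab[tab$tumor_id == tid, ], ds),
                           meta = attr(ds, "meta"))
      res <- run_pipeline(sub, file.path(out_dir, tid), pattern = "1AN",
                          standard = standard, center = center,
                          f_kind = f_kind, methods = methods,
                          n_perm = n_perm, seed = seed)
      sub_results[[tid]] <- res
      files <- c(files, res$files)
    }
    manifest <- file.path(out_dir, "summary.json")
    jsonlite::write_json(
      list(pattern = pat, standard = standard, center = center,
           tumors = tumors,
           bundles = file.path(tumors, "summary.json")),
      manifest, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(list(pattern = pat, tumors = sub_results,
                          manifest = manifest,
                          files = c(files, manifest))))
  }
  all_methods <- c("anova", "kw", "mixed", "lmm", "perm")
  if (is.null(methods)) {
    methods <- if (pat %in% c("1AN", "TAN")) all_methods else character(0)
  } else {
    methods <- match.arg(methods, all_methods, several.ok = TRUE)
    if (pat %in% c("TA1", "T1N") && length(methods) > 0L) {
      stop(sprintf("between-arm statistics require >= 2 animals per arm per tumor; pattern %s does not support them",
                   pat), call. = FALSE)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  add_tsv <- function(tab, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(tab, path, progress = FALSE)
    files <<- c(files, path)
    path
  }
  add_fig <- function(p, name) {
    path <- file.path(out_dir, name)
    suppressMessages(ggplot2::ggsave(path, plot = p, width = 7, height = 4.5))
    files <<- c(files, path)
    path
  }
  results <- list(pattern = pat)

  summaries <- summarize_arms(ds, center)
  add_tsv(summaries, "arm_summaries.tsv")
  add_fig(plot_growth_curves(summaries), "growth_curves.pdf")
  add_fig(plot_animal_curves(ds), "animal_curves.pdf")
  results$summaries <- summaries

  tumors <- unique(as_tbl(ds)$tumor_id)
  if (length(methods) > 0L) {
    stats_rows <- list()
    for (tid in tumors) {
      ev <- endpoint_values(ds, "growth_rate", "slope_log")
      ev <- ev[ev$tumor_id == tid, ]
      if ("anova" %in% methods) {
        r <- one_way_test(ev$value, ev$arm, parametric = TRUE)
        stats_rows[[length(stats_rows) + 1L]] <- tibble::tibble(
          tumor_id = tid, method = r$method, term = "arm",
          statistic = r$statistic, p_value = r$p_value)
      }
      if ("kw" %in% methods) {
        r <- one_way_test(ev$value, ev$arm, parametric = FALSE)
        stats_rows[[length(stats_rows) + 1L]] <- tibble::tibble(
          tumor_id = tid, method = r$method, term = "arm",
          statistic = r$statistic, p_value = r$p_value)
      }
      if ("mixed" %in% methods) {
        r <- mixed_anova(ds, tid)
        stats_rows[[length(stats_rows) + 1L]] <- tibble::tibble(
          tumor_id = tid, method = r$method, term = r$terms$term,
          statistic = r$terms$statistic, p_value = r$terms$p_value)
      }
      if ("lmm" %in% methods) {
        r <- fit_lmm(ds, tid)
        stats_rows[[length(stats_rows) + 1L]] <- tibble::tibble(
          tumor_id = tid, method = r$method, term = "arm (omnibus)",
          statistic = r$statistic, p_value = r$p_value)
      }
      if ("perm" %in% methods) {
        r <- permutation_curve_test(ds, tid, n_perm = n_perm, seed = seed)
        stats_rows[[length(stats_rows) + 1L]] <- tibble::tibble(
          tumor_id = tid, method = "permutation",
          term = paste(r$arm_a, "vs", r$arm_b),
          statistic = r$statistic, p_value = r$p_adjusted)
      }
    }
    results$stats <- dplyr::bind_rows(stats_rows)
    add_tsv(results$stats, "stats.tsv")
  }

  if (pat %in% c("1AN", "T1N", "TAN")) {
    tgi <- compute_tgi(ds, f_kind = f_kind, center = center)
    results$tgi <- tgi
    add_tsv(tgi, "tgi.tsv")
    add_fig(plot_tgi_series(tgi), "tgi_series.pdf")
  }

  calls <- label_responses(ds, standard)
  indices <- arm_indices(calls)
  ranked <- rank_arms(indices)
  results$calls <- calls
  results$indices <- ranked
  add_tsv(calls, "calls.tsv")
  add_tsv(ranked, "arm_indices.tsv")
  add_fig(plot_response_bar(indices, calls), "response_bar.pdf")
  wf_metric <- if (standard == "npdxe") "best_avg_response" else "end_delta_pct"
  add_fig(plot_waterfall(calls, wf_metric), "waterfall.pdf")

  manifest <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(pattern = pat, standard = standard, center = center,
         n_tumors = length(tumors),
         files = basename(files)),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  results$files <- c(files, manifest)
  invisible(results)
}
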