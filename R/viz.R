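# Figures are built as "figure + lossless companion table": every plot
# function returns an ipddta_figure holding the ggplot object and the data
# frame(s) of computed coordinates, so rendering can be tested numerically
# and every export has a CSV twin.

new_figure <- function(plot, data, name) {
  structure(list(plot = plot, data = data, name = name),
            class = "ipddta_figure")
}

#' @export
print.ipddta_figure <- function(x, ...) {
  print(x$plot)
  invisible(x)
}

#' Save a figure and its companion table
#'
#' @param fig An `ipddta_figure`.
#' @param file Output path without extension.
#' @param formats Any of `"pdf"`, `"png"`, `"svg"` for the figure; the
#'   companion table is always written as `<file>.csv`.
#' @param width,height Device size in inches.
#' @return Character vector of files written, invisibly.
#' @export
save_figure <- function(fig, file, formats = "pdf", width = 8, height = 6) {
  written <- character(0)
  for (fmt in formats) {
    out <- paste0(file, ".", fmt)
    ggplot2::ggsave(out, fig$plot, width = width, height = height,
                    device = fmt)
    written <- c(written, out)
  }
  if (is.data.frame(fig$data)) {
    csv <- paste0(file, ".csv")
    write.csv(fig$data, csv, row.names = FALSE)
    written <- c(written, csv)
  } else {
    # composite figures carry several companion tables
    for (nm in names(fig$data)) {
      csv <- paste0(file, "_", nm, ".csv")
      write.csv(fig$data[[nm]], csv, row.names = FALSE)
      written <- c(written, csv)
    }
  }
  invisible(written)
}

#' Forest plot
#'
#' Generic forest plot: one row per study with a point estimate sized by
#' weight and CI whiskers, optionally followed by pooled diamonds (e.g. the
#' fixed-effect and random-effects summaries). Rows are displayed in the
#' order given, top to bottom.
#'
#' @param rows Data frame with `label`, `estimate`, `ci_low`, `ci_high`
#'   and optional `weight`.
#' @param pooled Optional data frame with the same columns for summary
#'   rows (drawn as diamonds).
#' @param xlab Axis label.
#' @return An `ipddta_figure`; `$data` binds the study and pooled rows with
#'   a `row_type` column.
#' @export
plot_forest <- function(rows, pooled = NULL, xlab = "Estimate") {
  if (is.null(rows) || nrow(rows) == 0) {
    ipd_abort("forest plot needs at least one row", "ipddta_empty_error")
  }
  if (is.null(rows$weight)) rows$weight <- 1
  rows$row_type <- "study"
  tab <- rows[, c("label", "estimate", "ci_low", "ci_high", "weight", "row_type")]
  if (!is.null(pooled) && nrow(pooled)) {
    pooled$weight <- NA
    pooled$row_type <- "pooled"
    tab <- rbind(tab, pooled[, names(tab)])
  }
  tab$y <- rev(seq_len(nrow(tab)))
  p <- ggplot(tab, aes(x = .data$estimate, y = .data$y)) +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2, linewidth = 0.4) +
    geom_point(data = tab[tab$row_type == "study", ],
               aes(size = .data$weight), shape = 15, show.legend = FALSE) +
    scale_y_continuous(breaks = tab$y, labels = tab$label) +
    scale_size_area(max_size = 4) +
    labs(x = xlab, y = NULL) +
    theme_minimal()
  if (any(tab$row_type == "pooled")) {
    p <- p + geom_point(data = tab[tab$row_type == "pooled", ],
                        shape = 18, size = 4)
  }
  new_figure(p, tab, "forest")
}

#' Paired forest plots of sensitivity and specificity
#'
#' Side-by-side forest panels for the per-study sensitivities and
#' specificities of a dichotomized analysis.
#'
#' @param panel Data frame from [accuracy_panel()] applied per study (must
#'   contain `study_id`, `sens`, `sens_low`, `sens_high`, `spec`,
#'   `spec_low`, `spec_high`).
#' @return An `ipddta_figure` with a faceted plot; `$data` is the long
#'   table of both panels.
#' @export
plot_forest_sesp <- function(panel) {
  long <- rbind(
    data.frame(label = paste("Study", panel$study_id), measure = "Sensitivity",
               estimate = panel$sens, ci_low = panel$sens_low,
               ci_high = panel$sens_high),
    data.frame(label = paste("Study", panel$study_id), measure = "Specificity",
               estimate = panel$spec, ci_low = panel$spec_low,
               ci_high = panel$spec_high))
  long$y <- rev(as.integer(factor(long$label, levels = unique(long$label))))
  p <- ggplot(long, aes(x = .data$estimate, y = .data$y)) +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2, linewidth = 0.4) +
    geom_point(shape = 15, size = 2) +
    facet_wrap(~measure) +
    scale_y_continuous(breaks = unique(long$y),
                       labels = unique(long$label)) +
    coord_cartesian(xlim = c(0, 1)) +
    labs(x = NULL, y = NULL) +
    theme_minimal()
  new_figure(p, long, "forest_sesp")
}

#' Ridgeline plot of a numeric variable by study and disease group
#'
#' Staggered kernel density curves (one ridge per study, filled by disease
#' group) of the index test or a continuous covariate. Densities use a
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth and are scaled
#' to a common ridge height. A panel with fewer than two distinct values is
#' drawn as a spike at the observed value, with a warning.
#'
#' @param data An `ipd_dataset`.
#' @param variable `"test_result"` or the name of a continuous covariate.
#' @return An `ipddta_figure`; `$data` has `study_id`, `group`, `x`,
#'   `density` (the unscaled density) and `y` (the staggered ordinate).
#' @export
plot_ridgeline <- function(data, variable = "test_result") {
  v <- data[[variable]]
  if (is.null(v)) ipd_abort(sprintf("unknown variable '%s'", variable),
                            "ipddta_lookup_error")
  if (!is.numeric(v)) {
    ipd_abort(sprintf("variable '%s' is not numeric", variable), "ipddta_type_error")
  }
  ids <- sort(unique(data$study_id))
  rows <- list(); degenerate <- FALSE
  for (i in ids) for (g in c(0, 1)) {
    x <- v[data$study_id == i & data$disease == g]
    x <- x[!is.na(x)]
    if (!length(x)) next
    if (length(unique(x)) < 2) {
      degenerate <- TRUE
      rows[[length(rows) + 1]] <- data.frame(
        study_id = i, group = ifelse(g == 1, "diseased", "nondiseased"),
        x = unique(x)[1], density = 1)
      next
    }
    d <- density(x, bw = "nrd0", kernel = "gaussian")
    rows[[length(rows) + 1]] <- data.frame(
      study_id = i, group = ifelse(g == 1, "diseased", "nondiseased"),
      x = d$x, density = d$y)
  }
  if (degenerate) {
    ipd_warn("a study/group panel had a constant value; drawn as a spike",
             "ipddta_degenerate_density_warning")
  }
  tab <- do.call(rbind, rows)
  scale <- 0.9 / max(tab$density)
  tab$y <- tab$study_id + tab$density * scale
  p <- ggplot(tab, aes(x = .data$x, group = interaction(.data$study_id, .data$group))) +
    geom_ribbon(aes(ymin = .data$study_id, ymax = .data$y, fill = .data$group),
                alpha = 0.55, colour = "grey30", linewidth = 0.2) +
    scale_y_continuous(breaks = ids, labels = paste("Study", ids)) +
    labs(x = variable, y = NULL, fill = NULL) +
    theme_minimal()
  new_figure(p, tab, paste0("ridgeline_", variable))
}

#' Empirical ROC curves of all studies in one plot
#'
#' @param data An `ipd_dataset`.
#' @return An `ipddta_figure`; `$data` stacks the per-study step-function
#'   coordinates from [roc_points()].
#' @export
plot_roc_by_study <- function(data) {
  ids <- analyzable_studies(data)
  if (!length(ids)) ipd_abort("no analyzable study", "ipddta_empty_error")
  tab <- do.call(rbind, lapply(ids, function(i) {
    v <- test_by_class(data, i)
    cbind(study_id = i, roc_points(v$diseased, v$nondiseased))
  }))
  tab$study <- paste("Study", tab$study_id)
  p <- ggplot(tab, aes(x = .data$fpr, y = .data$tpr, colour = .data$study)) +
    geom_step(direction = "hv") +
    geom_abline(slope = 1, intercept = 0, linetype = 3, colour = "grey50") +
    coord_equal() +
    labs(x = "1 - Specificity", y = "Sensitivity", colour = NULL) +
    theme_minimal()
  new_figure(p, tab, "roc_by_study")
}

#' Pooled scatter of test result against a covariate with per-study fits
#'
#' @param data An `ipd_dataset`.
#' @param covariate Name of a continuous covariate.
#' @param fits Data frame from [per_study_regressions()]; studies absent
#'   from `fits` (skipped upstream) draw no line.
#' @return An `ipddta_figure`; `$data` is a list with `points` and `lines`
#'   (fitted segments clipped to each study's covariate range).
#' @export
plot_scatter_fits <- function(data, covariate, fits) {
  types <- covariate_types(data)
  if (!covariate %in% names(types) || types[[covariate]] != "continuous") {
    ipd_abort(sprintf("'%s' is not a continuous covariate", covariate),
              "ipddta_type_error")
  }
  if (!all(fits$study_id %in% data$study_id)) {
    ipd_abort("fits reference studies absent from the data", "ipddta_consistency_error")
  }
  pts <- data.frame(study_id = data$study_id, x = data[[covariate]],
                    y = data$test_result)
  pts <- pts[!is.na(pts$x) & !is.na(pts$y), ]
  lines <- do.call(rbind, lapply(seq_len(nrow(fits)), function(j) {
    f <- fits[j, ]
    xr <- range(pts$x[pts$study_id == f$study_id])
    data.frame(study_id = f$study_id, x_start = xr[1], x_end = xr[2],
               y_start = f$intercept + f$slope * xr[1],
               y_end = f$intercept + f$slope * xr[2])
  }))
  pts$study <- paste("Study", pts$study_id)
  lines$study <- paste("Study", lines$study_id)
  p <- ggplot(pts, aes(colour = .data$study)) +
    geom_point(aes(x = .data$x, y = .data$y), alpha = 0.4, size = 0.8) +
    geom_segment(data = lines,
                 aes(x = .data$x_start, xend = .data$x_end,
                     y = .data$y_start, yend = .data$y_end),
                 linewidth = 0.7) +
    labs(x = covariate, y = "test result", colour = NULL) +
    theme_minimal()
  new_figure(p, list(points = pts, lines = lines), "scatter_fits")
}

#' Stacked bar chart of a categorical covariate by study and disease group
#'
#' Two bars per study (diseased, nondiseased), each stacked to 100% across
#' covariate levels; level order is held fixed across studies.
#'
#' @param dist A `covariate_distribution` of categorical type (see
#'   [covariate_distributions()]).
#' @return An `ipddta_figure`; `$data` is the level percentage table.
#' @export
plot_stacked_bar <- function(dist) {
  if (!inherits(dist, "covariate_distribution") || dist$type != "categorical") {
    ipd_abort("stacked bar chart requires a categorical covariate summary",
              "ipddta_type_error")
  }
  tab <- dist$summary
  tab$level <- factor(tab$level, levels = sort(unique(tab$level)))
  p <- ggplot(tab, aes(x = .data$group, y = .data$pct, fill = .data$level)) +
    geom_col(position = "stack") +
    facet_wrap(~study_id, labeller = function(l) lapply(l, function(v) paste("Study", v))) +
    labs(x = NULL, y = "%", fill = dist$covariate) +
    theme_minimal()
  new_figure(p, tab, paste0("stacked_bar_", dist$covariate))
}

#' Summary ROC plot
#'
#' Composes the dichotomized meta-analysis display: per-study points in ROC
#' space scaled by sample size, the summary operating point with its
#' confidence region, and the summary ROC curve (clipped to the observed
#' FPR range by default).
#'
#' @param b A `bivariate_fit`.
#' @param tables The per-study 2x2 tables used in the fit.
#' @param level Confidence level of the region.
#' @param full_range Draw the curve over (0,1) instead of the observed FPR
#'   range.
#' @return An `ipddta_figure`; `$data` is a list with `points`, `curve`,
#'   `region`, `summary`.
#' @export
plot_sroc <- function(b, tables, level = 0.95, full_range = FALSE) {
  pts <- data.frame(
    study_id = tables$study_id,
    fpr = tables$FP / (tables$FP + tables$TN),
    tpr = tables$TP / (tables$TP + tables$FN),
    n = tables$TP + tables$FN + tables$FP + tables$TN)
  h <- bivariate_to_hsroc(b)
  rng <- if (full_range) c(0, 1) else range(pts$fpr)
  if (diff(rng) < 1e-6) rng <- c(max(0, rng[1] - 0.05), min(1, rng[2] + 0.05))
  curve <- sroc_curve(h, fpr_range = rng)
  sp <- summary_point(b, level = level)
  p <- ggplot(pts, aes(x = .data$fpr, y = .data$tpr)) +
    geom_point(aes(size = .data$n), shape = 1, show.legend = FALSE) +
    geom_path(data = curve, linewidth = 0.8) +
    geom_path(data = sp$region, linetype = 2, colour = "grey40") +
    annotate("point", x = sp$fpr, y = sp$tpr, shape = 18, size = 4) +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "1 - Specificity", y = "Sensitivity") +
    theme_minimal()
  new_figure(p, list(points = pts, curve = curve,
                     region = sp$region[, c("fpr", "tpr")],
                     summary = data.frame(fpr = sp$fpr, tpr = sp$tpr)),
             "sroc")
}
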