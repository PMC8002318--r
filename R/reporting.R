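#' Main-effects table of a designed experiment
#'
#' For each varied factor, averages the observed and predicted response
#' over the runs at each factor level (unweighted means over the runs at
#' that level). Factors with a single distinct value are skipped with a
#' message. Continuous factors with many distinct values (more than
#' `max_levels`) are binned into `bins` equal-width intervals and reported
#' at the bin midpoints, so randomly sampled designs can be summarized the
#' same way as gridded ones.
#'
#' @param table An [experiment_table()] with the observed response.
#' @param predictions Output of [predict_table()] for the same runs.
#' @param factors Character vector of factor columns to analyze.
#' @param response `"mrt"` or `"varnorm"`.
#' @param max_levels,bins Binning control for continuous factors.
#' @return A data.frame of class `main_effects_table` with columns
#'   `factor`, `level`, `n`, `mean_obs`, `mean_pred`.
#' @export
main_effects <- function(table, predictions,
                         factors = c("fr_kg_h", "rpm", "ls_pct", "nk", "sa_deg"),
                         response = c("mrt", "varnorm"),
                         max_levels = 10, bins = 4) {
  response <- match.arg(response)
  obs <- if (response == "mrt") table$mrt_s else table$varnorm
  pred_col <- if (response == "mrt") "mrt_pred_s" else "varnorm_pred"
  pred <- predictions[[pred_col]][match(table$run_id, predictions$run_id)]
  keep <- !is.na(obs) & !is.na(pred)
  rows <- list()
  for (f in factors) {
    if (!f %in% names(table)) next
    x <- table[[f]][keep]
    if (length(unique(x)) < 2) {
      message("main_effects: factor ", f, " has a single level; skipped")
      next
    }
    if (length(unique(x)) > max_levels) {
      brk <- seq(min(x), max(x), length.out = bins + 1)
      bin <- cut(x, brk, include.lowest = TRUE)
      lev <- (brk[-1] + brk[-length(brk)]) / 2
      x <- lev[as.integer(bin)]
    }
    agg <- stats::aggregate(cbind(obs = obs[keep], pred = pred[keep]),
                            by = list(level = x), FUN = mean)
    cnt <- as.vector(table(factor(x, levels = agg$level)))
    rows[[f]] <- data.frame(factor = f, level = agg$level, n = cnt,
                            mean_obs = agg$obs, mean_pred = agg$pred,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("main_effects_table", "data.frame")
  out
}

#' Plot a main-effects table
#'
#' Observed versus predicted level means per factor, one panel per factor
#' (the numbers plotted are exactly the rows of the table; the table is the
#' source of truth).
#'
#' @param me A [main_effects()] table.
#' @return A ggplot object.
#' @export
plot_main_effects <- function(me) {
  df <- rbind(
    data.frame(factor = me$factor, level = me$level, value = me$mean_obs,
               series = "observed"),
    data.frame(factor = me$factor, level = me$level, value = me$mean_pred,
               series = "predicted")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~factor, scales = "free_x") +
    ggplot2::labs(x = "factor level", y = "mean response", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write a parity report to disk
#'
#' Writes the per-run parity records (observed, predicted, band, in-band
#' flag, partition label) as CSV, the summary statistics (RMSE and in-band
#' fraction per metric) as JSON, and a parity scatter figure with the Y=X
#' line and the Y=X±band envelope. The CSV contains exactly the numbers the
#' figure shows.
#'
#' @param evaluation An [evaluate_fit()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
parity_report <- function(evaluation, dir, prefix = "parity") {
  stopifnot(inherits(evaluation, "rtd_evaluation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv_path <- file.path(dir, paste0(prefix, ".csv"))
  json_path <- file.path(dir, paste0(prefix, "_summary.json"))
  png_path <- file.path(dir, paste0(prefix, ".png"))
  utils::write.csv(evaluation$parity, csv_path, row.names = FALSE)
  jsonlite::write_json(list(mrt_rmse = evaluation$mrt_rmse,
                            varnorm_rmse = evaluation$varnorm_rmse,
                            in_band = as.list(evaluation$in_band)),
                       json_path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  p <- plot_parity(evaluation)
  grDevices::png(png_path, width = 800, height = 400)
  print(p)
  grDevices::dev.off()
  invisible(c(csv = csv_path, summary = json_path, figure = png_path))
}

#' Parity scatter plot
#'
#' Observed (x) versus predicted (y) responses with the identity line and
#' the ± band envelope, one panel per metric, points coloured by partition.
#'
#' @param evaluation An [evaluate_fit()] result.
#' @return A ggplot object.
#' @export
plot_parity <- function(evaluation) {
  df <- evaluation$parity
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                   colour = .data$partition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(ggplot2::aes(slope = 1, intercept = .data$band),
                         data = unique(df[, c("metric", "band")]),
                         linetype = "dashed") +
    ggplot2::geom_abline(ggplot2::aes(slope = 1, intercept = -.data$band),
                         data = unique(df[, c("metric", "band")]),
                         linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "observed", y = "predicted", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Reciprocal trend of the MRT scale constant against liquid content
#'
#' Fits the saturation-like relationship between the fitted MRT scale `b1`
#' and the dataset-averaged liquid-to-solid percentage by ordinary least
#' squares on the reciprocal scale: `1/b1 = intercept + slope * (1/LS)`.
#' With exactly two points the fit is exact (R-squared 1 by construction).
#'
#' @param b1 Fitted scale constants, one per dataset (> 0).
#' @param ls_avg_pct Number-averaged liquid-to-solid percentages (> 0).
#' @return A list of class `reciprocal_trend`: `slope`, `intercept`,
#'   `r_squared`, and the `points` data.frame (`inv_ls`, `inv_b1`).
#' @export
reciprocal_b1_trend <- function(b1, ls_avg_pct) {
  if (length(b1) != length(ls_avg_pct) || length(b1) < 2) {
    stop("need at least 2 paired (b1, LS) points", call. = FALSE)
  }
  if (any(b1 <= 0) || any(ls_avg_pct <= 0)) {
    stop("b1 and LS averages must be > 0", call. = FALSE)
  }
  pts <- data.frame(inv_ls = 1 / ls_avg_pct, inv_b1 = 1 / b1)
  fit <- stats::lm(inv_b1 ~ inv_ls, data = pts)
  ss_tot <- sum((pts$inv_b1 - mean(pts$inv_b1))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 points = pts),
            class = "reciprocal_trend")
}

#' @export
print.reciprocal_trend <- function(x, ...) {
  cat("Reciprocal trend 1/b1 = ", signif(x$intercept, 5), " + ",
      signif(x$slope, 5), " * (1/LS);  R^2 = ", signif(x$r_squared, 5),
      "\n", sep = "")
  invisible(x)
}
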