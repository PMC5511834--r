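#' Screen physiological indicators by Pearson correlation with treatment level
#'
#' Correlates each indicator (criterion column) against the ordered numeric
#' treatment levels (e.g. NaCl concentration in mM, or treatment days) and
#' flags the indicators whose linear association is significant. Growth
#' indicators typically fall with salinity (negative r) while antioxidant
#' enzyme activities rise (positive r); both directions count as informative.
#'
#' @param panel decision matrix of indicator measurements
#'   (alternatives x criteria).
#' @param levels numeric treatment values, one per alternative, strictly
#'   ordered.
#' @param alpha selection threshold on the two-sided p-value (default 0.05).
#' @return a data frame of class `"correlation_report"` with one row per
#'   indicator: `indicator`, Pearson `r`, two-sided `p` (t approximation,
#'   m - 2 df), significance `tier` (`"**"` p < 0.01, `"*"` p < 0.05, else
#'   `""`), logical `selected`, and logical `degenerate` marking
#'   zero-variance indicators whose correlation is undefined (reported as
#'   `NA`, never silently 0).
#' @examples
#' panel <- decision_matrix(cbind(height = c(12, 9, 7, 5),
#'                                POD = c(40, 60, 85, 120)))
#' pearson_screen(panel, levels = c(0, 50, 100, 150))
#' @export
pearson_screen <- function(panel, levels, alpha = 0.05) {
  panel <- as.matrix(panel)
  if (length(levels) != nrow(panel))
    stop("need one treatment level per alternative")
  if (is.unsorted(levels, strictly = TRUE) && is.unsorted(rev(levels), strictly = TRUE))
    stop("treatment levels must be strictly ordered")
  if (nrow(panel) < 3L)
    stop("need at least 3 levels for a correlation p-value")
  res <- lapply(seq_len(ncol(panel)), function(j) {
    y <- panel[, j]
    if (stats::sd(y) == 0) {
      data.frame(indicator = colnames(panel)[j], r = NA_real_, p = NA_real_,
                 tier = "", selected = FALSE, degenerate = TRUE)
    } else {
      ct <- stats::cor.test(levels, y, method = "pearson",
                            alternative = "two.sided")
      p <- ct$p.value
      data.frame(indicator = colnames(panel)[j], r = unname(ct$estimate),
                 p = p,
                 tier = if (p < 0.01) "**" else if (p < alpha) "*" else "",
                 selected = p < alpha, degenerate = FALSE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("correlation_report", "data.frame")
  out
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Indicator screen (Pearson correlation vs. treatment level)\n")
  df <- as.data.frame(x)
  df$r <- round_half_up(df$r, 3)
  df$p <- signif(df$p, 3)
  print.data.frame(df, ...)
  invisible(x)
}

#' Evaluate treatment conditions: indicator screen plus TOPSIS ranking
#'
#' The full condition-selection stage: screen the indicator panel by Pearson
#' correlation against the treatment levels, infer (or accept) criterion
#' orientations, and rank the treatment conditions by TOPSIS relative
#' closeness. With monotone stress-response indicators and any positive
#' weight vector, the strongest-response condition ranks first.
#'
#' @param panel indicator [decision_matrix()] (conditions x indicators).
#' @param levels numeric treatment values, one per condition.
#' @param weights criterion weights summing to 1; default equal `1/n`.
#' @param orientations `"auto"` (default) infers benefit/cost from the sign
#'   of each indicator's Pearson correlation with the treatment level
#'   (positive r = benefit, negative r = cost); or a character vector of
#'   `"benefit"`/`"cost"` per criterion.
#' @param alpha significance threshold for the screen (default 0.05).
#' @return list of class `"condition_eval"` with components `topsis` (the
#'   [topsis()] fit), `screen` (the [pearson_screen()] report) and `table`
#'   (report-layout data frame: Alternative, d_plus, d_minus, R, Rank).
#' @examples
#' truth <- indicator_truth(noise_sd = 0)
#' panel <- gen_indicator_panel(truth)
#' ev <- evaluate_conditions(panel, levels = truth$levels)
#' ev$table
#' @export
evaluate_conditions <- function(panel, levels, weights = NULL,
                                orientations = "auto", alpha = 0.05) {
  screen <- pearson_screen(panel, levels, alpha = alpha)
  if (identical(orientations, "auto")) {
    if (anyNA(screen$r))
      stop("cannot infer orientation for zero-variance indicators: ",
           paste(screen$indicator[is.na(screen$r)], collapse = ", "),
           "; supply orientations explicitly")
    orientations <- ifelse(screen$r >= 0, "benefit", "cost")
  }
  fit <- topsis(panel, orientations = orientations, weights = weights)
  structure(list(topsis = fit, screen = screen, table = as.data.frame(fit)),
            class = "condition_eval")
}

#' @export
print.condition_eval <- function(x, ...) {
  print(x$screen)
  cat("\n")
  print(x$topsis)
  invisible(x)
}
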