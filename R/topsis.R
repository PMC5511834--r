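#' Construct a decision matrix for multi-criteria evaluation
#'
#' A decision matrix holds the rating \eqn{x_{ij}} of each alternative
#' \eqn{A_i} (row) on each criterion \eqn{C_j} (column), in the criterion's
#' native units. It is the input to [topsis()] and to the indicator screen
#' [pearson_screen()].
#'
#' @param x numeric matrix (or object coercible to one) of positive, finite
#'   ratings; rows are alternatives, columns are criteria.
#' @param alternatives optional character vector of row labels.
#' @param criteria optional character vector of column labels.
#' @return a numeric matrix of class `"decision_matrix"`.
#' @examples
#' dm <- decision_matrix(rbind(c(10, 50), c(8, 80), c(5, 120)),
#'                       alternatives = c("0 mM", "100 mM", "200 mM"),
#'                       criteria = c("height_cm", "POD_U_per_g"))
#' @export
decision_matrix <- function(x, alternatives = rownames(x), criteria = colnames(x)) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L) stop("a decision matrix needs at least 2 alternatives")
  if (ncol(x) < 1L) stop("a decision matrix needs at least 1 criterion")
  if (anyNA(x) || any(!is.finite(x))) stop("ratings must be finite with no missing cells")
  if (any(x <= 0)) stop("ratings must be strictly positive in criterion-native units")
  if (is.null(alternatives)) alternatives <- paste0("A", seq_len(nrow(x)))
  if (is.null(criteria)) criteria <- paste0("C", seq_len(ncol(x)))
  dimnames(x) <- list(alternatives, criteria)
  class(x) <- c("decision_matrix", "matrix", "array")
  x
}

#' Vector-normalize a decision matrix
#'
#' Scales each criterion column to unit Euclidean norm:
#' \deqn{r_{ij} = x_{ij} / \sqrt{\sum_i x_{ij}^2}}
#' so that criteria measured in different units become comparable.
#'
#' @param x numeric matrix of ratings (alternatives x criteria).
#' @return matrix of normalized ratings with unit-norm columns.
#' @examples
#' topsis_normalize(cbind(c(3, 4)))  # the 3-4-5 triangle: 0.6, 0.8
#' @export
topsis_normalize <- function(x) {
  x <- unclass(as.matrix(x))
  norms <- sqrt(colSums(x^2))
  if (any(norms == 0)) stop("cannot normalize an all-zero criterion column")
  sweep(x, 2L, norms, "/")
}

#' Apply criterion weights to a normalized decision matrix
#'
#' Computes the weighted normalized ratings \eqn{v_{ij} = w_j r_{ij}}.
#' Weights must sum to 1.
#'
#' @param r normalized ratings from [topsis_normalize()].
#' @param weights numeric vector of criterion weights, one per column,
#'   summing to 1 (tolerance 1e-8).
#' @return matrix of weighted normalized ratings.
#' @export
topsis_weight <- function(r, weights) {
  r <- as.matrix(r)
  if (length(weights) != ncol(r))
    stop("need one weight per criterion")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("criterion weights must sum to 1")
  sweep(r, 2L, weights, "*")
}

#' Positive and negative ideal solutions
#'
#' For each criterion, the positive ideal solution A+ takes the best weighted
#' value across alternatives and the negative ideal A- the worst; "best" is
#' the maximum for a benefit criterion and the minimum for a cost criterion.
#'
#' @param v weighted normalized ratings from [topsis_weight()].
#' @param orientations character vector, one of `"benefit"` or `"cost"` per
#'   criterion.
#' @return list with numeric vectors `pos` (A+) and `neg` (A-).
#' @export
ideal_solutions <- function(v, orientations) {
  v <- as.matrix(v)
  orientations <- match.arg(orientations, c("benefit", "cost"), several.ok = TRUE)
  if (length(orientations) == 1L) orientations <- rep(orientations, ncol(v))
  if (length(orientations) != ncol(v))
    stop("need an orientation for every criterion")
  hi <- apply(v, 2L, max)
  lo <- apply(v, 2L, min)
  cost <- orientations == "cost"
  pos <- ifelse(cost, lo, hi)
  neg <- ifelse(cost, hi, lo)
  names(pos) <- names(neg) <- colnames(v)
  list(pos = pos, neg = neg)
}

#' Euclidean separation from the ideal solutions
#'
#' Distance of each alternative's weighted profile from the positive and
#' negative ideal solutions:
#' \deqn{d_i^\pm = \sqrt{\sum_j (v_{ij} - A_j^\pm)^2}}
#'
#' @param v weighted normalized ratings.
#' @param ideals list with components `pos` and `neg` from [ideal_solutions()].
#' @return list with numeric vectors `d_pos` and `d_neg`, one entry per
#'   alternative.
#' @export
separations <- function(v, ideals) {
  v <- as.matrix(v)
  d_pos <- sqrt(rowSums(sweep(v, 2L, ideals$pos, "-")^2))
  d_neg <- sqrt(rowSums(sweep(v, 2L, ideals$neg, "-")^2))
  list(d_pos = d_pos, d_neg = d_neg)
}

#' Relative closeness to the ideal solution
#'
#' \deqn{R = d^- / (d^+ + d^-)} for each alternative; R = 1 means the
#' alternative coincides with the positive ideal, R = 0 with the negative
#' ideal.
#'
#' @param d_pos,d_neg non-negative separation measures from [separations()]
#'   (or taken from a published table).
#' @return numeric vector of closeness values in \[0, 1\].
#' @examples
#' closeness(0.2262, 1.4237)  # 0.8629 to 4 dp
#' @export
closeness <- function(d_pos, d_neg) {
  if (length(d_pos) != length(d_neg))
    stop("d_pos and d_neg must have the same length")
  if (any(d_pos < 0) || any(d_neg < 0)) stop("separations must be non-negative")
  tot <- d_pos + d_neg
  if (any(tot == 0))
    stop("d+ and d- are both zero: alternatives are indistinguishable, ranking is meaningless")
  d_neg / tot
}

#' Rank alternatives by relative closeness
#'
#' Rank 1 goes to the largest closeness value. Ties are broken by the smaller
#' positive separation d+ (closer to the ideal wins), then by input order, so
#' the ranking is deterministic.
#'
#' @param R numeric closeness values.
#' @param d_pos optional positive separations used for tie-breaking.
#' @return integer ranks, a permutation of `1:length(R)`.
#' @examples
#' rank_alternatives(c(0, 0.1786, 0.3813, 0.461, 0.8629, 0.784))
#' @export
rank_alternatives <- function(R, d_pos = NULL) {
  if (is.null(d_pos)) d_pos <- rep(0, length(R))
  ord <- order(-R, d_pos, seq_along(R))
  rk <- integer(length(R))
  rk[ord] <- seq_along(R)
  rk
}

#' TOPSIS ranking of treatment alternatives
#'
#' Fits the Technique for Order Preference by Similarity to Ideal Solution
#' to a decision matrix: vector-normalize each criterion, apply weights,
#' locate the positive/negative ideal solutions, measure each alternative's
#' Euclidean separation from both, and rank by relative closeness
#' \eqn{R = d^-/(d^+ + d^-)}.
#'
#' @param x a [decision_matrix()] or plain numeric matrix
#'   (alternatives x criteria).
#' @param orientations `"benefit"` (larger is better) or `"cost"` (smaller is
#'   better), one per criterion (recycled if length 1).
#' @param weights criterion weights summing to 1; `NULL` (default) uses equal
#'   weights `1/n`.
#' @return an object of class `"topsis"`: a list with the normalized and
#'   weighted matrices, ideal solutions, separations `d_pos`/`d_neg`,
#'   `closeness`, and `rank`.
#' @seealso [evaluate_conditions()] for the full screen-then-rank stage,
#'   [closeness()], [rank_alternatives()].
#' @examples
#' dm <- decision_matrix(rbind(c(12, 40), c(9, 80), c(5, 130)),
#'                       alternatives = c("0 mM", "100 mM", "200 mM"),
#'                       criteria = c("height", "POD"))
#' fit <- topsis(dm, orientations = c("cost", "benefit"))
#' fit$rank
#' @export
topsis <- function(x, orientations, weights = NULL) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(orientations) == 1L) orientations <- rep(orientations, n)
  r <- topsis_normalize(x)
  v <- topsis_weight(r, weights)
  ideals <- ideal_solutions(v, orientations)
  sep <- separations(v, ideals)
  R <- closeness(sep$d_pos, sep$d_neg)
  rk <- rank_alternatives(R, sep$d_pos)
  alts <- rownames(x)
  if (is.null(alts)) alts <- paste0("A", seq_len(nrow(x)))
  names(R) <- names(rk) <- names(sep$d_pos) <- names(sep$d_neg) <- alts
  structure(list(
    ratings = x, normalized = r, weighted = v,
    weights = stats::setNames(weights, colnames(x)),
    orientations = stats::setNames(orientations, colnames(x)),
    ideal_pos = ideals$pos, ideal_neg = ideals$neg,
    d_pos = sep$d_pos, d_neg = sep$d_neg,
    closeness = R, rank = rk
  ), class = "topsis")
}

#' @export
print.topsis <- function(x, digits = 4, ...) {
  cat("TOPSIS ranking of", length(x$closeness), "alternatives on",
      ncol(x$ratings), "criteria\n\n")
  print(as.data.frame(x), digits = digits)
  invisible(x)
}

#' @export
summary.topsis <- function(object, ...) {
  structure(list(fit = object), class = "summary.topsis")
}

#' @export
print.summary.topsis <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nCriterion weights and orientations:\n")
  print(data.frame(weight = fit$weights, orientation = fit$orientations))
  cat("\nPositive ideal solution (A+):\n")
  print(round_half_up(fit$ideal_pos, 4))
  cat("Negative ideal solution (A-):\n")
  print(round_half_up(fit$ideal_neg, 4))
  invisible(x)
}

#' Tabulate a TOPSIS fit in report layout
#'
#' @param x a `"topsis"` object.
#' @param row.names,optional,... passed on conventions of [as.data.frame()];
#'   unused.
#' @return data frame with columns `Alternative`, `d_plus`, `d_minus`, `R`,
#'   `Rank`, separations and closeness rounded half-up to 4 decimal places
#'   for display (the fitted object keeps full precision).
#' @export
as.data.frame.topsis <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    Alternative = names(x$closeness),
    d_plus = round_half_up(x$d_pos, 4),
    d_minus = round_half_up(x$d_neg, 4),
    R = round_half_up(x$closeness, 4),
    Rank = x$rank,
    row.names = NULL
  )
}

#' @export
plot.topsis <- function(x, ...) {
  ord <- order(x$rank)
  graphics::barplot(x$closeness[ord], names.arg = names(x$closeness)[ord],
                    ylab = "relative closeness R", las = 2,
                    main = "TOPSIS relative closeness", ...)
  invisible(x)
}
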