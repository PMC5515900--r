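#' F-score feature ranking
#'
#' Scores every feature by the one-way ANOVA F statistic — the ratio of
#' between-class to within-class variance of that feature across trials —
#' and attaches the upper-tail p-value from the F distribution with
#' `(1, n - 2)` degrees of freedom (two classes). Features with high F
#' separate the class distributions well; the p-value gives the usual
#' significance reading used for topographic interpretation.
#'
#' Degenerate features are kept rankable and deterministic: zero
#' within-class variance with nonzero between-class separation scores the
#' largest finite double with `p = 0`; a completely constant feature scores
#' `F = 0` with `p = 1`. Ties in F break by feature order.
#'
#' @param X Trials x features numeric matrix.
#' @param labels Vector with exactly two distinct values, `>= 2` trials each.
#' @return A data.frame of class `"feature_scores"` with columns `feature`
#'   (name or index), `F`, `p`, `rank` (1-based, descending F), in original
#'   feature order.
#' @examples
#' X <- cbind(sep = c(1, 2, 3, 4, 5, 6), flat = rep(1, 6))
#' fscore(X, rep(c("a", "b"), each = 3))
#' @export
fscore <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stop("`labels` length must match rows of `X`")
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("exactly two classes are required")
  n_per <- table(factor(labels, classes))
  if (any(n_per < 2)) stop("each class needs >= 2 trials")
  n <- nrow(X)

  in1 <- labels == classes[1]
  m1 <- colMeans(X[in1, , drop = FALSE])
  m2 <- colMeans(X[!in1, , drop = FALSE])
  m <- colMeans(X)
  n1 <- sum(in1)
  n2 <- n - n1
  ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ssw <- colSums((X[in1, , drop = FALSE] -
                    matrix(m1, n1, ncol(X), byrow = TRUE))^2) +
         colSums((X[!in1, , drop = FALSE] -
                    matrix(m2, n2, ncol(X), byrow = TRUE))^2)
  msb <- ssb / 1
  msw <- ssw / (n - 2)

  f <- ifelse(msw > 0, msb / msw,
              ifelse(msb > 0, .Machine$double.xmax, 0))
  p <- ifelse(msw > 0, stats::pf(msb / pmax(msw, .Machine$double.xmin),
                                 1, n - 2, lower.tail = FALSE),
              ifelse(msb > 0, 0, 1))

  ord <- order(-f, seq_along(f))
  rk <- integer(length(f))
  rk[ord] <- seq_along(f)
  nm <- colnames(X)
  if (is.null(nm)) nm <- as.character(seq_len(ncol(X)))
  structure(data.frame(feature = nm, F = f, p = p, rank = rk,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("feature_scores", "data.frame"))
}

#' Significance mask of scored features
#'
#' Boolean mask over the features, true where the F-distribution p-value is
#' below `alpha`. Deliberately applies no multiple-testing correction: the
#' raw `p < 0.05` reading is what the topographic feature-map analysis uses.
#'
#' @param scores A [fscore()] result.
#' @param alpha Significance level (default 0.05).
#' @return Logical vector in feature order.
#' @export
significant_features <- function(scores, alpha = 0.05) {
  stopifnot(inherits(scores, "feature_scores"))
  scores$p < alpha
}

#' Feature indices in descending F order
#'
#' @param scores A [fscore()] result.
#' @return Integer vector: original feature indices ordered by rank.
#' @export
feature_ranking <- function(scores) {
  stopifnot(inherits(scores, "feature_scores"))
  order(scores$rank)
}
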