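#' Fit a Gaussian naive Bayes model
#'
#' Models each of the two emotion classes by independent per-feature Gaussian
#' densities: class-conditional sample means and variances, plus class
#' priors. Variances are floored at `1e-9` times the largest per-feature
#' variance in the training pool (or `1e-9` absolute if everything is
#' constant) so that constant features — common after min-max normalisation —
#' cannot produce degenerate densities.
#'
#' @param X Trials x features numeric matrix.
#' @param y Label vector, exactly two distinct values, `>= 2` trials each.
#' @param priors Optional named numeric vector of class priors (summing to
#'   1); defaults to the empirical class frequencies. The cross-day pipeline
#'   forces equal priors after class balancing.
#' @param feature_indices Optional integer vector recording which columns of
#'   the full feature space `X` represents; carried through for portability
#'   of the selected subspace.
#' @return A `"gnb"` object: list with `classes`, `means` and `vars`
#'   (2 x features), `priors`, `feature_indices`.
#' @export
fit_gnb <- function(X, y, priors = NULL, feature_indices = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y)) stop("`y` length must match rows of `X`")
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("exactly two classes are required")
  if (any(table(factor(y, classes)) < 2)) stop("each class needs >= 2 trials")

  means <- vars <- matrix(0, 2, ncol(X),
                          dimnames = list(classes, colnames(X)))
  for (i in 1:2) {
    Xc <- X[y == classes[i], , drop = FALSE]
    means[i, ] <- colMeans(Xc)
    vars[i, ] <- apply(Xc, 2, stats::var)
  }
  vmax <- max(vars)
  floor_v <- if (vmax > 0) 1e-9 * vmax else 1e-9
  vars <- pmax(vars, floor_v)

  if (is.null(priors)) {
    priors <- as.numeric(table(factor(y, classes))) / length(y)
    names(priors) <- classes
  } else {
    if (is.null(names(priors))) names(priors) <- classes
    priors <- priors[classes]
    if (any(priors <= 0) || abs(sum(priors) - 1) > 1e-8)
      stop("`priors` must be positive and sum to 1")
  }
  structure(list(classes = classes, means = means, vars = vars,
                 priors = priors, feature_indices = feature_indices),
            class = "gnb")
}

#' Predict emotion classes with a Gaussian naive Bayes model
#'
#' Assigns each trial to the class maximising the log posterior
#' `log prior + sum of per-feature log Gaussian densities`, computed in log
#' space for stability with up to 110 features. Exact posterior ties break to
#' the lexicographically first class label.
#'
#' @param object A [fit_gnb()] model.
#' @param newdata Trials x features matrix with the model's feature count.
#' @param type `"class"` (default) for labels, `"logposterior"` for the raw
#'   trials x 2 score matrix.
#' @param ... Unused.
#' @return Character vector of labels, or the score matrix.
#' @export
predict.gnb <- function(object, newdata, type = c("class", "logposterior"),
                        ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != ncol(object$means))
    stop(sprintf("feature count mismatch: model has %d, data has %d",
                 ncol(object$means), ncol(X)))
  lp <- sapply(1:2, function(i) {
    mu <- object$means[i, ]
    v <- object$vars[i, ]
    ll <- -0.5 * (log(2 * pi * v)[col(X)] +
                    (X - matrix(mu, nrow(X), ncol(X), byrow = TRUE))^2 /
                      matrix(v, nrow(X), ncol(X), byrow = TRUE))
    rowSums(ll) + log(object$priors[i])
  })
  lp <- matrix(lp, ncol = 2, dimnames = list(NULL, object$classes))
  if (type == "logposterior") return(lp)
  object$classes[max.col(lp, ties.method = "first")]
}

#' @export
print.gnb <- function(x, ...) {
  cat(sprintf("Gaussian naive Bayes: classes %s, %d feature(s), priors %s\n",
              paste(x$classes, collapse = " / "), ncol(x$means),
              paste(sprintf("%.3f", x$priors), collapse = " / ")))
  invisible(x)
}
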