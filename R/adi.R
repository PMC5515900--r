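#' Balanced subsample of a binary-labelled trial set
#'
#' Draws, without replacement, as many trials from each class as the minority
#' class holds, using the current RNG state. Used inside every balanced
#' repetition of the feature-count optimisation to neutralise class-imbalance
#' bias.
#'
#' @param labels Vector with exactly two distinct values.
#' @return Integer vector of retained trial indices (sorted).
#' @export
balance_classes <- function(labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("exactly two classes are required")
  n_min <- min(table(factor(labels, classes)))
  idx <- unlist(lapply(classes, function(cl) {
    pool <- which(labels == cl)
    if (length(pool) == n_min) pool else sample(pool, n_min)
  }), use.names = FALSE)
  sort(idx)
}

# Stratified fold assignment: within each class, shuffle and deal trials to
# folds round-robin. Uses the current RNG state.
stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    pool <- sample(which(labels == cl))
    assign[pool] <- rep_len(seq_len(folds), length(pool))
  }
  assign
}

# Accuracy over nested feature subsets, vectorised: with features walked in
# ranked order, the GNB log-posterior with the top-d features is the d-th
# cumulative sum of per-feature log-density differences, so one pass scores
# every candidate d at once.
nested_accuracy <- function(Xtr, ytr, Xte, yte, ranking) {
  classes <- sort(unique(ytr))
  stats_for <- function(cl) {
    Xc <- Xtr[ytr == cl, , drop = FALSE]
    v <- apply(Xc, 2, stats::var)
    v[is.na(v)] <- 0                       # single-trial fold: variance floor
    list(mu = colMeans(Xc), v = v)
  }
  s1 <- stats_for(classes[1])
  s2 <- stats_for(classes[2])
  vmax <- max(s1$v, s2$v)
  floor_v <- if (vmax > 0) 1e-9 * vmax else 1e-9
  s1$v <- pmax(s1$v, floor_v)
  s2$v <- pmax(s2$v, floor_v)

  loglik <- function(s) {
    -0.5 * (matrix(log(2 * pi * s$v), nrow(Xte), ncol(Xte), byrow = TRUE) +
              (Xte - matrix(s$mu, nrow(Xte), ncol(Xte), byrow = TRUE))^2 /
                matrix(s$v, nrow(Xte), ncol(Xte), byrow = TRUE))
  }
  delta <- (loglik(s1) - loglik(s2))[, ranking, drop = FALSE]
  # trials x candidate counts
  cum <- if (ncol(delta) == 1) delta else t(apply(delta, 1, cumsum))
  # Equal priors (training is balanced); ties favour the first class.
  pred1 <- cum >= 0
  truth1 <- yte == classes[1]
  colMeans(pred1 == truth1)
}

#' Optimise the feature count by balanced repeated cross-validation
#'
#' Implements the add-feature-in scheme: over `reps` balanced repetitions,
#' each a stratified `folds`-fold cross-validation, the Gaussian naive Bayes
#' accuracy is measured for every nested subset of the top-`d` ranked
#' features (`d = 1 .. length(ranking)`). The per-`d` accuracies are averaged
#' over all folds and repetitions and the selected count `d*` is the smallest
#' `d` attaining the maximum of the averaged curve (ties break toward fewer
#' features).
#'
#' @param X Trials x features matrix (full training pool).
#' @param y Binary label vector.
#' @param ranking Integer vector of feature indices in descending F-score
#'   order (see [feature_ranking()]).
#' @param reps Number of balanced repetitions (default 100).
#' @param folds Cross-validation folds (default 5).
#' @param seed Seed for the repetition substreams.
#' @return List with `d_star`, `curve` (mean CV accuracy per candidate
#'   count), `reps`, `folds`.
#' @export
optimize_feature_count <- function(X, y, ranking, reps = 100, folds = 5,
                                   seed = 1) {
  X <- as.matrix(X)
  y <- as.character(y)
  n_min <- min(table(y))
  if (n_min < folds)
    stop("too few trials per class (", n_min, ") for ", folds, "-fold CV")
  acc <- matrix(0, reps * folds, length(ranking))
  row <- 0L
  for (r in seq_len(reps)) {
    fold_of <- with_seed(substream_seed(seed, r), {
      keep <- balance_classes(y)
      f <- integer(length(y))
      f[keep] <- stratified_folds(y[keep], folds)
      f                                    # 0 = not in this repetition
    })
    for (f in seq_len(folds)) {
      tr <- which(fold_of > 0 & fold_of != f)
      te <- which(fold_of == f)
      row <- row + 1L
      acc[row, ] <- nested_accuracy(X[tr, , drop = FALSE], y[tr],
                                    X[te, , drop = FALSE], y[te], ranking)
    }
  }
  curve <- colMeans(acc)
  list(d_star = which.max(curve), curve = curve, reps = reps, folds = folds)
}

#' Run the add-day-in (ADI) cross-day validation
#'
#' The realistic cross-day protocol: for every condition `D = 1 .. n_days-1`,
#' train on days `1..D` and test on the unseen day `D+1` — (1) Day 1 vs. Day
#' 2, (2) Days 1-2 vs. Day 3, (3) Days 1-3 vs. Day 4, (4) Days 1-4 vs. Day 5
#' for a five-day dataset. Per condition: trials of the training days are
#' pooled and trial-averaged, features are ranked once by F-score on the full
#' training pool, the feature count is optimised by
#' [optimize_feature_count()], a final GNB is fitted on all training trials
#' with equal priors restricted to the top-`d*` features, and the test day —
#' trimmed to the same features — is scored. Test-day data never touch
#' ranking, optimisation, or fitting.
#'
#' The analytical manner selects what the trial vectors are computed from:
#' the trial matrix itself (`"original"`), or the sparse / low-rank component
#' of its per-trial robust PCA decomposition (`"rpca_sparse"` /
#' `"rpca_low_rank"`).
#'
#' @param dataset A `"cd_dataset"` (see [generate_feature_dataset()]) or any
#'   list with `days`, each day a list of `trials` (feature x window
#'   matrices) and `labels`. `neutral`-labelled trials are dropped.
#' @param manner `"original"`, `"rpca_sparse"`, or `"rpca_low_rank"`.
#' @param reps,folds Passed to [optimize_feature_count()].
#' @param seed Master seed for the balanced repetitions.
#' @param lambda,rule,tol,max_iter Robust PCA settings (see [rpca()]); used
#'   only for the RPCA manners.
#' @return An `"adi_report"`: list with `results` (data.frame: condition,
#'   training_days, test_day, d_star, accuracy), `selected` (per condition,
#'   the selected feature indices in rank order), `curves`, `manner`, `seed`.
#' @export
run_adi <- function(dataset, manner = c("original", "rpca_sparse",
                                        "rpca_low_rank"),
                    reps = 100, folds = 5, seed = 1,
                    lambda = NULL, rule = c("paper", "sqrt"),
                    tol = 1e-7, max_iter = 1000) {
  manner <- match.arg(manner)
  rule <- match.arg(rule)
  days <- dataset$days
  if (length(days) < 2) stop("need >= 2 days for cross-day validation")

  day_vectors <- lapply(days, function(day) {
    keep <- day$labels != "neutral"
    trials <- day$trials[keep]
    vecs <- t(vapply(trials, function(X) {
      X <- as.matrix(X)
      if (manner == "original") return(trial_average(X))
      dec <- rpca(X, lambda = lambda, rule = rule, tol = tol,
                  max_iter = max_iter)
      trial_average(if (manner == "rpca_sparse") dec$S else dec$L)
    }, numeric(nrow(as.matrix(trials[[1]])))))
    list(X = vecs, y = day$labels[keep])
  })
  for (d in seq_along(day_vectors)) {
    if (length(unique(day_vectors[[d]]$y)) < 2)
      stop("day ", d, " lacks one of the two classes")
  }

  n_cond <- length(days) - 1
  results <- data.frame(condition = seq_len(n_cond),
                        training_days = vapply(seq_len(n_cond), function(D)
                          paste(1:D, collapse = ","), ""),
                        test_day = seq_len(n_cond) + 1,
                        d_star = NA_integer_, accuracy = NA_real_,
                        stringsAsFactors = FALSE)
  selected <- curves <- vector("list", n_cond)
  for (D in seq_len(n_cond)) {
    Xtr <- do.call(rbind, lapply(day_vectors[1:D], `[[`, "X"))
    ytr <- unlist(lapply(day_vectors[1:D], `[[`, "y"))
    ranking <- feature_ranking(fscore(Xtr, ytr))
    opt <- optimize_feature_count(Xtr, ytr, ranking, reps = reps,
                                  folds = folds,
                                  seed = substream_seed(seed, 500 + D))
    sel <- ranking[seq_len(opt$d_star)]
    model <- fit_gnb(Xtr[, sel, drop = FALSE], ytr,
                     priors = c(0.5, 0.5), feature_indices = sel)
    te <- day_vectors[[D + 1]]
    pred <- predict(model, te$X[, sel, drop = FALSE])
    results$d_star[D] <- opt$d_star
    results$accuracy[D] <- mean(pred == te$y)
    selected[[D]] <- sel
    curves[[D]] <- opt$curve
  }
  structure(list(results = results, selected = selected, curves = curves,
                 manner = manner, seed = seed, reps = reps, folds = folds),
            class = "adi_report")
}

#' @export
print.adi_report <- function(x, ...) {
  cat(sprintf("Add-day-in report (manner = %s, %d reps x %d folds)\n",
              x$manner, x$reps, x$folds))
  df <- x$results
  for (i in seq_len(nrow(df)))
    cat(sprintf("  Days %-7s vs. Day %d:  d* = %3d   accuracy = %.3f\n",
                df$training_days[i], df$test_day[i], df$d_star[i],
                df$accuracy[i]))
  invisible(x)
}
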