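#' Two-dimensional discriminant projection of class distributions
#'
#' Projects trial vectors to a 2-D space built for visualising cross-day
#' class distributions: axis 1 is the (shrinkage-regularised) linear
#' discriminant direction of the two classes; axis 2 is the leading residual
#' variance direction orthogonal to axis 1. A two-class problem has a rank-1
#' between-class scatter, so a literal second discriminant component does not
#' exist — the orthogonal-variance axis preserves the intent
#' (discrimination plus spread) deterministically.
#'
#' The within-class scatter is shrunk toward its diagonal,
#' `(1 - shrinkage) * Sw + shrinkage * diag(Sw)`, which keeps it invertible
#' when trials are far fewer than the 110 features. Axes are unit norm with
#' the first nonzero loading positive.
#'
#' The decision boundary attached to the result is the line perpendicular to
#' the segment joining the two projected class centroids, through its
#' midpoint.
#'
#' @param X Trials x features matrix.
#' @param y Binary label vector.
#' @param shrinkage Diagonal shrinkage coefficient in `[0, 1]` (default 0.5).
#' @return A `"projection_result"`: list with `coords` (trials x 2),
#'   `axes` (features x 2), `centroids` (2 x 2, rows = classes), `boundary`
#'   (list `point`, `normal`), `classes`.
#' @export
discriminant_project <- function(X, y, shrinkage = 0.5) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("exactly two classes are required")
  mu1 <- colMeans(X[y == classes[1], , drop = FALSE])
  mu2 <- colMeans(X[y == classes[2], , drop = FALSE])

  Xc <- X
  Xc[y == classes[1], ] <- sweep(X[y == classes[1], , drop = FALSE], 2, mu1)
  Xc[y == classes[2], ] <- sweep(X[y == classes[2], , drop = FALSE], 2, mu2)
  Sw <- crossprod(Xc) / max(1, nrow(X) - 2)
  Sw <- (1 - shrinkage) * Sw + shrinkage * diag(diag(Sw), ncol(X))
  diag(Sw) <- diag(Sw) + 1e-10 * max(1, max(diag(Sw)))

  fix_sign <- function(v) {
    j <- which(abs(v) > 1e-12)[1]
    if (!is.na(j) && v[j] < 0) -v else v
  }
  a1 <- solve(Sw, mu1 - mu2)
  if (sum(a1^2) < 1e-24) a1 <- c(1, rep(0, ncol(X) - 1))  # coincident means
  a1 <- fix_sign(a1 / sqrt(sum(a1^2)))
  # Residual variance orthogonal to axis 1.
  resid <- Xc - (Xc %*% a1) %*% t(a1)
  a2 <- fix_sign(svd(resid, nu = 0, nv = 1)$v[, 1])
  a2 <- a2 - sum(a2 * a1) * a1
  a2 <- fix_sign(a2 / sqrt(sum(a2^2)))

  axes <- cbind(axis1 = a1, axis2 = a2)
  coords <- X %*% axes
  centroids <- rbind(colMeans(coords[y == classes[1], , drop = FALSE]),
                     colMeans(coords[y == classes[2], , drop = FALSE]))
  rownames(centroids) <- classes
  structure(list(coords = coords, axes = axes, centroids = centroids,
                 boundary = list(point = colMeans(centroids),
                                 normal = centroids[1, ] - centroids[2, ]),
                 classes = classes),
            class = "projection_result")
}

#' Feature-importance maps, jointly normalised
#'
#' Turns per-manner F-score vectors into comparable "topographic" importance
#' maps: all supplied maps are min-max normalised *jointly* (one min and one
#' max over their concatenation), so the relative importance across
#' analytical manners within a day is preserved. Scalp rendering is out of
#' scope; maps are plain 110-vectors.
#'
#' @param maps Named list of equal-length numeric vectors (e.g. F-scores per
#'   analytical manner for one day).
#' @return Named list of vectors in `[0, 1]`.
#' @export
importance_maps <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1)
  len <- unique(vapply(maps, length, 1L))
  if (length(len) != 1) stop("all maps must have equal length")
  all_v <- unlist(maps, use.names = FALSE)
  rng <- range(all_v)
  if (diff(rng) == 0) return(lapply(maps, function(v) v * 0))
  lapply(maps, function(v) (v - rng[1]) / diff(rng))
}

#' Euclidean distance between two importance maps
#'
#' A longer distance means two more distinct feature maps; used to quantify
#' how far the music-listening maps of each analytical manner sit from the
#' eye-closed resting benchmark.
#'
#' @param a,b Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
map_distance <- function(a, b) {
  if (length(a) != length(b)) stop("maps must have equal length")
  sqrt(sum((a - b)^2))
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Signed-rank statistic for paired samples: zero differences are dropped,
#' absolute differences are ranked (ties by midranks), and the statistic `V`
#' is the rank sum of the positive differences. The two-sided p-value is
#' exact (from the signed-rank distribution) when `n <= 50` after zero
#' removal and no ties are present, and otherwise uses the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param x Numeric vector, or paired differences if `y` is `NULL`.
#' @param y Optional second sample, paired with `x`.
#' @return List with `statistic` (V), `p.value`, `n` (pairs used), `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all pairs are tied (zero differences)")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(r))
  exact <- n <= 50 && !ties
  if (exact) {
    p <- min(1, 2 * min(stats::psignrank(V, n),
                        stats::psignrank(V - 1, n, lower.tail = FALSE)))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = V, p.value = p, n = n, exact = exact)
}
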