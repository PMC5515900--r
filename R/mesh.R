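#' MESH feature names
#'
#' The fixed, documented row ordering of the 110-dimensional MESH feature
#' space: band-major, and within each band the 12 single-electrode powers in
#' montage order, then the 6 laterality (left minus right) asymmetries, then
#' the 4 caudality (frontal minus posterior) asymmetries. Names are
#' `"<band>_<attribute>"`, e.g. `"alpha_AF3"`, `"alpha_AF3-AF4"`. Stability of
#' this ordering is what makes selected-feature indices portable between
#' training and test days.
#'
#' @return Character vector of length 110.
#' @export
mesh_feature_names <- function() {
  attrs <- c(cd_channels,
             paste(cd_laterality_pairs[, 1], cd_laterality_pairs[, 2],
                   sep = "-"),
             paste(cd_caudality_pairs[, 1], cd_caudality_pairs[, 2],
                   sep = "-"))
  unlist(lapply(names(cd_bands), function(b) paste(b, attrs, sep = "_")),
         use.names = FALSE)
}

#' Build the MESH feature matrix from band powers
#'
#' Expands a band-power array into the 110-row MESH matrix: for each of the
#' five bands, the 12 per-electrode powers plus 6 laterality and 4 caudality
#' power asymmetries (22 attributes x 5 bands). Asymmetries are computed on
#' the raw powers — before any normalisation — so they may be negative.
#'
#' The asymmetry operator defaults to the plain power difference of the
#' ordered pair; `"ratio"` (left / right) and `"log_ratio"` (log of that
#' ratio, with a small floor) are available behind the `asymmetry` switch.
#'
#' @param bp A `"band_power"` object from [stft_bandpower()], or a band x
#'   channel x window array with dimnames.
#' @param asymmetry `"difference"` (default), `"ratio"`, or `"log_ratio"`.
#' @return A `"mesh_matrix"`: 110 x n-window numeric matrix with rownames
#'   [mesh_feature_names()], carrying `day`, `trial`, `label` attributes when
#'   present on the input.
#' @export
build_mesh <- function(bp, asymmetry = c("difference", "ratio", "log_ratio")) {
  asymmetry <- match.arg(asymmetry)
  values <- if (inherits(bp, "band_power")) bp$values else bp
  if (length(dim(values)) != 3)
    stop("`bp` must be a band x channel x window array")
  miss_b <- setdiff(names(cd_bands), dimnames(values)[[1]])
  if (length(miss_b) > 0)
    stop("missing band(s): ", paste(miss_b, collapse = ", "))
  miss_c <- setdiff(cd_channels, dimnames(values)[[2]])
  if (length(miss_c) > 0)
    stop("missing channel(s): ", paste(miss_c, collapse = ", "))

  pair_op <- switch(asymmetry,
    difference = function(a, b) a - b,
    ratio = function(a, b) a / pmax(b, 1e-12),
    log_ratio = function(a, b) log(pmax(a, 1e-12) / pmax(b, 1e-12)))

  n_win <- dim(values)[3]
  pairs <- rbind(cd_laterality_pairs, cd_caudality_pairs)
  out <- matrix(0, 110, n_win, dimnames = list(mesh_feature_names(), NULL))
  row <- 0L
  for (b in names(cd_bands)) {
    for (ch in cd_channels) {
      row <- row + 1L
      out[row, ] <- values[b, ch, ]
    }
    for (i in seq_len(nrow(pairs))) {
      row <- row + 1L
      out[row, ] <- pair_op(values[b, pairs[i, 1], ], values[b, pairs[i, 2], ])
    }
  }
  meta <- if (inherits(bp, "band_power")) bp[c("day", "trial", "label")]
          else list(day = NULL, trial = NULL, label = NULL)
  structure(out, class = c("mesh_matrix", class(out)),
            day = meta$day, trial = meta$trial, label = meta$label)
}

#' Average a feature time series within a trial
#'
#' Collapses a features x windows matrix to one vector by the per-feature
#' arithmetic mean over windows — the trial-level representation used for
#' feature selection and classification.
#'
#' @param mesh Numeric matrix (features x windows).
#' @return Named numeric vector of per-feature means.
#' @export
trial_average <- function(mesh) {
  m <- unclass(mesh)
  if (!is.matrix(m) || ncol(m) < 1) stop("`mesh` must have >= 1 window")
  rowMeans(m)
}
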