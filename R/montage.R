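#' Electrode montage and frequency band definitions
#'
#' The pipeline targets a 12-electrode consumer-headset montage (the 14-channel
#' Emotiv layout with the temporal electrodes T7/T8 dropped). Asymmetry
#' features are built from six left-right (laterality) pairs and four
#' fronto-posterior (caudality) pairs, and band powers are computed over the
#' five stereotypical bands, with gamma capped at 43 Hz by the headset
#' bandwidth.
#'
#' @format
#' * `cd_channels`: character vector of the 12 electrode labels, in montage
#'   order.
#' * `cd_laterality_pairs`: 6 x 2 character matrix of ordered (left, right)
#'   electrode pairs.
#' * `cd_caudality_pairs`: 4 x 2 character matrix of ordered
#'   (frontal, posterior) electrode pairs.
#' * `cd_bands`: named list of `c(lo, hi)` band edges in Hz
#'   (delta 1-3, theta 4-7, alpha 8-13, beta 14-30, gamma 31-43).
#' @name montage
NULL

#' @rdname montage
#' @export
cd_channels <- c("AF3", "F7", "F3", "FC5", "P7", "O1",
                 "O2", "P8", "FC6", "F4", "F8", "AF4")

#' @rdname montage
#' @export
cd_laterality_pairs <- matrix(
  c("AF3", "AF4",
    "F7",  "F8",
    "F3",  "F4",
    "FC5", "FC6",
    "P7",  "P8",
    "O1",  "O2"),
  ncol = 2, byrow = TRUE,
  dimnames = list(NULL, c("left", "right")))

#' @rdname montage
#' @export
cd_caudality_pairs <- matrix(
  c("AF3", "O1",
    "F7",  "P7",
    "AF4", "O2",
    "F8",  "P8"),
  ncol = 2, byrow = TRUE,
  dimnames = list(NULL, c("frontal", "posterior")))

#' @rdname montage
#' @export
cd_bands <- list(
  delta = c(1, 3),
  theta = c(4, 7),
  alpha = c(8, 13),
  beta  = c(14, 30),
  gamma = c(31, 43))

#' Emotion labels recognised by the pipeline
#'
#' `neutral` trials are loaded but excluded from classification; `baseline`
#' marks pre-stimulus eye-closed segments, which inherit the emotion label of
#' the subsequent music trial when classified.
#' @export
cd_labels <- c("happiness", "sadness", "neutral", "baseline")

# Deterministic substream seed derived from a master seed. Keeps every derived
# seed a positive 32-bit integer so it is safe for set.seed().
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  ((abs(as.numeric(seed)) %% 48611) * 44111 + as.numeric(stream) * 7919 + 1) %%
    2147483647
}

# Run an expression under a local RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}
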