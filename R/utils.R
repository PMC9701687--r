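#' Luma (perceived brightness) of RGB pixels
#'
#' ITU-R BT.601 luma on 8-bit values: `0.299 R + 0.587 G + 0.114 B`.
#' The pipeline calls a pixel *background* when its luma exceeds 170.
#'
#' @param pixels An `h x w x 3` numeric array with values in `[0, 255]`,
#'   or a length-3 RGB vector.
#' @return A numeric `h x w` matrix (or scalar for a single pixel).
#' @examples
#' luma(c(255, 255, 255))  # 255
#' luma(c(0, 0, 0))        # 0
#' @export
luma <- function(pixels) {
  w <- c(0.299, 0.587, 0.114)
  if (is.null(dim(pixels))) {
    stopifnot(length(pixels) == 3L)
    return(sum(w * pixels))
  }
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  w[1] * pixels[, , 1] + w[2] * pixels[, , 2] + w[3] * pixels[, , 3]
}

#' Linear-interpolation percentile
#'
#' The single percentile convention used project-wide (density filter,
#' vote-score aggregation, concentration scaling): linear interpolation
#' between order statistics, i.e. `stats::quantile(type = 7)`.
#'
#' @param x Numeric vector.
#' @param p Percentile in `[0, 100]`.
#' @return The interpolated percentile value.
#' @export
percentile <- function(x, p) {
  unname(stats::quantile(x, p / 100, type = 7, names = FALSE))
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed from the Wilcoxon rank statistic with
#' the midrank convention for ties; equals the probability that a random
#' positive outscores a random negative (ties counting 1/2).
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param positive Logical vector, `TRUE` for the positive class, or a factor
#'   whose reference positive level is `"non-DF"`.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, positive) {
  pos <- as_positive(positive)
  np <- sum(pos)
  nn <- sum(!pos)
  if (np == 0L || nn == 0L) {
    stop("rank_auc: both classes must be present (degenerate labels)")
  }
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

# Coerce labels to a logical positive-class indicator. The positive class is
# non-DF (recurrence within 1 year) throughout the package.
as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  as.character(labels) == "non-DF"
}

outcome_levels <- c("DF", "non-DF")

as_outcome <- function(x) factor(as.character(x), levels = outcome_levels)

# Deterministic 32-bit seed derived from a base seed plus arbitrary
# string/integer tags; keeps derived seeds below 2^31.
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0(part, "|"))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate expr with a local RNG state: seeds deterministically, restores the
# caller's .Random.seed afterwards.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Read an 8-bit RGB image
#'
#' @param path Path to a PNG file.
#' @return An `h x w x 3` numeric array with values in `[0, 255]`.
#' @export
read_image_rgb <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write an 8-bit RGB image
#'
#' @param pixels `h x w x 3` array in `[0, 255]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image_rgb <- function(pixels, path) {
  png::writePNG(clip(pixels, 0, 255) / 255, path)
  invisible(path)
}

# Bilinear resize of an h x w (x 3) array to side x side.
resize_bilinear <- function(pixels, side) {
  if (is.na(side) || (nrow(pixels) == side && ncol(pixels) == side)) {
    return(pixels)
  }
  out <- EBImage::resize(pixels, w = side, h = side, filter = "bilinear")
  as.array(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
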