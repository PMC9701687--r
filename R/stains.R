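#' Canonical H&E stain matrix
#'
#' The widely published hematoxylin/eosin optical-density stain vectors
#' (hematoxylin ~ (0.65, 0.70, 0.29), eosin ~ (0.07, 0.99, 0.11)), columns
#' normalized to unit Euclidean norm. Column 1 is hematoxylin (the larger
#' red-channel OD component), column 2 eosin.
#'
#' @return A 3x2 matrix with columns `H`, `E`.
#' @export
canonical_stain_matrix <- function() {
  M <- cbind(H = c(0.65, 0.70, 0.29), E = c(0.07, 0.99, 0.11))
  sweep(M, 2, sqrt(colSums(M^2)), "/")
}

#' Construct a stain model
#'
#' A stain model bundles the 3x2 unit-norm stain-vector matrix with the
#' reference 99th-percentile concentrations and the Macenko parameters
#' (transmitted white level `io`, OD transparency cutoff `beta`, robust
#' angular percentile `alpha`).
#'
#' @param stain_matrix 3x2 matrix, columns hematoxylin then eosin; columns
#'   are re-normalized to unit norm and must be non-negative.
#' @param max_concentrations Length-2 positive vector of reference
#'   99th-percentile stain concentrations.
#' @param io Transmitted-light white level (default 255).
#' @param beta OD cutoff below which a pixel counts as transparent
#'   (default 0.15).
#' @param alpha Robust percentile for the angular extremes (default 1).
#' @return An object of class `stain_model`.
#' @export
stain_model <- function(stain_matrix, max_concentrations = c(1, 1),
                        io = 255, beta = 0.15, alpha = 1) {
  stopifnot(is.matrix(stain_matrix), all(dim(stain_matrix) == c(3L, 2L)))
  if (any(stain_matrix < -1e-8)) {
    stop("stain_model: stain vectors must have non-negative entries")
  }
  M <- pmax(stain_matrix, 0)
  M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  if (M[1, 1] < M[1, 2]) {
    stop("stain_model: column 1 must be hematoxylin (larger red-channel OD)")
  }
  colnames(M) <- c("H", "E")
  structure(list(stain_matrix = M,
                 max_concentrations = as.numeric(max_concentrations),
                 io = io, beta = beta, alpha = alpha),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("Stain model (Macenko):\n")
  print(round(x$stain_matrix, 4))
  cat(sprintf("max concentrations: %.4f (H), %.4f (E); io=%g beta=%g alpha=%g\n",
              x$max_concentrations[1], x$max_concentrations[2],
              x$io, x$beta, x$alpha))
  invisible(x)
}

#' The fixed reference stain model
#'
#' Canonical H&E matrix with unit reference concentrations; every slide is
#' normalized towards this target unless another reference is supplied.
#'
#' @inheritParams stain_model
#' @return A `stain_model`.
#' @export
reference_stain_model <- function(io = 255, beta = 0.15, alpha = 1) {
  stain_model(canonical_stain_matrix(), c(1, 1), io = io, beta = beta, alpha = alpha)
}

#' RGB to optical density
#'
#' `OD = -log10((I + 1) / io)` per channel; non-negative for 8-bit input and
#' monotone decreasing in intensity.
#'
#' @param pixels Numeric array/matrix/vector of 8-bit intensities.
#' @param io Transmitted-light white level.
#' @return Optical densities, same shape as the input.
#' @examples
#' rgb_to_od(254)  # 0
#' rgb_to_od(0)    # log10(255) ~ 2.407
#' @export
rgb_to_od <- function(pixels, io = 255) {
  -log10((pixels + 1) / io)
}

#' Optical density back to 8-bit RGB
#'
#' Inverse of [rgb_to_od()], rounded and clipped to `[0, 255]`.
#'
#' @param od Optical densities.
#' @param io Transmitted-light white level.
#' @return 8-bit intensities, same shape as the input.
#' @export
od_to_rgb <- function(od, io = 255) {
  clip(round(io * 10^(-od) - 1), 0, 255)
}

# Flatten an h x w x 3 array (or n x 3 matrix) to an n x 3 OD matrix.
od_pixels <- function(pixels, io) {
  if (length(dim(pixels)) == 3L) {
    pixels <- cbind(as.vector(pixels[, , 1]), as.vector(pixels[, , 2]),
                    as.vector(pixels[, , 3]))
  }
  rgb_to_od(pixels, io)
}

#' Non-negative stain concentrations
#'
#' Solves, per pixel, the 2-variable non-negative least-squares problem
#' `OD ~ stain_matrix %*% c`, exactly (active-set enumeration over the
#' three feasible supports), fully vectorized over pixels.
#'
#' @param od `n x 3` matrix of optical densities.
#' @param stain_matrix 3x2 stain matrix.
#' @return `n x 2` matrix of non-negative concentrations (H, E).
#' @export
solve_concentrations <- function(od, stain_matrix) {
  M <- stain_matrix
  pinv <- solve(crossprod(M), t(M))          # 2 x 3
  C <- od %*% t(pinv)                        # unconstrained LS
  c1 <- pmax(0, od %*% M[, 1] / sum(M[, 1]^2))   # E = 0 support
  c2 <- pmax(0, od %*% M[, 2] / sum(M[, 2]^2))   # H = 0 support
  bad <- C[, 1] < 0 | C[, 2] < 0
  if (any(bad)) {
    # residual^2 of the two single-stain candidates
    r1 <- rowSums((od[bad, , drop = FALSE] -
                     tcrossprod(c1[bad], M[, 1]))^2)
    r2 <- rowSums((od[bad, , drop = FALSE] -
                     tcrossprod(c2[bad], M[, 2]))^2)
    use1 <- r1 <= r2
    C[bad, 1] <- ifelse(use1, c1[bad], 0)
    C[bad, 2] <- ifelse(use1, 0, c2[bad])
  }
  colnames(C) <- c("H", "E")
  C
}

#' Estimate a Macenko stain model from an image
#'
#' Removes transparent pixels (all channels' OD <= `beta`), finds the two
#' leading principal directions of the OD cloud, projects tissue pixels onto
#' that plane, takes the stain vectors at the `alpha`-th and
#' `(100 - alpha)`-th percentile angles, and records per-stain
#' 99th-percentile concentrations.
#'
#' @param image `h x w x 3` RGB array (or `n x 3` matrix) in `[0, 255]`.
#' @param io,beta,alpha Macenko parameters; see [stain_model()].
#' @param max_pixels Deterministic subsample cap for the PCA (memory/time).
#' @param min_pixels Minimum tissue pixels required (default 100).
#' @return A fitted `stain_model`.
#' @section Errors: fewer than `min_pixels` tissue pixels, or a
#'   rank-deficient (single-stain) OD cloud, raise a degenerate-stain error
#'   of class `melaprog_degenerate_stain`.
#' @export
estimate_stain_model <- function(image, io = 255, beta = 0.15, alpha = 1,
                                 max_pixels = 50000L, min_pixels = 100L) {
  od <- od_pixels(image, io)
  tissue <- od[apply(od, 1, max) > beta, , drop = FALSE]
  if (nrow(tissue) < min_pixels) {
    stop(errorCondition(
      sprintf("degenerate stain: only %d tissue pixels (need >= %d)",
              nrow(tissue), min_pixels),
      class = "melaprog_degenerate_stain"))
  }
  # sort pixels before subsampling so the estimate is a function of the
  # pixel *set* (invariant to rotation and pixel order)
  fit_px <- tissue[order(tissue[, 1], tissue[, 2], tissue[, 3]), , drop = FALSE]
  if (nrow(fit_px) > max_pixels) {
    keep <- unique(round(seq(1, nrow(fit_px), length.out = max_pixels)))
    fit_px <- fit_px[keep, , drop = FALSE]
  }
  eg <- eigen(stats::cov(fit_px), symmetric = TRUE)
  if (eg$values[2] < 1e-4 * eg$values[1]) {
    stop(errorCondition("degenerate stain: rank-deficient OD cloud (single stain)",
                        class = "melaprog_degenerate_stain"))
  }
  V <- eg$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) if (sum(V[, j]) < 0) V[, j] <- -V[, j]
  proj <- fit_px %*% V
  phi <- atan2(proj[, 2], proj[, 1])
  lo <- percentile(phi, alpha)
  hi <- percentile(phi, 100 - alpha)
  v1 <- V %*% c(cos(lo), sin(lo))
  v2 <- V %*% c(cos(hi), sin(hi))
  fix <- function(v) {
    if (sum(v) < 0) v <- -v
    v <- pmax(v, 0)
    v / sqrt(sum(v^2))
  }
  v1 <- fix(v1); v2 <- fix(v2)
  M <- if (v1[1] >= v2[1]) cbind(v1, v2) else cbind(v2, v1)
  conc <- solve_concentrations(tissue, M)
  maxC <- c(percentile(conc[, 1], 99), percentile(conc[, 2], 99))
  stain_model(M, maxC, io = io, beta = beta, alpha = alpha)
}

#' Normalize a crop to a reference stain model
#'
#' Decomposes the crop into stain concentrations under the source model,
#' rescales each stain by `reference$max_concentrations /
#' source$max_concentrations`, and recomposes with the reference stain
#' matrix. A crop with no pixel above `beta` is returned unchanged with a
#' warning (nothing to normalize).
#'
#' @param crop `h x w x 3` RGB array in `[0, 255]`.
#' @param source Fitted `stain_model` of the crop's slide.
#' @param reference Target `stain_model` (default [reference_stain_model()]).
#' @return RGB array of the same shape.
#' @export
normalize_crop <- function(crop, source, reference = reference_stain_model()) {
  stopifnot(inherits(source, "stain_model"), inherits(reference, "stain_model"))
  od <- od_pixels(crop, source$io)
  if (!any(apply(od, 1, max) > source$beta)) {
    warning("normalize_crop: all-background crop, returned unchanged")
    return(crop)
  }
  conc <- solve_concentrations(od, source$stain_matrix)
  scale <- reference$max_concentrations / source$max_concentrations
  conc <- sweep(conc, 2, scale, "*")
  od_new <- conc %*% t(reference$stain_matrix)
  out <- od_to_rgb(od_new, reference$io)
  array(out, dim(crop))
}

#' Serialize a stain model to JSON
#'
#' @param model A `stain_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stain_model <- function(model, path) {
  jsonlite::write_json(list(
    stain_matrix = as.vector(t(model$stain_matrix)),  # row-major
    max_concentrations = model$max_concentrations,
    io = model$io, beta = model$beta, alpha = model$alpha
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a stain model written by [write_stain_model()]
#'
#' @param path JSON path.
#' @return A `stain_model`.
#' @export
read_stain_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stain_model(matrix(x$stain_matrix, 3, 2, byrow = TRUE),
              x$max_concentrations, io = x$io, beta = x$beta, alpha = x$alpha)
}
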