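#' Specify a feature-extraction backend
#'
#' Three transfer-learning backends mirror the standard ImageNet-pretrained
#' architectures, each tapped at its global-average-pooled penultimate
#' layer: `resnet50` (224 px in, 2048 features), `densenet201` (224 px,
#' 1920), `inceptionv3` (299 px, 2048). The pretrained weights are an
#' optional plug-in supplied as `extractor`; they are never required to
#' instantiate the backend description. The `toy` backend is a deterministic multiscale
#' summary (histograms, gradient/Laplacian texture, stain statistics) of
#' configurable length, and needs no weights.
#'
#' @param name One of `"toy"`, `"resnet50"`, `"densenet201"`,
#'   `"inceptionv3"`.
#' @param dim Feature length; fixed at 2048/1920/2048 for the named CNNs,
#'   configurable (default 64, minimum 34) for `toy`.
#' @param input_side Input resize side; fixed at 224/224/299 for the named
#'   CNNs; `NA` (native resolution) for `toy`.
#' @param extractor For CNN backends, a function `(pixels) -> numeric(dim)`
#'   wrapping locally available pretrained weights.
#' @return An object of class `feature_backend`.
#' @examples
#' feature_backend("resnet50")$dim     # 2048
#' feature_backend("densenet201")$dim  # 1920
#' @export
feature_backend <- function(name = c("toy", "resnet50", "densenet201", "inceptionv3"),
                            dim = NULL, input_side = NULL, extractor = NULL) {
  name <- match.arg(name)
  known <- list(resnet50 = c(side = 224, dim = 2048),
                densenet201 = c(side = 224, dim = 1920),
                inceptionv3 = c(side = 299, dim = 2048))
  if (name == "toy") {
    dim <- as.integer(dim %||% 64L)
    if (dim < 34L) stop("toy backend requires dim >= 34")
    input_side <- input_side %||% NA_integer_
  } else {
    k <- known[[name]]
    if (!is.null(dim) && dim != k[["dim"]]) {
      stop(sprintf("%s emits %d features per crop; dim = %d is inconsistent",
                   name, k[["dim"]], dim))
    }
    if (!is.null(input_side) && input_side != k[["side"]]) {
      stop(sprintf("%s takes %d x %d input; input_side = %d is inconsistent",
                   name, k[["side"]], k[["side"]], input_side))
    }
    dim <- as.integer(k[["dim"]])
    input_side <- as.integer(k[["side"]])
  }
  structure(list(name = name, dim = dim, input_side = input_side,
                 extractor = extractor),
            class = "feature_backend")
}

#' @export
print.feature_backend <- function(x, ...) {
  cat(sprintf("Feature backend '%s': input %s px -> %d features%s\n", x$name,
              ifelse(is.na(x$input_side), "native", x$input_side), x$dim,
              if (x$name != "toy" && is.null(x$extractor)) " (no weights plug-in)" else ""))
  invisible(x)
}

# Deterministic multiscale crop summary. Fixed block of 28 statistics plus
# (dim - 28) channel-histogram bins.
toy_crop_features <- function(pixels, dim = 64L) {
  g <- luma(pixels) / 255
  h <- nrow(g); w <- ncol(g)
  rh <- 1:(h %/% 2); ch <- 1:(w %/% 2)
  quads <- list(g[rh, ch], g[rh, -ch], g[-rh, ch], g[-rh, -ch])
  quad_stats <- unlist(lapply(quads, function(q) {
    gx <- abs(q[, -1] - q[, -ncol(q)])
    gy <- abs(q[-1, ] - q[-nrow(q), ])
    lap <- abs(4 * q[2:(nrow(q) - 1), 2:(ncol(q) - 1)] -
                 q[1:(nrow(q) - 2), 2:(ncol(q) - 1)] -
                 q[3:nrow(q), 2:(ncol(q) - 1)] -
                 q[2:(nrow(q) - 1), 1:(ncol(q) - 2)] -
                 q[2:(nrow(q) - 1), 3:ncol(q)])
    c(mean(q), stats::sd(q), mean(gx) + mean(gy), mean(lap))
  }))
  chan <- unlist(lapply(1:3, function(k) {
    v <- pixels[, , k] / 255
    c(mean(v), stats::sd(v))
  }))
  hconc <- solve_concentrations(od_pixels(pixels, 255), canonical_stain_matrix())[, 1]
  stain_stats <- c(mean(hconc), stats::sd(hconc), percentile(hconc, 75),
                   mean(hconc > 0.3))
  lum <- luma(pixels)
  frac_stats <- c(mean(lum < 100), mean(lum > 170))
  fixed <- c(quad_stats, chan, stain_stats, frac_stats)   # 16 + 6 + 4 + 2 = 28
  nb <- dim - length(fixed)
  per <- nb %/% 3L
  extra <- nb - 3L * per
  bins <- per + (seq_len(3L) <= extra)
  hists <- unlist(lapply(1:3, function(k) {
    v <- pixels[, , k]
    counts <- tabulate(pmin(floor(v / (256 / bins[k])) + 1L, bins[k]), bins[k])
    counts / length(v)
  }))
  out <- c(fixed, hists)
  names(out) <- paste0("f", seq_along(out) - 1L)
  out
}

#' Extract a feature matrix from crops
#'
#' Resizes each crop (bilinear) to the backend's input side and computes
#' its feature vector: the deterministic `toy` summary, or a user-supplied
#' pretrained-CNN extractor for the named architectures. Extraction is
#' label-blind: a pure function of the pixels.
#'
#' @param crops An `mp_crops` (from [preprocess_slide()]) or a list of RGB
#'   arrays plus a `manifest` data.frame passed separately.
#' @param backend A [feature_backend()].
#' @param manifest Optional manifest when `crops` is a bare list.
#' @return An object of class `mp_features`: `values` (`n_crops x dim`
#'   matrix, columns `f0..f{dim-1}`), `crop_id`, `patient_id`, `label`
#'   (factor DF/non-DF), `backend`.
#' @export
extract_features <- function(crops, backend = feature_backend("toy"),
                             manifest = NULL) {
  stopifnot(inherits(backend, "feature_backend"))
  if (inherits(crops, "mp_crops")) {
    manifest <- crops$manifest
    crops <- crops$crops
  }
  if (is.null(manifest)) {
    manifest <- data.frame(crop_id = sprintf("crop_%04d", seq_along(crops)),
                           patient_id = NA_character_, label = NA_character_)
  }
  fn <- if (backend$name == "toy") {
    function(px) toy_crop_features(px, backend$dim)
  } else {
    if (is.null(backend$extractor)) {
      stop(sprintf(paste0(
        "backend '%s' needs its ImageNet-pretrained weights, which are an ",
        "optional plug-in: pass feature_backend(\"%s\", extractor = <function>) ",
        "wrapping a local deep-learning runtime (e.g. torchvision exports)"),
        backend$name, backend$name))
    }
    backend$extractor
  }
  values <- matrix(NA_real_, length(crops), backend$dim,
                   dimnames = list(NULL, paste0("f", seq_len(backend$dim) - 1L)))
  for (i in seq_along(crops)) {
    px <- resize_bilinear(crops[[i]], backend$input_side)
    values[i, ] <- fn(px)
  }
  structure(list(values = values,
                 crop_id = manifest$crop_id,
                 patient_id = manifest$patient_id,
                 label = as_outcome(manifest$label),
                 backend = backend),
            class = "mp_features")
}

#' @export
print.mp_features <- function(x, ...) {
  cat(sprintf("Feature matrix: %d crops x %d features (backend '%s'), %d patients\n",
              nrow(x$values), ncol(x$values), x$backend$name,
              length(unique(x$patient_id))))
  invisible(x)
}

#' Combine feature matrices from multiple slides
#'
#' @param ... `mp_features` objects sharing one backend.
#' @return A single row-bound `mp_features`.
#' @export
rbind_features <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "mp_features")) {
    parts <- parts[[1]]
  }
  stopifnot(all(vapply(parts, inherits, logical(1), "mp_features")))
  structure(list(values = do.call(rbind, lapply(parts, `[[`, "values")),
                 crop_id = unlist(lapply(parts, `[[`, "crop_id")),
                 patient_id = unlist(lapply(parts, `[[`, "patient_id")),
                 label = as_outcome(unlist(lapply(parts, function(p) as.character(p$label)))),
                 backend = parts[[1]]$backend),
            class = "mp_features")
}

#' Write a feature store (CSV plus backend sidecar JSON)
#'
#' @param features An `mp_features`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.backend.json`.
#' @return `path`, invisibly.
#' @export
write_feature_store <- function(features, path) {
  df <- data.frame(crop_id = features$crop_id,
                   patient_id = features$patient_id,
                   label = as.character(features$label),
                   features$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(name = features$backend$name,
                            dim = features$backend$dim,
                            input_side = features$backend$input_side),
                       paste0(path, ".backend.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature store written by [write_feature_store()]
#'
#' @param path CSV path.
#' @return An `mp_features`.
#' @export
read_feature_store <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".backend.json"), simplifyVector = TRUE)
  fcols <- grep("^f[0-9]+$", names(df))
  structure(list(values = as.matrix(df[, fcols, drop = FALSE]),
                 crop_id = df$crop_id, patient_id = df$patient_id,
                 label = as_outcome(df$label),
                 backend = feature_backend(meta$name,
                                           dim = if (meta$name == "toy") meta$dim,
                                           input_side = if (meta$name == "toy") meta$input_side)),
            class = "mp_features")
}
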