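#' Tessellate an ROI into fixed-size tiles
#'
#' Lays a regular non-overlapping grid of `tile_side`-pixel tiles anchored
#' at the top-left of the ROI bounding box. A tile is emitted only if it is
#' fully inside the image and at least half of its pixels lie inside the
#' ROI mask.
#'
#' @param slide `h x w x 3` RGB array in `[0, 255]`.
#' @param roi Logical `h x w` matrix (the ROI mask).
#' @param tile_side Tile side in pixels (default 224, the working size at
#'   20x magnification).
#' @param slide_id Identifier carried into each tile's provenance.
#' @param min_coverage Minimum ROI fraction for a tile to be kept.
#' @return A list of `mp_tile` objects (possibly empty), each with
#'   `slide_id`, `origin` (0-based `c(x, y)` pixel offset), `pixels`,
#'   `tile_side`, and `cell_count`/`cell_density` slots (`NA` until
#'   [count_cells()] runs). Tiles are ordered row-major.
#' @export
tessellate_roi <- function(slide, roi, tile_side = 224L, slide_id = "slide",
                           min_coverage = 0.5) {
  stopifnot(length(dim(slide)) == 3L)
  if (!all(dim(roi) == dim(slide)[1:2])) {
    stop("tessellate_roi: ROI mask shape does not match the slide")
  }
  if (!any(roi)) return(list())
  rr <- range(which(rowSums(roi) > 0))
  cc <- range(which(colSums(roi) > 0))
  h <- nrow(roi); w <- ncol(roi)
  tiles <- list()
  for (r0 in seq(rr[1], h, by = tile_side)) {
    if (r0 + tile_side - 1 > h) break
    for (c0 in seq(cc[1], w, by = tile_side)) {
      if (c0 + tile_side - 1 > w) break
      rs <- r0:(r0 + tile_side - 1); cs <- c0:(c0 + tile_side - 1)
      if (mean(roi[rs, cs]) >= min_coverage) {
        tiles[[length(tiles) + 1L]] <- structure(list(
          slide_id = slide_id,
          origin = c(x = c0 - 1L, y = r0 - 1L),
          pixels = slide[rs, cs, , drop = FALSE],
          tile_side = as.integer(tile_side),
          cell_count = NA_integer_,
          cell_density = NA_real_
        ), class = "mp_tile")
      }
    }
  }
  tiles
}

#' @export
print.mp_tile <- function(x, ...) {
  cat(sprintf("Tile %s @ (%d, %d), %dpx, cells: %s\n", x$slide_id,
              x$origin[["x"]], x$origin[["y"]], x$tile_side,
              ifelse(is.na(x$cell_count), "not counted", x$cell_count)))
  invisible(x)
}

#' Detect cell nuclei in a tile
#'
#' Nuclei (tumor cells and lymphocytes) appear as dark, blob-like,
#' hematoxylin-rich objects. The detector deconvolves the tile into stain
#' concentrations with the canonical H&E matrix, then runs multiscale
#' Laplacian-of-Gaussian blob detection on the hematoxylin channel with
#' non-maximum suppression across space and scale.
#'
#' @param tile An `mp_tile` or an `h x w x 3` RGB array.
#' @param min_diam,max_diam Nuclear diameter range in pixels.
#' @param n_scales Number of LoG scales spanning the diameter range.
#' @param threshold Minimum scale-normalized LoG response.
#' @param margin Border margin (px) excluded from detection.
#' @return A data.frame with 0-based `x`, `y` centroids plus the detection
#'   `scale` (sigma) and `response`; zero rows for a blank tile.
#' @export
detect_cells <- function(tile, min_diam = 5, max_diam = 19, n_scales = 4L,
                         threshold = 0.08, margin = 2L) {
  pixels <- if (inherits(tile, "mp_tile")) tile$pixels else tile
  h <- nrow(pixels); w <- ncol(pixels)
  od <- od_pixels(pixels, 255)
  hconc <- matrix(solve_concentrations(od, canonical_stain_matrix())[, 1], h, w)
  sigmas <- seq(min_diam, max_diam, length.out = n_scales) / (2 * sqrt(2))
  lap_k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  cand <- list()
  for (s in sigmas) {
    blurred <- as.matrix(EBImage::gblur(hconc, sigma = s))
    resp <- -s^2 * as.matrix(EBImage::filter2(blurred, lap_k))
    # local maxima over the 8-neighborhood (borders handled by the margin)
    ri <- 2:(h - 1); ci <- 2:(w - 1)
    ctr <- resp[ri, ci]
    peak <- matrix(FALSE, h, w)
    peak[ri, ci] <- ctr > threshold &
      ctr >= resp[ri - 1, ci - 1] & ctr >= resp[ri - 1, ci] &
      ctr >= resp[ri - 1, ci + 1] & ctr >= resp[ri, ci - 1] &
      ctr >= resp[ri, ci + 1] & ctr >= resp[ri + 1, ci - 1] &
      ctr >= resp[ri + 1, ci] & ctr >= resp[ri + 1, ci + 1]
    peak[c(seq_len(margin), h - seq_len(margin) + 1L), ] <- FALSE
    peak[, c(seq_len(margin), w - seq_len(margin) + 1L)] <- FALSE
    idx <- which(peak)
    if (length(idx)) {
      cand[[length(cand) + 1L]] <- data.frame(
        row = ((idx - 1L) %% h) + 1L, col = ((idx - 1L) %/% h) + 1L,
        scale = s, response = resp[idx])
    }
  }
  if (!length(cand)) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      scale = numeric(0), response = numeric(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$response), , drop = FALSE]
  # greedy non-maximum suppression across scales
  keep <- logical(nrow(cand))
  min_sep2 <- (0.7 * min_diam)^2
  kept_r <- numeric(0); kept_c <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kept_r) == 0 ||
        min((cand$row[i] - kept_r)^2 + (cand$col[i] - kept_c)^2) > min_sep2) {
      keep[i] <- TRUE
      kept_r <- c(kept_r, cand$row[i]); kept_c <- c(kept_c, cand$col[i])
    }
  }
  out <- cand[keep, , drop = FALSE]
  data.frame(x = out$col - 1L, y = out$row - 1L,
             scale = out$scale, response = out$response)
}

#' Count cells in every tile
#'
#' Runs [detect_cells()] on each tile and fills `cell_count` and
#' `cell_density` (cells per pixel^2, i.e. count / tile area).
#'
#' @param tiles List of `mp_tile`.
#' @param ... Passed to [detect_cells()].
#' @return The tiles, with counts filled in.
#' @export
count_cells <- function(tiles, ...) {
  lapply(tiles, function(t) {
    t$cell_count <- nrow(detect_cells(t, ...))
    t$cell_density <- t$cell_count / (t$tile_side^2)
    t
  })
}

#' Retain high-cell-density tiles
#'
#' Forms the cell-density distribution over one ROI's tiles and keeps the
#' tiles whose density strictly exceeds its 90th percentile (linear
#' interpolation). If no tile exceeds it (e.g. all densities equal), the
#' single densest tile is kept, ties broken by origin in row-major order.
#'
#' @param tiles List of `mp_tile` with densities filled by [count_cells()].
#' @param probs Percentile level (default 90).
#' @return The retained tiles (empty input gives empty output).
#' @export
filter_tiles_by_density <- function(tiles, probs = 90) {
  if (!length(tiles)) return(list())
  d <- vapply(tiles, function(t) t$cell_density, numeric(1))
  if (anyNA(d)) stop("filter_tiles_by_density: run count_cells() first")
  cut <- percentile(d, probs)
  keep <- which(d > cut)
  if (!length(keep)) {
    ox <- vapply(tiles, function(t) t$origin[["x"]], numeric(1))
    oy <- vapply(tiles, function(t) t$origin[["y"]], numeric(1))
    keep <- order(-d, oy, ox)[1L]
  }
  tiles[keep]
}

#' Background fraction of a crop
#'
#' Fraction of pixels whose [luma()] exceeds `cutoff` (default 170).
#'
#' @param pixels RGB array.
#' @param cutoff Luma background threshold.
#' @return Fraction in `[0, 1]`.
#' @export
background_fraction <- function(pixels, cutoff = 170) {
  mean(luma(pixels) > cutoff)
}

#' Sample crops from a tile
#'
#' Candidate crop centers are drawn from an isotropic Gaussian centered on
#' the tile (`sigma = tile_side / 4`), rejection-sampled until the crop
#' rectangle lies fully inside the tile (at most `10 * max_crops` draws).
#' Up to `max_crops` candidates are generated; a candidate is retained only
#' if its background fraction (Luma > `luma_cutoff`) is strictly below
#' `bg_max`. Deterministic for a fixed seed.
#'
#' @param tile An `mp_tile`.
#' @param crop_side Crop side in pixels; default 112 (one-fourth of the
#'   tile area for 224-pixel tiles).
#' @param max_crops Cap on generated candidates per tile (default 50).
#' @param rng_seed Integer seed.
#' @param luma_cutoff Luma background threshold (default 170).
#' @param bg_max Maximum background fraction, exclusive (default 0.25).
#' @param sigma Gaussian sd for center sampling; default `tile_side / 4`.
#' @param label Slide label inherited by every crop.
#' @return List of `mp_crop` objects: `slide_id`, `tile_origin`, `center`
#'   (0-based slide coordinates), `pixels`, `background_fraction`, `label`.
#' @export
sample_crops <- function(tile, crop_side = 112L, max_crops = 50L, rng_seed = 1L,
                         luma_cutoff = 170, bg_max = 0.25, sigma = NULL,
                         label = NA_character_) {
  stopifnot(inherits(tile, "mp_tile"))
  side <- tile$tile_side
  if (crop_side > side) stop("sample_crops: crop_side exceeds the tile side")
  sigma <- sigma %||% (side / 4)
  half <- crop_side %/% 2L
  crops <- list()
  with_local_seed(rng_seed, {
    n_cand <- 0L
    draws <- 0L
    while (n_cand < max_crops && draws < 10L * max_crops) {
      draws <- draws + 1L
      cx <- round(stats::rnorm(1, (side + 1) / 2, sigma))
      cy <- round(stats::rnorm(1, (side + 1) / 2, sigma))
      r0 <- cy - half; c0 <- cx - half
      if (r0 < 1 || c0 < 1 || r0 + crop_side - 1 > side || c0 + crop_side - 1 > side) {
        next                                  # redraw out-of-bounds candidate
      }
      n_cand <- n_cand + 1L
      px <- tile$pixels[r0:(r0 + crop_side - 1), c0:(c0 + crop_side - 1), ,
                        drop = FALSE]
      bf <- background_fraction(px, luma_cutoff)
      if (bf < bg_max) {
        crops[[length(crops) + 1L]] <- structure(list(
          slide_id = tile$slide_id,
          tile_origin = tile$origin,
          center = c(x = tile$origin[["x"]] + cx - 1L,
                     y = tile$origin[["y"]] + cy - 1L),
          pixels = px,
          background_fraction = bf,
          label = label
        ), class = "mp_crop")
      }
    }
  })
  crops
}

#' Options for slide preprocessing
#'
#' Bundles every pre-processing constant at its standard value: 224-pixel
#' tiles, 90th-percentile density filter, 112-pixel crops, 50-crop cap,
#' Luma 170 background call with a 25% rejection rule, Macenko
#' normalization to the canonical reference.
#'
#' @param tile_side,crop_side,max_crops,density_percentile,luma_cutoff,bg_max
#'   See [tessellate_roi()], [sample_crops()], [filter_tiles_by_density()].
#' @param normalize Run Macenko normalization of retained crops.
#' @param reference Reference `stain_model`.
#' @param detect Named list of [detect_cells()] arguments.
#' @param seed Base seed for crop sampling.
#' @return A list of class `preprocess_options`.
#' @export
preprocess_options <- function(tile_side = 224L, crop_side = 112L,
                               max_crops = 50L, density_percentile = 90,
                               luma_cutoff = 170, bg_max = 0.25,
                               normalize = TRUE,
                               reference = reference_stain_model(),
                               detect = list(), seed = 1L) {
  structure(list(tile_side = as.integer(tile_side),
                 crop_side = as.integer(crop_side),
                 max_crops = as.integer(max_crops),
                 density_percentile = density_percentile,
                 luma_cutoff = luma_cutoff, bg_max = bg_max,
                 normalize = normalize, reference = reference,
                 detect = detect, seed = as.integer(seed)),
            class = "preprocess_options")
}

#' Preprocess one annotated slide into normalized crops
#'
#' Full pre-processing chain: tessellation, cell detection, 90th-percentile
#' density filtering, Gaussian crop sampling with background rejection,
#' per-slide Macenko stain estimation (pooled over the retained tiles) and
#' crop normalization to the reference. If stain estimation is degenerate
#' the slide's crops are dropped with a warning.
#'
#' @param slide RGB array, an `mp_slide`, or a PNG path.
#' @param roi Logical mask, a mask PNG path, or a GeoJSON path (ignored
#'   when `slide` is an `mp_slide`).
#' @param slide_id,label Provenance and the inherited outcome label.
#' @param opts A [preprocess_options()].
#' @return An object of class `mp_crops`: list with `crops` (list of RGB
#'   arrays), `manifest` (data.frame: crop_id, patient_id, tile_x, tile_y,
#'   center_x, center_y, background_fraction, label), `stain_model`, and
#'   `n_tiles`/`n_tiles_kept`.
#' @export
preprocess_slide <- function(slide, roi = NULL, slide_id = NULL, label = NULL,
                             opts = preprocess_options()) {
  if (inherits(slide, "mp_slide")) {
    slide_id <- slide_id %||% slide$patient_id
    label <- label %||% slide$outcome
    roi <- slide$roi
    slide <- slide$image
  } else if (is.character(slide)) {
    slide <- read_image_rgb(slide)
  }
  if (is.character(roi)) {
    roi <- if (grepl("\\.geojson$", roi)) {
      read_roi_geojson(roi, ncol(slide), nrow(slide))
    } else {
      png::readPNG(roi) > 0.5
    }
  }
  slide_id <- slide_id %||% "slide"
  tiles <- tessellate_roi(slide, roi, opts$tile_side, slide_id)
  n_tiles <- length(tiles)
  crops <- list()
  model <- NULL
  if (n_tiles) {
    tiles <- do.call(count_cells, c(list(tiles), opts$detect))
    kept <- filter_tiles_by_density(tiles, opts$density_percentile)
    model <- tryCatch({
      pooled <- do.call(rbind, lapply(kept, function(t) {
        cbind(as.vector(t$pixels[, , 1]), as.vector(t$pixels[, , 2]),
              as.vector(t$pixels[, , 3]))
      }))
      estimate_stain_model(pooled, io = opts$reference$io,
                           beta = opts$reference$beta,
                           alpha = opts$reference$alpha)
    }, melaprog_degenerate_stain = function(e) {
      warning(sprintf("slide %s: %s; its crops are dropped", slide_id,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(model) || !opts$normalize) {
      for (ti in seq_along(kept)) {
        cr <- sample_crops(kept[[ti]], opts$crop_side, opts$max_crops,
                           rng_seed = derive_seed(opts$seed, slide_id, ti),
                           luma_cutoff = opts$luma_cutoff, bg_max = opts$bg_max,
                           label = label)
        crops <- c(crops, cr)
      }
      if (opts$normalize && length(crops)) {
        crops <- lapply(crops, function(cr) {
          cr$pixels <- normalize_crop(cr$pixels, model, opts$reference)
          cr
        })
      }
    }
  } else {
    kept <- list()
  }
  manifest <- if (length(crops)) {
    data.frame(
      crop_id = vapply(seq_along(crops), function(i) {
        sprintf("%s_%d_%d_%02d", slide_id, crops[[i]]$tile_origin[["x"]],
                crops[[i]]$tile_origin[["y"]], i)
      }, character(1)),
      patient_id = slide_id,
      tile_x = vapply(crops, function(c) c$tile_origin[["x"]], numeric(1)),
      tile_y = vapply(crops, function(c) c$tile_origin[["y"]], numeric(1)),
      center_x = vapply(crops, function(c) c$center[["x"]], numeric(1)),
      center_y = vapply(crops, function(c) c$center[["y"]], numeric(1)),
      background_fraction = vapply(crops, function(c) c$background_fraction,
                                   numeric(1)),
      label = as.character(label %||% NA_character_),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(crop_id = character(0), patient_id = character(0),
               tile_x = numeric(0), tile_y = numeric(0),
               center_x = numeric(0), center_y = numeric(0),
               background_fraction = numeric(0), label = character(0))
  }
  structure(list(crops = lapply(crops, function(c) c$pixels),
                 manifest = manifest, stain_model = model,
                 n_tiles = n_tiles, n_tiles_kept = length(kept)),
            class = "mp_crops")
}

#' @export
print.mp_crops <- function(x, ...) {
  cat(sprintf("Preprocessed slide: %d/%d tiles kept, %d crops retained\n",
              x$n_tiles_kept, x$n_tiles, length(x$crops)))
  invisible(x)
}

#' Write crops as PNG files plus a manifest CSV
#'
#' @param crops An `mp_crops`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_crops <- function(crops, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- crops$manifest
  manifest$crop_path <- file.path(dir, paste0(manifest$crop_id, ".png"))
  for (i in seq_along(crops$crops)) {
    write_image_rgb(crops$crops[[i]], manifest$crop_path[i])
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(crops$stain_model)) {
    write_stain_model(crops$stain_model, file.path(dir, "stain_model.json"))
  }
  invisible(dir)
}

#' Read crops written by [write_crops()]
#'
#' @param dir Directory containing `manifest.csv` and crop PNGs.
#' @return An `mp_crops` (without tile bookkeeping).
#' @export
read_crops <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  crops <- lapply(manifest$crop_path, read_image_rgb)
  sm_path <- file.path(dir, "stain_model.json")
  structure(list(crops = crops, manifest = manifest,
                 stain_model = if (file.exists(sm_path)) read_stain_model(sm_path),
                 n_tiles = NA_integer_, n_tiles_kept = NA_integer_),
            class = "mp_crops")
}
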