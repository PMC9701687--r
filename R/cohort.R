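#' Configuration of a synthetic melanoma cohort
#'
#' Defines the study conditions the generator emulates: cohort size and
#' class imbalance (defaults mirror a 43-patient design cohort with 12
#' non-disease-free cases), a plantable class signal of tunable magnitude,
#' slide geometry, nuclear density and per-slide stain-matrix perturbation.
#'
#' @param n_patients Number of patients (>= 2).
#' @param frac_nondf Fraction of non-DF (recurrence) patients in `[0, 1]`;
#'   the positive class. Default `12/43`.
#' @param effect_size Non-negative magnitude of the planted class signal:
#'   non-DF slides get their nuclear density scaled by
#'   `1 + 0.4 * effect_size` and their nuclear-size log-sd scaled by
#'   `1 + 0.3 * effect_size`. `0` yields class-exchangeable images.
#' @param slide_px Slide side in pixels. Default 1120 (a 5x5 grid of
#'   224-pixel tiles), keeping a full run desk-sized.
#' @param nuclei_density_mean Mean nuclei per 10^4 pixel^2 of tissue.
#' @param stain_jitter Sd of the per-slide additive perturbation applied to
#'   the canonical H&E stain matrix (columns re-normalized afterwards).
#' @param seed Integer seed; all generator output is a pure function of
#'   `(config, patient_id, seed)`.
#' @param tile_side Tile side in pixels used downstream (for validation).
#' @param clinical_association If `TRUE`, tumor stage is sampled dependent
#'   on outcome so the clinical model has signal to find; by default
#'   clinical covariates are independent of outcome.
#' @param association_strength Log-odds shift per stage step used when
#'   `clinical_association = TRUE`.
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [render_slide()]
#' @export
cohort_config <- function(n_patients = 43L, frac_nondf = 12 / 43,
                          effect_size = 1.5, slide_px = 1120L,
                          nuclei_density_mean = 20, stain_jitter = 0.05,
                          seed = 1L, tile_side = 224L,
                          clinical_association = FALSE,
                          association_strength = 2) {
  if (!is.numeric(n_patients) || n_patients < 2 || n_patients != round(n_patients)) {
    stop("invalid config: n_patients must be an integer >= 2")
  }
  if (!is.numeric(frac_nondf) || frac_nondf < 0 || frac_nondf > 1) {
    stop("invalid config: frac_nondf must lie in [0, 1]")
  }
  n_nondf <- round(n_patients * frac_nondf)
  if (frac_nondf > 0 && frac_nondf < 1 && (n_nondf == 0 || n_nondf == n_patients)) {
    stop("invalid config: both classes must be non-empty when frac_nondf is in (0, 1)")
  }
  if (effect_size < 0) stop("invalid config: effect_size must be non-negative")
  if (stain_jitter < 0) stop("invalid config: stain_jitter must be non-negative")
  if (slide_px < tile_side) {
    stop("invalid config: slide_px must be at least one tile side")
  }
  structure(list(
    n_patients = as.integer(n_patients), frac_nondf = frac_nondf,
    effect_size = effect_size, slide_px = as.integer(slide_px),
    nuclei_density_mean = nuclei_density_mean, stain_jitter = stain_jitter,
    seed = as.integer(seed), tile_side = as.integer(tile_side),
    clinical_association = isTRUE(clinical_association),
    association_strength = association_strength
  ), class = "cohort_config")
}

# Design-cohort marginals for the clinical covariates.
clinical_marginals <- list(
  gender = c(Male = 0.488, Female = 0.512),
  tumor_site = c("Trunk" = 0.466, "Extremities" = 0.256, "Head & neck" = 0.023,
                 "Palms" = 0.023, "Lymph nodes" = 0.116, "Other" = 0.116),
  stage = c(I = 0.140, II = 0.627, III = 0.233),
  T = c(T0 = 0.047, T1 = 0.068, T2 = 0.233, T3 = 0.140, T4 = 0.512)
)

#' Generate a synthetic patient cohort
#'
#' Draws `n_patients` clinical records with design-cohort-like marginals
#' (gender, tumor site, stage I-III, T category, age ~ N(64, 14.9)) and a
#' fixed class split `round(n_patients * frac_nondf)` non-DF. Covariates are
#' independent of outcome unless `config$clinical_association` is set, in
#' which case stage is shifted towards III for non-DF patients.
#'
#' @param config A [cohort_config()].
#' @return An object of class `mp_cohort` with elements `clinical`
#'   (data.frame: patient_id, outcome, gender, tumor_site, stage, T, age)
#'   and `config`. Identical config and seed give identical output.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 43, frac_nondf = 12 / 43))
#' table(coh$clinical$outcome)  # 31 DF, 12 non-DF
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  n_nondf <- round(n * config$frac_nondf)
  clinical <- with_local_seed(derive_seed(config$seed, "cohort"), {
    outcome <- rep("DF", n)
    outcome[sample.int(n, n_nondf)] <- "non-DF"
    m <- clinical_marginals
    stage <- character(n)
    if (config$clinical_association) {
      s <- config$association_strength
      for (i in seq_len(n)) {
        sgn <- if (outcome[i] == "non-DF") 1 else -1
        w <- m$stage * exp(sgn * s * (seq_along(m$stage) - 2))
        stage[i] <- sample(names(m$stage), 1L, prob = w / sum(w))
      }
    } else {
      stage <- sample(names(m$stage), n, replace = TRUE, prob = m$stage)
    }
    data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      outcome = outcome,
      gender = sample(names(m$gender), n, replace = TRUE, prob = m$gender),
      tumor_site = sample(names(m$tumor_site), n, replace = TRUE, prob = m$tumor_site),
      stage = stage,
      T = sample(names(m$T), n, replace = TRUE, prob = m$T),
      age = as.integer(clip(round(stats::rnorm(n, 64, 14.9)), 20, 95)),
      stringsAsFactors = FALSE
    )
  })
  clinical$outcome <- as_outcome(clinical$outcome)
  clinical$stage <- factor(clinical$stage, levels = names(clinical_marginals$stage))
  clinical$T <- factor(clinical$T, levels = names(clinical_marginals$T))
  structure(list(clinical = clinical, config = config), class = "mp_cohort")
}

#' @export
print.mp_cohort <- function(x, ...) {
  tab <- table(x$clinical$outcome)
  cat(sprintf("Synthetic melanoma cohort: %d patients (%d DF / %d non-DF), seed %d\n",
              nrow(x$clinical), tab[["DF"]], tab[["non-DF"]], x$config$seed))
  invisible(x)
}

# Smooth positive random field of size px x px built from a coarse lognormal
# grid, bilinearly upsampled; mean ~ 1.
smooth_field <- function(px, grid = 7L, sdlog = 0.5) {
  coarse <- matrix(exp(stats::rnorm(grid * grid, -sdlog^2 / 2, sdlog)), grid, grid)
  as.matrix(EBImage::resize(coarse, w = px, h = px, filter = "bilinear"))
}

# Paint soft elliptical nuclei into a concentration field. Returns the field.
# centers: n x 2 matrix of (row, col) 1-based; a, b semi-axes; theta radians;
# amp peak optical-density amplitude per nucleus.
paint_nuclei <- function(field, centers, a, b, theta, amp) {
  px_r <- nrow(field); px_c <- ncol(field)
  for (i in seq_len(nrow(centers))) {
    w <- ceiling(2 * max(a[i], b[i]))
    r0 <- max(1L, centers[i, 1] - w); r1 <- min(px_r, centers[i, 1] + w)
    c0 <- max(1L, centers[i, 2] - w); c1 <- min(px_c, centers[i, 2] + w)
    dr <- (r0:r1) - centers[i, 1]
    dc <- (c0:c1) - centers[i, 2]
    ct <- cos(theta[i]); st <- sin(theta[i])
    xr <- outer(dr * ct, dc * st, "+")        # rotated row coord
    yr <- outer(-dr * st, dc * ct, "+")       # rotated col coord
    u <- (xr / a[i])^2 + (yr / b[i])^2
    field[r0:r1, c0:c1] <- field[r0:r1, c0:c1] + amp[i] * exp(-u)
  }
  field
}

#' Render a synthetic H&E slide for one patient
#'
#' Color formation follows the Beer-Lambert model: a hematoxylin
#' concentration field (soft elliptical nuclei at an inhomogeneous Poisson
#' density) and an eosin field (smooth stroma, displaced inside nuclei) are
#' combined through a per-slide stain matrix (the canonical H&E pair
#' perturbed by `stain_jitter`) and exponentiated to transmitted RGB.
#' Pixels outside the elliptical ROI (and inside a few "tear" artifacts)
#' are near-white, with Luma > 170. Non-DF patients receive denser and more
#' size-variable nuclei in proportion to `effect_size`.
#'
#' @param patient One row of a cohort's `clinical` data.frame (or a list
#'   with `patient_id` and `outcome`).
#' @param config The [cohort_config()] the cohort was generated with.
#' @return An object of class `mp_slide`: list with `image` (`px x px x 3`
#'   array in `[0, 255]`), `roi` (logical matrix), and `truth` (list:
#'   `stain_matrix` 3x2, `centroids` data.frame with 0-based `x`, `y`,
#'   `n_nuclei`, `density_multiplier`, `roi_ellipse`).
#' @export
render_slide <- function(patient, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$slide_px < config$tile_side) {
    stop("invalid config: slide_px must be at least one tile side")
  }
  px <- config$slide_px
  pid <- as.character(patient$patient_id)
  outcome <- as.character(patient$outcome)
  with_local_seed(derive_seed(config$seed, "slide", pid), {
    # --- ROI: axis-aligned ellipse ---------------------------------------
    cx <- px * (0.5 + stats::runif(1, -0.02, 0.02))
    cy <- px * (0.5 + stats::runif(1, -0.02, 0.02))
    ax <- px * stats::runif(1, 0.40, 0.46)
    ay <- px * stats::runif(1, 0.40, 0.46)
    cols <- matrix(seq_len(px), px, px, byrow = TRUE)
    rows <- matrix(seq_len(px), px, px)
    roi <- ((cols - cx) / ax)^2 + ((rows - cy) / ay)^2 <= 1

    # --- planted class signal --------------------------------------------
    dens_mult <- if (outcome == "non-DF") 1 + 0.4 * config$effect_size else 1
    size_sd_mult <- if (outcome == "non-DF") 1 + 0.3 * config$effect_size else 1
    slide_mult <- exp(stats::rnorm(1, 0, 0.15))

    # --- nuclei placement: inhomogeneous Poisson over the ROI ------------
    lambda_field <- smooth_field(px, grid = 7L, sdlog = 0.5)
    roi_idx <- which(roi)
    area <- length(roi_idx)
    n_nuclei <- stats::rpois(1, config$nuclei_density_mean / 1e4 * area *
                                slide_mult * dens_mult)
    wts <- lambda_field[roi_idx]
    pick <- roi_idx[sample.int(length(roi_idx), n_nuclei, replace = TRUE,
                               prob = wts)]
    centers <- cbind(row = ((pick - 1L) %% px) + 1L,
                     col = ((pick - 1L) %/% px) + 1L)

    # --- nuclear geometry and hematoxylin field --------------------------
    a <- 4 * exp(stats::rnorm(n_nuclei, 0, 0.22 * size_sd_mult))
    b <- a * stats::runif(n_nuclei, 0.65, 1)
    theta <- stats::runif(n_nuclei, 0, pi)
    amp <- stats::runif(n_nuclei, 0.75, 1.05)
    h_field <- paint_nuclei(matrix(0, px, px), centers, a, b, theta, amp)

    # --- eosin field: smooth stroma, displaced inside nuclei -------------
    e_noise <- smooth_field(px, grid = 9L, sdlog = 0.25)
    e_field <- clip(0.55 * e_noise, 0.4, 0.7) * exp(-2.5 * h_field)
    e_field[!roi] <- 0
    h_field[!roi] <- 0

    # --- tear artifacts: small near-white holes inside the ROI -----------
    n_tear <- sample.int(4L, 1L) - 1L
    tear <- matrix(FALSE, px, px)
    if (n_tear > 0) {
      for (i in seq_len(n_tear)) {
        tc <- centers[sample.int(max(n_nuclei, 1L), 1L), , drop = TRUE]
        ta <- stats::runif(1, 0.02, 0.05) * px
        tb <- stats::runif(1, 0.02, 0.05) * px
        tear <- tear | (((cols - tc[2]) / ta)^2 + ((rows - tc[1]) / tb)^2 <= 1)
      }
      h_field[tear] <- 0
      e_field[tear] <- 0
    }

    # --- per-slide stain matrix ------------------------------------------
    M <- canonical_stain_matrix()
    if (config$stain_jitter > 0) {
      M <- abs(M + matrix(stats::rnorm(6, 0, config$stain_jitter), 3, 2))
      M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
    }

    # --- Beer-Lambert color formation ------------------------------------
    io <- 255
    img <- array(0, c(px, px, 3))
    for (ch in 1:3) {
      od <- M[ch, 1] * h_field + M[ch, 2] * e_field
      img[, , ch] <- io * 10^(-od) - 1
    }
    bg <- !roi | tear
    nbg <- sum(bg)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[bg] <- clip(stats::rnorm(nbg, 250, 1.5), 244, 255)
      img[, , ch] <- plane
    }
    img <- clip(round(img), 0, 255)

    truth <- list(
      stain_matrix = M,
      centroids = data.frame(x = centers[, "col"] - 1L, y = centers[, "row"] - 1L),
      n_nuclei = n_nuclei,
      density_multiplier = slide_mult * dens_mult,
      size_sd_multiplier = size_sd_mult,
      roi_ellipse = c(cx = cx - 1, cy = cy - 1, ax = ax, ay = ay)
    )
    structure(list(image = img, roi = roi, truth = truth,
                   patient_id = pid, outcome = outcome),
              class = "mp_slide")
  })
}

#' Write a cohort (clinical CSV, slides, ROI annotations, ground truth)
#'
#' @param cohort An [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param slides If `TRUE`, render and write each patient's slide PNG, ROI
#'   annotation and ground-truth JSON.
#' @param roi_format `"mask"` (binary PNG) or `"geojson"` (polygon with
#'   0-based pixel coordinates, x right / y down).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, slides = TRUE, roi_format = c("mask", "geojson")) {
  stopifnot(inherits(cohort, "mp_cohort"))
  roi_format <- match.arg(roi_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  if (slides) {
    for (i in seq_len(nrow(cohort$clinical))) {
      p <- cohort$clinical[i, ]
      sl <- render_slide(p, cohort$config)
      write_image_rgb(sl$image, file.path(dir, sprintf("slide_%s.png", p$patient_id)))
      if (roi_format == "mask") {
        png::writePNG(sl$roi * 1, file.path(dir, sprintf("roi_%s.png", p$patient_id)))
      } else {
        write_roi_geojson(sl$truth$roi_ellipse,
                          file.path(dir, sprintf("roi_%s.geojson", p$patient_id)))
      }
      tr <- sl$truth
      jsonlite::write_json(
        list(patient_id = p$patient_id,
             stain_matrix = tr$stain_matrix,
             n_nuclei = tr$n_nuclei,
             density_multiplier = tr$density_multiplier,
             centroids = tr$centroids),
        file.path(dir, sprintf("truth_%s.json", p$patient_id)),
        digits = NA, auto_unbox = TRUE)
    }
  }
  invisible(dir)
}

# Write an elliptical ROI as a GeoJSON polygon (0-based pixel coordinates).
write_roi_geojson <- function(ellipse, path, n_vertices = 64L) {
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)
  xs <- ellipse[["cx"]] + ellipse[["ax"]] * cos(t)
  ys <- ellipse[["cy"]] + ellipse[["ay"]] * sin(t)
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(name = "ROI"),
    geometry = list(type = "Polygon",
                    coordinates = list(Map(c, xs, ys)))
  )))
  jsonlite::write_json(gj, path, digits = 6, auto_unbox = TRUE)
  invisible(path)
}

#' Rasterize a GeoJSON polygon ROI to a logical mask
#'
#' Scanline (even-odd) polygon fill over 0-based pixel coordinates.
#'
#' @param path GeoJSON file with one Polygon feature.
#' @param width,height Slide dimensions in pixels.
#' @return A `height x width` logical matrix.
#' @export
read_roi_geojson <- function(path, width, height) {
  gj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ring <- gj$features$geometry$coordinates[[1]]
  if (is.array(ring) && length(dim(ring)) == 3L) ring <- ring[1, , ]
  if (is.list(ring)) ring <- do.call(rbind, ring)
  ring <- as.matrix(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  n <- length(xs)
  mask <- matrix(FALSE, height, width)
  for (row in seq_len(height)) {
    y <- row - 1                      # pixel-center y, 0-based
    j <- n
    xint <- numeric(0)
    for (i in seq_len(n)) {
      if ((ys[i] > y) != (ys[j] > y)) {
        xint <- c(xint, xs[i] + (y - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i]))
      }
      j <- i
    }
    if (length(xint) >= 2) {
      xint <- sort(xint)
      for (k in seq(1, length(xint) - 1, by = 2)) {
        c0 <- max(1L, ceiling(xint[k] + 1))
        c1 <- min(width, floor(xint[k + 1] + 1))
        if (c0 <= c1) mask[row, c0:c1] <- TRUE
      }
    }
  }
  mask
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `clinical.csv` and per-patient slide and
#'   ROI files.
#' @return A list with `clinical` (data.frame) and a `slide_paths` /
#'   `roi_paths` lookup (named by patient_id).
#' @export
read_cohort_dir <- function(dir) {
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"), stringsAsFactors = FALSE)
  clinical$outcome <- as_outcome(clinical$outcome)
  ids <- clinical$patient_id
  sp <- file.path(dir, sprintf("slide_%s.png", ids))
  rp_mask <- file.path(dir, sprintf("roi_%s.png", ids))
  rp_gj <- file.path(dir, sprintf("roi_%s.geojson", ids))
  rp <- ifelse(file.exists(rp_mask), rp_mask, rp_gj)
  list(clinical = clinical,
       slide_paths = stats::setNames(sp, ids),
       roi_paths = stats::setNames(rp, ids))
}
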