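test_that("luma formula is sane at the extremes", {
  expect_equal(luma(c(255, 255, 255)), 255)
  expect_equal(luma(c(0, 0, 0)), 0)
  arr <- array(255, c(2, 2, 3))
  expect_equal(luma(arr), matrix(255, 2, 2))
})

test_that("tessellation lays a full-tile grid anchored at the ROI bbox", {
  mk <- function(px) array(120, c(px, px, 3))
  full <- function(px) matrix(TRUE, px, px)

  t4 <- tessellate_roi(mk(448), full(448), 224)
  expect_length(t4, 4L)
  origins <- t(vapply(t4, function(t) t$origin, numeric(2)))
  expect_equal(origins, rbind(c(0, 0), c(224, 0), c(0, 224), c(224, 224)),
               ignore_attr = TRUE)

  expect_length(tessellate_roi(mk(224), full(224), 224), 1L)
  # partial grid cells are discarded
  expect_length(tessellate_roi(mk(300), full(300), 224), 1L)

  # empty ROI -> empty list, not an error
  expect_length(tessellate_roi(mk(224), matrix(FALSE, 224, 224), 224), 0L)
  # mismatched mask shape -> input error
  expect_error(tessellate_roi(mk(224), matrix(TRUE, 100, 100), 224),
               "shape")
})

test_that("tiles below 50% ROI coverage are dropped", {
  img <- array(120, c(448, 448, 3))
  roi <- matrix(FALSE, 448, 448)
  roi[1:448, 1:300] <- TRUE   # left 300 columns
  tiles <- tessellate_roi(img, roi, 224)
  # column-wise: tile at x=0 fully covered; tile at x=224 covers 76/224 = 34%
  origins <- t(vapply(tiles, function(t) t$origin, numeric(2)))
  expect_equal(sort(unique(origins[, 1])), 0)
  expect_length(tiles, 2L)
})

test_that("the LoG detector finds rendered nuclei and ignores blank tiles", {
  expect_equal(nrow(detect_cells(array(255, c(64, 64, 3)))), 0L)

  centers <- separated_centers(10)
  det <- detect_cells(render_nuclei_tile(centers))
  expect_true(abs(nrow(det) - 10L) <= 1L)
  dists <- vapply(seq_len(nrow(centers)), function(i) {
    min(sqrt((det$y + 1 - centers[i, "row"])^2 +
               (det$x + 1 - centers[i, "col"])^2))
  }, numeric(1))
  expect_true(all(dists <= 3))

  one <- render_nuclei_tile(cbind(row = 112, col = 112))
  expect_equal(nrow(detect_cells(one)), 1L)
})

test_that("density filter keeps tiles strictly above the 90th percentile", {
  tiles <- lapply(1:100, function(i) {
    stub_tile(i / 224^2, origin = c(x = (i - 1) * 224, y = 0))
  })
  kept <- filter_tiles_by_density(tiles)
  kept_d <- vapply(kept, function(t) t$cell_density * 224^2, numeric(1))
  expect_equal(sort(kept_d), 91:100)   # P90 = 90.1 by linear interpolation

  # all equal densities -> fallback keeps exactly the first tile row-major
  eq <- lapply(1:5, function(i) stub_tile(10 / 224^2,
                                          origin = c(x = (i - 1) * 224, y = 0)))
  kept_eq <- filter_tiles_by_density(eq)
  expect_length(kept_eq, 1L)
  expect_equal(kept_eq[[1]]$origin[["x"]], 0)

  single <- filter_tiles_by_density(eq[3])
  expect_length(single, 1L)
  expect_length(filter_tiles_by_density(list()), 0L)
  expect_error(filter_tiles_by_density(list(stub_tile(NA))), "count_cells")
})

test_that("crop sampling enforces the background rule and the 50-crop cap", {
  white <- as_tile(array(255, c(224, 224, 3)))
  expect_length(sample_crops(white, rng_seed = 1), 0L)

  dark <- as_tile(array(100, c(224, 224, 3)))
  crops <- sample_crops(dark, rng_seed = 1)
  expect_length(crops, 50L)
  expect_true(all(vapply(crops, function(c) c$background_fraction, numeric(1)) == 0))

  # a candidate with background fraction exactly 0.25 is rejected
  px <- array(100, c(8, 8, 3))
  px[1:2, , ] <- 255                      # top quarter white
  qt <- as_tile(px)
  expect_length(sample_crops(qt, crop_side = 8, rng_seed = 1), 0L)

  expect_error(sample_crops(dark, crop_side = 300), "crop_side")
})

test_that("crops lie inside their tile and sampling is seed-deterministic", {
  cfg <- cohort_config(n_patients = 2, slide_px = 448, seed = 9)
  coh <- generate_cohort(cfg)
  sl <- render_slide(coh$clinical[1, ], cfg)
  tile <- tessellate_roi(sl$image, sl$roi, 224, "s")[[1]]
  crops <- sample_crops(tile, rng_seed = 4)
  expect_lte(length(crops), 50L)
  for (cr in crops) {
    expect_true(cr$center[["x"]] - tile$origin[["x"]] >= 56 - 1)
    expect_true(cr$center[["x"]] - tile$origin[["x"]] <= 224 - 56 + 1)
    expect_equal(dim(cr$pixels), c(112, 112, 3))
    expect_lt(cr$background_fraction, 0.25)
  }
  crops2 <- sample_crops(tile, rng_seed = 4)
  expect_identical(lapply(crops, `[[`, "center"),
                   lapply(crops2, `[[`, "center"))
})

test_that("crop retention is monotone in the background threshold", {
  cfg <- cohort_config(n_patients = 2, slide_px = 448, seed = 9)
  coh <- generate_cohort(cfg)
  sl <- render_slide(coh$clinical[2, ], cfg)
  tile <- tessellate_roi(sl$image, sl$roi, 224, "s")[[1]]
  keys <- function(crops) {
    vapply(crops, function(c) paste(c$center, collapse = "_"), character(1))
  }
  hi <- keys(sample_crops(tile, rng_seed = 2, luma_cutoff = 170))
  lo <- keys(sample_crops(tile, rng_seed = 2, luma_cutoff = 140))
  expect_true(all(lo %in% hi))
})

test_that("preprocess_slide produces a coherent crop manifest", {
  cfg <- cohort_config(n_patients = 2, slide_px = 448, seed = 15)
  coh <- generate_cohort(cfg)
  sl <- render_slide(coh$clinical[1, ], cfg)
  pc <- preprocess_slide(sl)
  expect_s3_class(pc, "mp_crops")
  expect_equal(length(pc$crops), nrow(pc$manifest))
  expect_gt(length(pc$crops), 0L)
  expect_true(all(pc$manifest$background_fraction < 0.25))
  expect_true(all(pc$manifest$label == as.character(coh$clinical$outcome[1])))
  expect_lte(pc$n_tiles_kept, pc$n_tiles)

  # crops round-trip through the PNG store
  dir <- withr::local_tempdir()
  write_crops(pc, dir)
  back <- read_crops(dir)
  expect_equal(length(back$crops), length(pc$crops))
  expect_equal(back$crops[[1]], pc$crops[[1]], ignore_attr = TRUE)
})
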