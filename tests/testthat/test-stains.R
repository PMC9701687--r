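test_that("optical-density transform matches its closed form and round-trips", {
  expect_equal(rgb_to_od(254), 0)
  expect_equal(rgb_to_od(0), log10(255))
  # monotone decreasing in intensity
  expect_true(all(diff(rgb_to_od(0:255)) < 0))
  # exact round trip on the 8-bit lattice
  expect_equal(od_to_rgb(rgb_to_od(0:255)), 0:255)
})

test_that("pure white crops fail the transparency filter", {
  white <- array(254, c(20, 20, 3))
  expect_true(all(rgb_to_od(white) < 0.15))
  expect_error(estimate_stain_model(white), class = "melaprog_degenerate_stain")
})

test_that("single-stain images raise a degenerate-stain error", {
  M <- canonical_stain_matrix()
  conc <- cbind(runif(500, 0.2, 1.5), 0)   # hematoxylin only
  px <- od_to_rgb(conc %*% t(M))
  expect_error(estimate_stain_model(px), class = "melaprog_degenerate_stain")
})

test_that("non-negative least squares concentrations are exact optima", {
  M <- canonical_stain_matrix()
  set.seed(8)
  conc <- cbind(runif(200, 0, 1.2), runif(200, 0, 1.2))
  od <- conc %*% t(M)
  est <- solve_concentrations(od, M)
  expect_equal(unname(est), unname(conc), tolerance = 1e-8)
  # negative-leaning pixels clamp to the boundary, never below zero
  od_neg <- matrix(c(0.5, 0, 0, 0, 0.5, 0.5), 2, 3, byrow = TRUE)
  est2 <- solve_concentrations(od_neg, M)
  expect_true(all(est2 >= 0))
})

test_that("Macenko estimation recovers a known stain matrix", {
  set.seed(21)
  true_M <- canonical_stain_matrix()
  true_M[, 1] <- true_M[, 1] + c(0.05, -0.03, 0.04)
  true_M <- pmax(true_M, 0)
  true_M <- sweep(true_M, 2, sqrt(colSums(true_M^2)), "/")
  # tissue-like mixture: hematoxylin-rich nuclei, eosin-only stroma, mixtures
  conc <- rbind(
    cbind(runif(5000, 0.5, 1.5), runif(5000, 0, 0.1)),    # nuclei
    cbind(runif(8000, 0, 0.1), runif(8000, 0.3, 1.5)),    # stroma
    cbind(runif(7000, 0, 1.2), runif(7000, 0, 1.2)))      # mixed
  px <- od_to_rgb(conc %*% t(true_M))
  sm <- estimate_stain_model(px)
  expect_gte(cosine_sim(sm$stain_matrix[, 1], true_M[, 1]), 0.99)
  expect_gte(cosine_sim(sm$stain_matrix[, 2], true_M[, 2]), 0.99)

  # synthesized with the reference matrix itself: reference concentrations
  # match the generator's 99th percentiles within 2%
  px_ref <- od_to_rgb(conc %*% t(canonical_stain_matrix()))
  sm_ref <- estimate_stain_model(px_ref)
  expect_lt(abs(sm_ref$max_concentrations[1] / ref_percentile(conc[, 1], 99) - 1), 0.02)
  expect_lt(abs(sm_ref$max_concentrations[2] / ref_percentile(conc[, 2], 99) - 1), 0.02)
})

test_that("stain estimation is invariant to rotation and pixel order", {
  cfg <- cohort_config(n_patients = 2, slide_px = 448, seed = 33)
  coh <- generate_cohort(cfg)
  img <- render_slide(coh$clinical[1, ], cfg)$image
  rot <- aperm(img, c(2, 1, 3))[, dim(img)[1]:1, , drop = FALSE]  # 90 degrees
  m1 <- estimate_stain_model(img)
  m2 <- estimate_stain_model(rot)
  expect_equal(m1$stain_matrix, m2$stain_matrix, tolerance = 1e-10)
  expect_equal(m1$max_concentrations, m2$max_concentrations, tolerance = 1e-10)
})

test_that("normalizing with the reference itself is close to the identity", {
  set.seed(4)
  M <- canonical_stain_matrix()
  conc <- cbind(runif(112 * 112, 0, 1), runif(112 * 112, 0, 1))
  crop <- array(od_to_rgb(conc %*% t(M)), c(112, 112, 3))
  src <- estimate_stain_model(crop)
  out <- normalize_crop(crop, src, src)
  expect_lt(mean(abs(out - crop)), 2)
})

test_that("normalization maps renderings under different stains together", {
  set.seed(14)
  conc <- cbind(runif(112 * 112, 0, 1.2), runif(112 * 112, 0, 1.2))
  jitter_M <- function(seed) {
    set.seed(seed)
    M <- abs(canonical_stain_matrix() + matrix(rnorm(6, 0, 0.06), 3, 2))
    sweep(M, 2, sqrt(colSums(M^2)), "/")
  }
  M1 <- jitter_M(1); M2 <- jitter_M(2)
  crop1 <- array(od_to_rgb(conc %*% t(M1)), c(112, 112, 3))
  crop2 <- array(od_to_rgb(conc %*% t(M2)), c(112, 112, 3))
  ref <- reference_stain_model()
  n1 <- normalize_crop(crop1, estimate_stain_model(crop1), ref)
  n2 <- normalize_crop(crop2, estimate_stain_model(crop2), ref)
  expect_lt(mean(abs(n1 - n2)), 5)
})

test_that("normalization is idempotent up to quantization", {
  cfg <- cohort_config(n_patients = 2, slide_px = 448, seed = 27)
  coh <- generate_cohort(cfg)
  sl <- render_slide(coh$clinical[1, ], cfg)
  ref <- reference_stain_model()
  once <- normalize_crop(sl$image, estimate_stain_model(sl$image), ref)
  twice <- normalize_crop(once, estimate_stain_model(once), ref)
  expect_lt(mean(abs(twice - once)), 2)
})

test_that("an all-background crop is returned unchanged with a warning", {
  bg <- array(250, c(16, 16, 3))
  expect_warning(out <- normalize_crop(bg, reference_stain_model()),
                 "all-background")
  expect_identical(out, bg)
})

test_that("stain models serialize to JSON and back", {
  set.seed(2)
  sm <- stain_model(canonical_stain_matrix(), c(1.3, 0.8))
  path <- withr::local_tempfile(fileext = ".json")
  write_stain_model(sm, path)
  back <- read_stain_model(path)
  expect_equal(back$stain_matrix, sm$stain_matrix)
  expect_equal(back$max_concentrations, sm$max_concentrations)
})
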