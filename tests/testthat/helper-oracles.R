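# Independent oracles, deliberately naive.

# AUC by brute-force enumeration of all positive/negative pairs.
brute_auc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  total <- 0
  for (a in sp) for (b in sn) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(sp) * length(sn))
}

# Linear-interpolation percentile from the definition h = (n-1)p + 1.
ref_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Best Youden J by exhaustive search over all midpoint cuts.
brute_youden_j <- function(scores, positive) {
  s <- sort(unique(scores))
  cuts <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  best <- -Inf
  for (t in cuts) {
    sens <- mean(scores[positive] > t)
    spec <- mean(scores[!positive] <= t)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Render a tile with nuclei at known centers through the same Beer-Lambert
# color model the generator uses (built here from primitives, so it is an
# oracle for the detector, not a copy of the slide renderer).
render_nuclei_tile <- function(centers, px = 224, a = 4, amp = 0.9,
                               eosin = 0.55, seed = 1) {
  set.seed(seed)
  n <- nrow(centers)
  h <- melaprog:::paint_nuclei(matrix(0, px, px), centers,
                               a = rep(a, n), b = rep(a * 0.85, n),
                               theta = stats::runif(n, 0, pi),
                               amp = rep(amp, n))
  e <- eosin * exp(-2.5 * h)
  M <- canonical_stain_matrix()
  img <- array(0, c(px, px, 3))
  for (ch in 1:3) {
    img[, , ch] <- pmax(pmin(round(255 * 10^(-(M[ch, 1] * h + M[ch, 2] * e)) - 1),
                             255), 0)
  }
  img
}

# Sample n well-separated centers inside [margin, px - margin].
separated_centers <- function(n, px = 224, margin = 30, min_sep = 25,
                              seed = 42) {
  set.seed(seed)
  repeat {
    centers <- cbind(row = sample(margin:(px - margin), n),
                     col = sample(margin:(px - margin), n))
    if (n < 2 || min(dist(centers)) >= min_sep) return(centers)
  }
}

# A single mp_tile built from a pixel array (full-image ROI).
as_tile <- function(pixels, slide_id = "t") {
  tessellate_roi(pixels, matrix(TRUE, nrow(pixels), ncol(pixels)),
                 tile_side = nrow(pixels), slide_id = slide_id)[[1]]
}

# Stub tile carrying only a cell density (for the density-filter tests).
stub_tile <- function(density, origin = c(x = 0, y = 0), side = 224L) {
  structure(list(slide_id = "stub", origin = origin, pixels = NULL,
                 tile_side = side,
                 cell_count = as.integer(round(density * side^2)),
                 cell_density = density),
            class = "mp_tile")
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
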