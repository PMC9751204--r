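test_that("preprocess removes constant backgrounds and keeps impulses", {
  cfg <- preprocess_config(lowpass_sigma = 0, post_gauss_sigma = 0,
                           ball_radius = 10)
  const <- matrix(7, 64, 64)
  pp <- preprocess(const, cfg)
  expect_equal(pp$background, const, ignore_attr = TRUE)
  expect_equal(pp$corrected, matrix(0, 64, 64), ignore_attr = TRUE)

  imp <- matrix(5, 64, 64)
  imp[32, 32] <- 500
  pp <- preprocess(imp, cfg)
  # the ball cannot enter a 1-px peak: baseline stays at the floor
  expect_equal(pp$background[32, 32], 5, tolerance = 1e-10)
  expect_equal(pp$corrected[32, 32], 495, tolerance = 1e-10)

  expect_error(preprocess(matrix(0, 8, 8), preprocess_config(ball_radius = 8)),
               "column length")
  expect_error(preprocess_config(ball_radius = -1), "ball_radius")
})

test_that("per-column rolling-ball baseline matches the exhaustive ball oracle", {
  set.seed(41)
  for (r in c(4, 9.5)) {
    img <- matrix(runif(64 * 8, 0, 100), 64, 8) +
      outer(sin(seq(0, 3, length.out = 64)) * 50, rep(1, 8))
    base <- vesiquant:::.rolling_ball_cols(img, r, 1)
    for (j in seq_len(ncol(img)))
      expect_equal(base[, j], oracle_rolling_ball_col(img[, j], r, 1),
                   tolerance = 1e-12)
  }
})

test_that("threshold map implements the column fluctuation rule", {
  const <- matrix(3, 32, 32)
  expect_equal(threshold_map(const, 2)$threshold, matrix(0, 32, 32))

  g <- matrix(8, 21, 4)
  g[, 2] <- c(rep(10, 11), rep(6, 10))  # median 10, min 6
  th <- threshold_map(g, 2)
  expect_equal(th$threshold[, 2], rep(16, 21))   # 2 * 2 * (10 - 6)
  expect_equal(th$threshold[, 1], rep(0, 21))
  # linear in SFR
  expect_equal(threshold_map(g, 3)$threshold, 1.5 * th$threshold)
})

test_that("spot detection equals a brute-force flood fill on random masks", {
  set.seed(7)
  for (trial in 1:30) {
    conn <- sample(c(4L, 8L), 1)
    mask <- matrix(runif(64 * 64) < 0.25, 64, 64)
    grid <- matrix(1, 64, 64) * mask
    sp <- detect_spots(grid, matrix(0.5, 64, 64), min_core_px = 1L,
                       connectivity = conn)
    lab <- oracle_label(mask, conn)
    expect_equal(nrow(sp$table), max(lab))
    # same pixel memberships: each core must be one oracle label
    for (px in sp$core)
      expect_length(unique(lab[px]), 1)
    expect_equal(sort(vapply(sp$core, nrow, integer(1))),
                 sort(unname(tabulate(lab[lab > 0]))))
  }
})

test_that("detection basics: empty grids, separated blocks, size filter", {
  z <- matrix(0, 32, 32)
  expect_equal(nrow(detect_spots(z, threshold_map(z, 2))$table), 0)

  g <- matrix(0, 32, 32)
  g[5:7, 5:7] <- 10
  g[20:22, 20:22] <- 10
  sp <- detect_spots(g, matrix(1, 32, 32))
  expect_equal(nrow(sp$table), 2)

  g2 <- matrix(0, 32, 32)
  g2[4, 4] <- 10                       # single pixel: below min_core_px = 2
  expect_equal(nrow(detect_spots(g2, matrix(1, 32, 32))$table), 0)
  expect_equal(nrow(detect_spots(g2, matrix(1, 32, 32), min_core_px = 1)$table), 1)
})

test_that("5x5 enlargement matches the per-pixel neighborhood-union oracle", {
  # single pixel at the center -> 25 px; at the corner -> 9 px
  mk <- function(r, c) {
    g <- matrix(0, 16, 16); g[r, c] <- 10
    enlarge_spots(detect_spots(g, matrix(1, 16, 16), min_core_px = 1))
  }
  expect_equal(mk(8, 8)$table$sigma_px, 25L)
  expect_equal(mk(1, 1)$table$sigma_px, 9L)

  set.seed(11)
  for (trial in 1:20) {
    mask <- matrix(runif(32 * 32) < 0.05, 32, 32)
    if (!any(mask)) next
    sp <- enlarge_spots(detect_spots(mask * 1, matrix(0.5, 32, 32),
                                     min_core_px = 1))
    for (j in seq_along(sp$core)) {
      want <- oracle_dilate(sp$core[[j]], c(32, 32))
      got <- sp$enlarged[[j]]
      expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                   unname(want[order(want[, 1], want[, 2]), , drop = FALSE]),
                   ignore_attr = TRUE)
    }
  }
})

test_that("integration matches naive per-pixel summation", {
  g <- matrix(5, 16, 16)
  sp <- detect_spots((g > 0) * 10, matrix(1, 16, 16))
  # constant 4-px enlarged mask example
  g2 <- matrix(0, 16, 16); g2[8, 8] <- 100
  sp2 <- integrate_spots(enlarge_spots(detect_spots(g2, matrix(1, 16, 16),
                                                    min_core_px = 1)), g2)
  expect_equal(sp2$table$I_int, 100)
  expect_equal(sp2$table$I_max, 100)

  set.seed(13)
  for (trial in 1:20) {
    grid <- matrix(runif(32 * 32, 0, 50), 32, 32)
    mask <- matrix(runif(32 * 32) < 0.04, 32, 32)
    if (!any(mask)) next
    sp <- integrate_spots(enlarge_spots(detect_spots(
      mask * 1, matrix(0.5, 32, 32), min_core_px = 1)), grid)
    for (j in seq_along(sp$core)) {
      s <- 0
      for (k in seq_len(nrow(sp$enlarged[[j]])))
        s <- s + grid[sp$enlarged[[j]][k, 1], sp$enlarged[[j]][k, 2]]
      expect_equal(sp$table$I_int[j], s)
      expect_equal(sp$table$I_max[j], max(grid[sp$core[[j]]]))
    }
  }
})

test_that("background sampling avoids occupied areas and integrates exactly", {
  const <- matrix(4, 128, 128)
  s <- sample_background(const, NULL, n_samples = 50, seed = 3)
  expect_equal(s$I_bg, 4 * s$sigma)
  expect_true(all(s$sigma >= 10 & s$sigma <= 100))

  zero <- matrix(0, 128, 128)
  expect_equal(sample_background(zero, NULL, n_samples = 20, seed = 3)$I_bg,
               rep(0, 20))

  # adversarially dense scene: samples must never touch occupied masks
  sc <- generate_scene(small_scene_params(seed = 19, n_vesicles = 120L))
  pp <- preprocess(sc$frame$blue)
  sp <- enlarge_spots(detect_spots(pp$corrected,
                                   threshold_map(pp$corrected, 3)))
  occupied <- matrix(FALSE, 256, 256)
  for (px in sp$enlarged) occupied[px] <- TRUE
  marked <- pp$corrected
  marked[occupied] <- 1e9
  s2 <- sample_background(marked, sp, n_samples = 100, seed = 5)
  expect_true(all(s2$I_bg < 1e8))     # no sample touched a marked pixel
  expect_error(sample_background(matrix(1, 8, 8), NULL, n_samples = 5,
                                 seed = 1), "occupied|free area|place")
})

test_that("background model fit matches the normal equations", {
  s <- data.frame(sigma = seq(10, 100, 10), I_bg = 3 * seq(10, 100, 10))
  m <- fit_background_model(s)
  expect_equal(m$a0, 0, tolerance = 1e-9)
  expect_equal(m$a1, 3, tolerance = 1e-12)

  set.seed(17)
  s2 <- data.frame(sigma = sample(10:100, 60, TRUE))
  s2$I_bg <- 2 + 5 * s2$sigma + rnorm(60)
  m2 <- fit_background_model(s2)
  X <- cbind(1, s2$sigma)
  beta <- solve(t(X) %*% X, t(X) %*% s2$I_bg)
  expect_equal(c(m2$a0, m2$a1), as.vector(beta), tolerance = 1e-9)

  expect_error(fit_background_model(s[1:5, ]), "at least 10")
  expect_error(fit_background_model(data.frame(sigma = rep(10, 12),
                                               I_bg = rnorm(12))),
               "degenerate")
})

test_that("normalization implements the background-relative definitions", {
  model <- structure(list(a0 = 0, a1 = 2, samples = NULL, channel = "blue"),
                     class = "vq_background_model")
  g <- matrix(0, 16, 16)
  g[8, 8] <- 60
  sp <- integrate_spots(enlarge_spots(detect_spots(g, matrix(1, 16, 16),
                                                   min_core_px = 1)), g)
  sp <- normalize_spots(sp, model)
  # sigma = 25 -> I_BG = 50; I_int = 60 -> I_tot = 0.2
  expect_equal(sp$table$I_tot, (60 - 50) / 50)
  # I_BG(1 px) = 2; I_max = 60 -> I_peak = 29
  expect_equal(sp$table$I_peak, (60 - 2) / 2)

  # I_int equal to the expected background -> I_tot = 0; double -> 1
  sp2 <- sp
  sp2$table$I_int <- 50
  expect_equal(normalize_spots(sp2, model)$table$I_tot, 0)
  sp2$table$I_int <- 100
  expect_equal(normalize_spots(sp2, model)$table$I_tot, 1)

  bad <- structure(list(a0 = -100, a1 = 1), class = "vq_background_model")
  expect_error(normalize_spots(sp, bad), "non-positive")
})

test_that("I_tot tracks true emitter flux on flat-field low-noise scenes", {
  p <- small_scene_params(seed = 7, image_shape = c(512L, 512L),
                          n_vesicles = 120L,
                          illumination = list(amplitude = 1, center = NULL,
                                              width = Inf),
                          noise_model = "gaussian", noise_sd = 2)
  sc <- generate_scene(p)
  det <- detect_vesicles(sc$frame$blue, channel = "blue", seed = 3)
  tr <- truth_channel(sc$truth, "blue")
  m <- match_truth(tr, det$spots$table)
  flux <- tr$flux_blue[m$matched_truth]
  itot <- det$spots$table$I_tot[m$matched]
  expect_gt(summary(lm(itot ~ flux))$r.squared, 0.99)
})

test_that("adding a constant offset moves a1 by ~ the offset and leaves I_tot stable", {
  sc <- generate_scene(small_scene_params(seed = 23, n_vesicles = 30L))
  raw <- unclass(sc$frame$blue)
  d1 <- detect_vesicles(raw, channel = "blue", seed = 2)
  d2 <- detect_vesicles(raw + 50, channel = "blue", seed = 2)
  # the rolling-ball baseline absorbs the offset: the corrected grid, the
  # background fit, and therefore I_tot are unchanged
  expect_equal(d2$model$a1, d1$model$a1, tolerance = 0.05)
  m1 <- match_truth(truth_channel(sc$truth, "blue"), d1$spots$table)
  m2 <- match_truth(truth_channel(sc$truth, "blue"), d2$spots$table)
  shared <- intersect(m1$matched_truth, m2$matched_truth)
  i1 <- d1$spots$table$I_tot[m1$matched[match(shared, m1$matched_truth)]]
  i2 <- d2$spots$table$I_tot[m2$matched[match(shared, m2$matched_truth)]]
  expect_equal(i2, i1, tolerance = 0.05)
})

test_that("spot count is non-increasing in SFR", {
  sc <- generate_scene(small_scene_params(seed = 29))
  pp <- preprocess(sc$frame$blue)
  counts <- vapply(c(1, 2, 3, 4, 6, 10), function(sfr)
    nrow(detect_spots(pp$corrected, threshold_map(pp$corrected, sfr))$table),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})
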