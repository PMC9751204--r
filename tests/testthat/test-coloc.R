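test_that("drift estimation recovers exact shifts and breaks ties sensibly", {
  set.seed(3)
  base <- matrix(rpois(120 * 90, 5), 120, 90)
  base[cbind(sample(20:100, 30), sample(20:70, 30))] <- 500

  same <- estimate_drift(base, base, max_shift = 5)
  expect_equal(c(same$drow, same$dcol), c(0L, 0L))
  expect_gt(same$peak, 0.999)

  shifted <- shift_matrix(base, 3, -2, fill = 5)
  off <- estimate_drift(base, shifted, max_shift = 5)
  expect_equal(c(off$drow, off$dcol), c(3L, -2L))

  # masks variant
  offm <- estimate_drift(base > 100, (shifted > 100) * 1, max_shift = 5)
  expect_equal(c(offm$drow, offm$dcol), c(3L, -2L))

  expect_error(estimate_drift(matrix(1, 10, 10), matrix(1, 10, 10), 3),
               "zero-variance")
  expect_error(estimate_drift(base, base[, 1:80], 3), "identical shape")
})

test_that("apply_drift translates literally and round-trips", {
  sc <- generate_scene(small_scene_params(seed = 3))
  det <- detect_vesicles(sc$frame$blue, seed = 1)
  sp <- det$spots
  expect_equal(apply_drift(sp, 0, 0)$table, sp$table)
  rt <- apply_drift(apply_drift(sp, 4, -3), -4, 3)
  interior <- !sp$table$border
  expect_equal(rt$table$centroid_row[interior],
               sp$table$centroid_row[interior])
  expect_equal(rt$table$centroid_col[interior],
               sp$table$centroid_col[interior])
  # manual per-spot addition oracle
  man <- apply_drift(sp, 2, 5)
  for (j in seq_len(nrow(sp$table))) {
    expect_equal(man$table$centroid_row[j], sp$table$centroid_row[j] + 2)
    expect_equal(man$table$centroid_col[j], sp$table$centroid_col[j] + 5)
  }
  # grids: literal translation with zero fill
  g <- matrix(1:12, 3, 4)
  expect_equal(apply_drift(g, 1, 0)[1, ], rep(0, 4))
  expect_equal(apply_drift(g, 1, 0)[2:3, ], g[1:2, ])
})

test_that("position matching is one-to-one, distance-greedy, and exhaustive-equivalent", {
  mk <- function(rc, channel) {
    tab <- data.frame(id = seq_len(nrow(rc)), channel = channel,
                      centroid_row = rc[, 1], centroid_col = rc[, 2],
                      core_px = 1L, sigma_px = 1L, I_int = 1, I_max = 1,
                      I_tot = 1, I_peak = 1, border = FALSE,
                      colocalized = FALSE, partner_id = NA_integer_)
    structure(list(table = tab, core = list(), enlarged = NULL,
                   channel = channel, shape = c(100L, 100L)),
              class = "vq_spots")
  }
  pts <- cbind(runif(6, 10, 90), runif(6, 10, 90))
  a <- mk(pts, "blue")
  b <- mk(pts, "red")
  res <- colocalize_by_position(a, b, radius = 2)
  expect_equal(res$frac_blue, 100)
  expect_equal(res$frac_red, 100)
  expect_true(!any(duplicated(res$pairs$blue_id)))
  expect_true(!any(duplicated(res$pairs$red_id)))

  far <- mk(pts + 50, "red")
  expect_equal(colocalize_by_position(a, far, radius = 2)$frac_blue, 0)

  set.seed(31)
  for (trial in 1:40) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    pa <- cbind(runif(na, 0, 30), runif(na, 0, 30))
    pb <- cbind(runif(nb, 0, 30), runif(nb, 0, 30))
    rho <- runif(1, 1, 6)
    res <- colocalize_by_position(mk(pa, "blue"), mk(pb, "red"), rho)
    d <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2)
    cand <- which(d <= rho, arr.ind = TRUE)
    expect_equal(nrow(res$pairs), oracle_max_matching(cand))
  }
})

test_that("position fraction is monotone in the radius and vanishes as radius -> 0", {
  sc <- generate_scene(small_scene_params(seed = 37, frac_colocalized = 0.5))
  db <- detect_vesicles(sc$frame$blue, channel = "blue", seed = 1)
  dr <- detect_vesicles(sc$frame$red, channel = "red", seed = 2)
  red_al <- apply_drift(dr$spots, -2, -1)
  fracs <- vapply(c(1e-6, 0.5, 1, 2, 4, 8), function(rho)
    colocalize_by_position(db$spots, red_al, rho)$frac_mean, numeric(1))
  expect_equal(fracs[1], 0)
  expect_true(all(diff(fracs) >= 0))
})

test_that("intensity-detected colocalization applies the SFR x background rule", {
  sc <- generate_scene(small_scene_params(seed = 41, frac_colocalized = 0.5))
  db <- detect_vesicles(sc$frame$blue, channel = "blue", seed = 1)
  dr <- detect_vesicles(sc$frame$red, channel = "red", seed = 2)
  off <- drift_offset(2, 1)

  # red grid identically equal to its fitted background -> I_tot ~ 0 -> none
  flatred <- matrix(dr$model$a1, 256, 256)
  flat_model <- structure(list(a0 = 0, a1 = dr$model$a1),
                          class = "vq_background_model")
  res0 <- colocalize_by_intensity(db$spots, dr$spots, db$corrected, flatred,
                                  db$model, flat_model, sfr = 2, drift = off)
  expect_equal(res0$frac_blue, 0)

  # grid at 2*(1+SFR)*background -> I_tot = 1 + 2*SFR >= SFR for any SFR >= 0
  for (sfr in c(0.5, 2, 5)) {
    hot <- matrix(2 * (1 + sfr) * dr$model$a1, 256, 256)
    res1 <- colocalize_by_intensity(db$spots, dr$spots, db$corrected, hot,
                                    db$model, flat_model, sfr = sfr,
                                    drift = off)
    expect_equal(res1$frac_blue, 100)
  }

  # transferred I_tot >= sfr is the exact pass criterion
  it <- transferred_itot(db$spots, dr$corrected, dr$model, 2, 1)
  res <- colocalize_by_intensity(db$spots, dr$spots, db$corrected,
                                 dr$corrected, db$model, dr$model, sfr = 2,
                                 drift = off)
  expect_equal(res$frac_blue, 100 * mean(it >= 2, na.rm = TRUE))
})

test_that("intensity fraction is non-increasing in the colocalization SFR", {
  sc <- generate_scene(small_scene_params(seed = 43, frac_colocalized = 0.5))
  db <- detect_vesicles(sc$frame$blue, channel = "blue", seed = 1)
  dr <- detect_vesicles(sc$frame$red, channel = "red", seed = 2)
  off <- drift_offset(2, 1)
  fr <- vapply(c(0.5, 1, 2, 4, 8, 16), function(sfr)
    colocalize_by_intensity(db$spots, dr$spots, db$corrected, dr$corrected,
                            db$model, dr$model, sfr, drift = off)$frac_mean,
    numeric(1))
  expect_true(all(diff(fr) <= 0))
})
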