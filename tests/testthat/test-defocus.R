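# Algorithm II: background matching, in-focus masks, fractional-height
# normalization, and the maximal reached height.

test_that("background intensity is the exact median", {
  expect_equal(background_intensity(matrix(17, 5, 5)), 17)
  expect_equal(background_intensity(matrix(c(1, 2, 3, 4, 100), 1)), 3)
  expect_error(background_intensity(matrix(numeric(0), 0, 0)), "empty")
})

test_that("in-focus masks follow the tolerance band and the ROI", {
  plane <- matrix(50, 10, 10)
  expect_true(all(in_focus_mask(plane, background = 50, tol = 0)))
  expect_false(any(in_focus_mask(plane + 1, background = 50, tol = 0)))
  roi <- matrix(FALSE, 10, 10); roi[1:3, ] <- TRUE
  m <- in_focus_mask(plane, background = 50, tol = 0, roi = roi)
  expect_equal(sum(m), 30)
  expect_error(in_focus_mask(plane, 50, tol = -1))
})

test_that("fractional-height columns are normalized and flagged", {
  p <- small_params(seed = 3L)
  st <- generate_lamellipodium_stack(p, small_config())
  fhs <- fractional_height_series(st)
  sums <- colSums(fhs)
  expect_true(all(abs(sums - 1) < 1e-12 | sums == 0))
  expect_true(all(fhs >= 0 & fhs <= 1))
  expect_equal(length(attr(fhs, "flagged")), length(st$frames))
})

test_that("all in-focus content at height 0 puts the whole fraction there", {
  p <- small_params(noise_sd = 0,
                    lift_profile = function(ph) rep(0, length(ph)))
  st <- generate_lamellipodium_stack(p, small_config())
  # restrict to cell pixels: with no lift and no noise they match the
  # background exactly at height 0 and deviate at every other plane
  gt <- st$ground_truth
  cell_roi <- lapply(seq_along(st$frames), function(i) {
    roi <- matrix(FALSE, 40, 120)
    roi[, seq_len(floor(gt$edge_um[i] / 0.1) - 12)] <- TRUE
    roi
  })
  fhs <- fractional_height_series(st, tol = 0, roi = cell_roi)
  expect_true(all(fhs[1, ] == 1))
  expect_true(all(fhs[-1, ] == 0))
})

test_that("the per-frame argmax height follows the lift profile", {
  p <- small_params(seed = 5L)          # default bump to 5 um
  st <- generate_lamellipodium_stack(p, small_config())
  fhs <- fractional_height_series(st)
  hs <- attr(fhs, "heights_um")
  am <- hs[apply(fhs, 2, which.max)]
  near <- vapply(st$ground_truth$height_um,
                 function(h) hs[which.min(abs(hs - h))], numeric(1))
  expect_gt(mean(am == near), 0.9)
  # in-focus count at 5 um peaks at the lifted phase
  lifted <- st$ground_truth$height_um >= 4.5
  expect_gt(min(fhs[hs == 5, lifted]), max(fhs[hs == 5, !lifted]))
})

test_that("the series is invariant to a global additive offset", {
  p <- small_params(seed = 8L)
  st <- generate_lamellipodium_stack(p, small_config())
  st2 <- st
  st2$frames <- lapply(st$frames, function(fr) lapply(fr, function(m) m + 37))
  expect_equal(unclass(fractional_height_series(st)),
               unclass(fractional_height_series(st2)))
})

test_that("max height trace reads the highest sufficiently occupied plane", {
  frac <- matrix(0, 4, 3)
  frac[1, ] <- c(0.6, 0.55, 1)
  frac[3, 1] <- 0.4; frac[2, 2] <- 0.45
  series <- structure(frac, heights_um = c(0, 1, 5, 6),
                      t_s = c(0, 5, 10), flagged = rep(FALSE, 3),
                      counts = frac,
                      class = c("fractional_height_series", "matrix"))
  mh <- max_height_trace(series, threshold = 0.1)
  expect_equal(mh$per_frame_um, c(5, 1, 0))
  expect_equal(max_height_trace(series, threshold = 0.1,
                                cycle_bounds_s = c(0, 10))$per_cycle_um, 5)
})

test_that("suppressing the lift lowers the reached height", {
  cfg <- small_config()
  st_lift <- generate_lamellipodium_stack(small_params(seed = 2L), cfg)
  st_flat <- generate_lamellipodium_stack(
    small_params(seed = 2L, lift_profile = function(ph) rep(0, length(ph))),
    cfg)
  h_lift <- max(max_height_trace(fractional_height_series(st_lift))$per_frame_um,
                na.rm = TRUE)
  h_flat <- max(max_height_trace(fractional_height_series(st_flat))$per_frame_um,
                na.rm = TRUE)
  expect_gte(h_lift, 4)
  # an adherent sheet can read as 1-2 um: phase contrast develops over
  # ~1 um of defocus, which bounds the axial resolution of the method
  expect_lte(h_flat, 2)
})
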