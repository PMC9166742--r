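# A ring-shaped test cell whose border intensity is fully controlled.
ring_cell <- function(n = 96, r = 30, border_val = 100, inside_val = 10,
                      arc_split = NULL, arc_vals = c(100, 10)) {
  mask <- make_disk_mask(n, r)
  img <- matrix(inside_val, n, n)
  img[mask == 0] <- inside_val
  rr <- row(img) - 0.5 - n / 2; cc <- col(img) - 0.5 - n / 2
  d <- sqrt(rr^2 + cc^2)
  band <- d >= r - 1.5 & d <= r + 1.5
  if (is.null(arc_split)) {
    img[band] <- border_val
  } else {
    th <- atan2(cc, rr)  # matches the traced arc parameterisation up to phase
    img[band & th >= 0] <- arc_vals[1]
    img[band & th < 0] <- arc_vals[2]
  }
  list(mask = mask, img = img)
}

test_that("border sampling reads controlled intensities", {
  z <- ring_cell(border_val = 100, inside_val = 10)
  o <- trace_outline(z$mask, 1)
  pr <- sample_border_intensity(z$img, o, band_halfwidth_px = 0)
  expect_s3_class(pr, "border_profile")
  expect_equal(mean(pr$raw), 100, tolerance = 0.02)
  expect_true(all(abs(pr$raw - 100) < 10))
  ## arc positions strictly increasing, 0..P
  expect_true(all(diff(pr$arc_um) > 0))
  expect_lt(max(pr$arc_um), pr$perimeter_um)
  ## outline outside the image is a geometry error
  o2 <- o; o2$vertices <- o2$vertices + 80
  expect_error(sample_border_intensity(z$img, o2),
               class = "geometry_error")
})

test_that("a two-level border yields a step profile at the known arc", {
  z <- ring_cell(arc_split = TRUE, arc_vals = c(100, 10))
  o <- trace_outline(z$mask, 1)
  pr <- sample_border_intensity(z$img, o, band_halfwidth_px = 0)
  hi <- pr$raw > 55
  ## half the arc bright, half dark, in two contiguous runs
  expect_equal(mean(hi), 0.5, tolerance = 0.04)
  transitions <- sum(diff(c(hi, hi[1])) != 0)
  expect_identical(transitions, 2L)
})

test_that("cytoplasm reference averages interior regions correctly", {
  mask <- make_disk_mask(96, 35)
  expect_equal(cytoplasm_reference(matrix(7, 96, 96), mask, seed = 2), 7)
  ## noisy image: mean recovered within 3 standard errors
  set.seed(11)
  img <- matrix(5 + rnorm(96 * 96), 96, 96)
  n_px <- 10 * nrow(monolayerq:::disk_offsets(5))
  est <- cytoplasm_reference(img, mask, n_regions = 10, seed = 3)
  expect_lt(abs(est - 5), 3 / sqrt(n_px) * 3)
  ## deterministic given the seed
  expect_identical(est, cytoplasm_reference(img, mask, n_regions = 10,
                                            seed = 3))
  ## tiny mask cannot host a region
  small <- matrix(0, 24, 24); small[11:13, 11:13] <- 1
  expect_error(cytoplasm_reference(img[1:24, 1:24], small, seed = 1),
               class = "geometry_error")
})

test_that("corrected profile follows the (I - c)/I normalisation", {
  mkpr <- function(raw) structure(
    list(cell_id = 1L, arc_um = seq_along(raw), raw = raw,
         perimeter_um = length(raw), corrected = NULL,
         cytoplasm_reference = NA_real_), class = "border_profile")
  c0 <- 40
  expect_true(all(corrected_profile(mkpr(rep(c0, 20)), c0)$corrected == 0))
  expect_true(all(corrected_profile(mkpr(rep(2 * c0, 20)), c0)$corrected ==
                    0.5))
  expect_true(all(corrected_profile(mkpr(rep(c0 / 2, 20)), c0)$corrected ==
                    -1))
  ## bounded above by 1; sign matches I - c
  raw <- c(10, 20, 39, 40, 41, 200, 4000)
  v <- corrected_profile(mkpr(raw), c0)$corrected
  expect_true(all(v < 1))
  expect_identical(sign(v), sign(raw - c0))
  ## near-zero samples are invalidated, all-invalid errors
  v2 <- corrected_profile(mkpr(c(rep(100, 10), 1e-12)), c0)$corrected
  expect_true(is.na(v2[11]))
  expect_error(corrected_profile(mkpr(rep(0, 10)), c0),
               class = "empty_profile")
})

test_that("positivity percentage counts strict positives among valid samples", {
  expect_equal(positivity_percentage(rep(0.5, 10)), 100)
  expect_equal(positivity_percentage(c(1, -1, 2, -2, 1, -1, 2, -2)), 50)
  ## zero counts as non-positive
  expect_equal(positivity_percentage(c(0, 0, 0, 0, 1, 1, 1, 1)), 50)
  ## complementarity is exact
  v <- c(-2, -1, 0, 1e-9, 3, 7, -5, 2, 0.1, -0.1)
  p <- positivity_percentage(v)
  np <- 100 * sum(v <= 0) / length(v)
  expect_identical(p + np, 100)
  expect_error(positivity_percentage(c(1, 2, 3)), class = "empty_profile")
})

test_that("positivity is invariant to intensity scaling and band width", {
  sc <- generate_monolayer(6, c(192, 192), 0.5, seed = 31)
  ## ideal rendering (no noise, no PSF): band width must barely matter
  np0 <- default_noise_params(); np0$psf_sigma_px <- 0
  r <- render_scene(sc, junction_positive_fraction = 0.6,
                    apply_noise = FALSE, regime = "subconfluent",
                    noise_params = np0)
  img <- r$images$junction
  lab <- r$rendered_label_map
  t1 <- junction_image_table(img, lab, 0.5, band_halfwidth_px = 1, seed = 4)
  ## multiplying the channel by a positive constant changes nothing
  t_scaled <- junction_image_table(img * 37, lab, 0.5, band_halfwidth_px = 1,
                                   seed = 4)
  expect_equal(t_scaled$positivity_percent, t1$positivity_percent,
               tolerance = 1e-12)
  ## band halfwidth 1 vs 3 moves the percentage by < 2 points (noiseless)
  t3 <- junction_image_table(img, lab, 0.5, band_halfwidth_px = 3, seed = 4)
  expect_true(all(abs(t3$positivity_percent - t1$positivity_percent) < 2))
  ## and the noiseless measurement matches the per-cell rendered truth
  tr <- r$junction_truth
  m <- merge(t1, tr, by = "cell_id")
  expect_true(all(abs(m$positivity_percent -
                        100 * m$realized_fraction) < 5))
})

test_that("condition tables aggregate per-cell percentages", {
  sc <- generate_monolayer(5, c(160, 160), 0.5, seed = 17)
  hi <- render_scene(sc, junction_positive_fraction = 0.8,
                     apply_noise = FALSE, regime = "subconfluent")
  lo <- render_scene(sc, junction_positive_fraction = 0.2,
                     apply_noise = FALSE, regime = "subconfluent")
  res <- junction_condition_table(
    list(ctrl = list(list(image = hi$images$junction,
                          label_map = hi$rendered_label_map)),
         treated = list(list(image = lo$images$junction,
                             label_map = lo$rendered_label_map))),
    0.5, seed = 2)
  s <- res$summary[order(res$summary$condition), ]
  expect_equal(s$n_cells, c(5, 5))
  diff_pct <- s$mean_percent[s$condition == "ctrl"] -
    s$mean_percent[s$condition == "treated"]
  expect_equal(diff_pct, 60, tolerance = 0.12)
  expect_true(all(res$cells$positivity_percent >= 0 &
                    res$cells$positivity_percent <= 100))
  ## single cell: SEM reported as missing
  one <- junction_condition_table(
    list(solo = list(list(image = hi$images$junction,
                          label_map = (hi$rendered_label_map == 1) * 1))),
    0.5, seed = 2)
  expect_identical(nrow(one$cells), 1L)
  expect_true(is.na(one$summary$sem_percent))
})
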