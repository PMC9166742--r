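test_that("monolayer generation partitions the field deterministically", {
  sc <- generate_monolayer(10, c(128, 128), 0.5, seed = 42)
  expect_s3_class(sc, "synthetic_scene")
  lab <- sc$cell_label_map
  ## labels contiguous 1..n, covering the whole field
  expect_identical(sort(unique(as.vector(lab))), 1:10)
  expect_true(all(lab >= 1))
  expect_length(sc$cell_outlines, 10)
  ## conservation: label areas sum to the field area exactly
  expect_identical(sum(tabulate(lab, 10)), 128L * 128L)
  ## identical seed + parameters -> bit-identical scene
  sc2 <- generate_monolayer(10, c(128, 128), 0.5, seed = 42)
  expect_identical(sc$cell_label_map, sc2$cell_label_map)
  expect_identical(sc$seed_points, sc2$seed_points)
  ## different seed -> different tessellation
  sc3 <- generate_monolayer(10, c(128, 128), 0.5, seed = 43)
  expect_false(identical(sc$cell_label_map, sc3$cell_label_map))
})

test_that("degenerate monolayer parameters are rejected or trivial", {
  expect_error(generate_monolayer(0, c(64, 64), 1, 1),
               class = "invalid_parameter")
  expect_error(generate_monolayer(100, c(64, 64), 1, 1),
               class = "infeasible_geometry")
  ## a single cell owns the whole field; its outline hugs the boundary
  sc1 <- generate_monolayer(1, c(64, 64), 1, seed = 5)
  expect_true(all(sc1$cell_label_map == 1L))
  ap <- polygon_area_perimeter(sc1$cell_outlines[[1]])
  expect_equal(unname(ap[["area_um2"]]), 64^2, tolerance = 0.05)
})

test_that("rendering honours the junction-positive fraction", {
  sc <- generate_monolayer(6, c(192, 192), 0.5, seed = 3)
  ## fully positive, no noise: border pixels strictly brighter than
  ## any cytoplasm pixel of the same cell
  r1 <- render_scene(sc, junction_positive_fraction = 1, apply_noise = FALSE,
                     regime = "subconfluent")
  img <- r1$images$junction
  o <- r1$rendered_outlines[[1]]
  pr <- sample_border_intensity(img, o, band_halfwidth_px = 0)
  cyto <- cytoplasm_reference(img, (r1$rendered_label_map == o$cell_id) * 1,
                              seed = 1)
  expect_true(all(pr$raw > cyto))
  ## half positive: realized fraction within one arc quantum of 0.5
  r5 <- render_scene(sc, junction_positive_fraction = 0.5,
                     apply_noise = FALSE, regime = "subconfluent")
  expect_true(all(abs(r5$junction_truth$realized_fraction - 0.5) < 0.02))
  ## truth intervals agree with an independent polygon-walk of the ring
  iv <- r5$junction_truth_intervals[[1]]
  tot <- sum(apply(iv, 1, function(x) {
    P <- r5$junction_truth$border_length_um[1]
    if (x[2] >= x[1]) x[2] - x[1] else P - x[1] + x[2]
  }))
  expect_equal(tot / r5$junction_truth$border_length_um[1],
               r5$junction_truth$realized_fraction[1], tolerance = 0.02)
  ## determinism of the full rendering
  r5b <- render_scene(sc, junction_positive_fraction = 0.5,
                      apply_noise = FALSE, regime = "subconfluent")
  expect_identical(r5$images, r5b$images)
  rn <- render_scene(sc, junction_positive_fraction = 0.5,
                     apply_noise = TRUE, regime = "subconfluent")
  rnb <- render_scene(sc, junction_positive_fraction = 0.5,
                      apply_noise = TRUE, regime = "subconfluent")
  expect_identical(rn$images, rnb$images)
})

test_that("rendering validates parameters and gap feasibility", {
  sc <- generate_monolayer(4, c(96, 96), 0.5, seed = 9)
  expect_error(render_scene(sc, junction_positive_fraction = 1.2),
               class = "invalid_parameter")
  expect_error(render_scene(sc, fiber_spacing_um = 0.5),
               class = "invalid_parameter")
  expect_error(render_scene(sc, gap_spec = list(list(area_um2 = 2000,
                                                     center = NULL))),
               class = "infeasible_geometry")
})

test_that("a rendered fibre ridge has the PSF-predicted width", {
  ## single isolated fibre: one cell, wide spacing so one ridge dominates;
  ## PSF sigma 2 px. Expected profile sigma: convolution of the intrinsic
  ## ridge (0.3 um = 0.6 px at 0.5 um/px) with the PSF.
  sc <- generate_monolayer(1, c(96, 96), 0.5, seed = 21)
  np <- default_noise_params(); np$psf_sigma_px <- 2
  r <- render_scene(sc, fiber_spacing_um = 30, apply_noise = FALSE,
                    noise_params = np)
  tr <- r$fiber_truth
  ## scan across the ridge through the cell centre
  ln <- place_scan_line(r$rendered_label_map == 1, 0.5, inset_px = 1)
  s <- extract_profile(r$images$actin, ln$p0, ln$p1, 0.5)
  fw_um <- fwhm_oracle(s$pos_um, s$intensity)
  sigma_eff_px <- sqrt(2^2 + (0.3 / 0.5)^2)
  expect_equal(fw_um / 0.5, 2.355 * sigma_eff_px, tolerance = 0.15)
})

test_that("datasets round-trip through TIFF and CSV byte-identically", {
  sc <- generate_monolayer(5, c(96, 96), 0.5, seed = 8)
  r <- render_scene(sc, junction_positive_fraction = 0.6,
                    gap_spec = NULL, apply_noise = TRUE,
                    regime = "subconfluent")
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  write_dataset(list(r, r), d1)
  expect_setequal(list.files(d1),
                  c("field_01.tif", "field_02.tif", "morphology_truth.csv",
                    "junction_truth.csv", "gap_truth.csv", "fiber_truth.csv",
                    "manifest.txt"))
  ## TIFF roundtrip is bit-exact
  back <- read_image_stack(file.path(d1, "field_01.tif"))
  expect_identical(back$junction, r$images$junction)
  expect_identical(back$actin, r$images$actin)
  expect_identical(back$nuclei, r$images$nuclei)
  ## same seed -> byte-identical CSVs
  write_dataset(list(r, r), d2)
  for (f in c("morphology_truth.csv", "junction_truth.csv", "manifest.txt"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  ## empty scene list: warning, manifest only
  d3 <- file.path(tempdir(), "ds3"); unlink(d3, recursive = TRUE)
  expect_warning(write_dataset(list(), d3), "empty")
  expect_identical(list.files(d3), "manifest.txt")
})
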