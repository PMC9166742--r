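## Synthetic multichannel fluorescence scenes of cell monolayers with full
## ground truth. The generator emulates what the downstream analyses need
## from real micrographs: Voronoi-like confluent (or eroded, sub-confluent)
## monolayers, junction staining along borders with a controllable
## positive-arc fraction, carved intercellular gaps, parallel actin stress
## fibres at a controllable spacing, a diffuse cytoplasmic pool in each
## channel, isotropic PSF blur, and Poisson-Gaussian camera noise.

#' Default channel intensity levels (16-bit count scale)
#'
#' Ambient background is kept non-zero (real cameras have an offset) so
#' border samples falling in inter-cell corridors remain valid; the
#' junction cytoplasm level models the diffuse cytoplasmic pool of the
#' junction protein, well above the gap/background class but below border
#' staining, as in real confluent VE-cadherin images.
#'
#' @return named list of intensity levels.
#' @export
default_channel_intensities <- function() {
  list(ambient = 5,
       junction_cytoplasm = 120,
       junction_border = 220,
       actin_cytoplasm = 40,
       fiber_amplitude = 180,
       nucleus_amplitude = 200)
}

#' Default PSF/noise parameters
#'
#' @return list with `psf_sigma_px` (Gaussian PSF sigma), `gain` (counts per
#'   photon) and `read_sd` (additive read-noise sigma, counts).
#' @export
default_noise_params <- function() {
  list(psf_sigma_px = 1.0, gain = 2.0, read_sd = 3.0)
}

#' Generate the geometry of a synthetic cell monolayer
#'
#' Seeds `n_cells` uniform random points in the field, assigns every pixel
#' to its nearest seed (discrete Voronoi tessellation) and applies
#' `relaxation_steps` Lloyd iterations (seeds moved to region centroids and
#' reassigned), which yields roughly convex, evenly sized cells resembling
#' an endothelial monolayer. Outlines are traced per region at sub-pixel
#' resolution.
#'
#' @param n_cells number of cells (>= 1).
#' @param field_shape integer (rows, cols) of the field in pixels.
#' @param pixel_size_um micrometres per pixel.
#' @param seed RNG seed; the same (parameters, seed) reproduce the scene
#'   bit-identically.
#' @param relaxation_steps Lloyd relaxation iterations (default 2).
#' @return a `synthetic_scene` with `cell_label_map` (1..n over the whole
#'   field), `cell_outlines`, seed points, and parameters.
#' @export
generate_monolayer <- function(n_cells, field_shape = c(512L, 512L),
                               pixel_size_um = 0.5, seed = 1L,
                               relaxation_steps = 2L) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1 ||
      n_cells != round(n_cells))
    stop_mlq("n_cells must be a positive integer", "invalid_parameter")
  n_cells <- as.integer(n_cells)
  nr <- as.integer(field_shape[1L]); nc <- as.integer(field_shape[2L])
  if (nr * nc / n_cells < 100)
    stop_mlq("field too small: mean cell area would be < 100 px",
             "infeasible_geometry")
  lab <- with_seed(seed, {
    sr <- runif(n_cells, 0, nr); sc <- runif(n_cells, 0, nc)
    lab <- voronoi_labels(sr, sc, nr, nc)
    steps <- as.integer(relaxation_steps)
    for (it in seq_len(max(0L, steps))) {
      for (k in seq_len(n_cells)) {
        idx <- which(lab == k, arr.ind = TRUE)
        if (nrow(idx) > 0L) {
          sr[k] <- mean(idx[, 1L] - 0.5); sc[k] <- mean(idx[, 2L] - 0.5)
        }
      }
      lab <- voronoi_labels(sr, sc, nr, nc)
    }
    lab <- enforce_connected(lab)
    attr(lab, "seeds") <- cbind(row = sr, col = sc)
    lab
  })
  seeds <- attr(lab, "seeds"); attr(lab, "seeds") <- NULL
  outlines <- lapply(seq_len(n_cells), function(k)
    trace_outline((lab == k) * 1, pixel_size_um, cell_id = k))
  structure(list(field_shape = c(nr, nc),
                 pixel_size_um = pixel_size_um,
                 n_cells = n_cells,
                 cell_label_map = lab,
                 cell_outlines = outlines,
                 seed_points = seeds,
                 seed = as.integer(seed),
                 relaxation_steps = as.integer(relaxation_steps),
                 noise_params = default_noise_params()),
            class = "synthetic_scene")
}

## Nearest-seed label assignment, one distance map per seed to bound memory.
#' @keywords internal
#' @noRd
voronoi_labels <- function(sr, sc, nr, nc) {
  best <- matrix(Inf, nr, nc)
  lab <- matrix(0L, nr, nc)
  rr <- (1:nr) - 0.5; cc <- (1:nc) - 0.5
  for (k in seq_along(sr)) {
    d2 <- outer((rr - sr[k])^2, (cc - sc[k])^2, "+")
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab[upd] <- k
  }
  lab
}

## Discrete nearest-seed assignment can pinch a thin region into separate
## pixel groups along bisector ties; keep each label's largest component and
## regrow the stray pixels from their 4-neighbourhoods (deterministic
## row-major order).
#' @keywords internal
#' @noRd
enforce_connected <- function(lab) {
  n_lab <- max(lab)
  for (k in seq_len(n_lab)) {
    comp <- EBImage::bwlabel(lab == k)
    if (max(comp) > 1L) {
      sizes <- tabulate(comp[comp > 0], max(comp))
      lab[comp > 0 & comp != which.max(sizes)] <- 0L
    }
  }
  nr <- nrow(lab); nc <- ncol(lab)
  while (any(lab == 0L)) {
    idx <- which(lab == 0L, arr.ind = TRUE)
    changed <- FALSE
    for (j in seq_len(nrow(idx))) {
      i <- idx[j, 1L]; c_ <- idx[j, 2L]
      nb <- c(if (i > 1L) lab[i - 1L, c_], if (i < nr) lab[i + 1L, c_],
              if (c_ > 1L) lab[i, c_ - 1L], if (c_ < nc) lab[i, c_ + 1L])
      nb <- nb[nb > 0L]
      if (length(nb)) { lab[i, c_] <- nb[1L]; changed <- TRUE }
    }
    if (!changed) break  # isolated zeros with no labelled neighbour
  }
  lab
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene: %d cells, %dx%d px, %.3g um/px, seed %d%s>\n",
              x$n_cells, x$field_shape[1L], x$field_shape[2L],
              x$pixel_size_um, x$seed,
              if (!is.null(x$images)) ", rendered" else ""))
  invisible(x)
}

#' Render a synthetic scene into multichannel images with ground truth
#'
#' Paints the junction channel (cytoplasmic pool plus bright border pixels
#' on the positive arc intervals; gaps carved as background-level corridors
#' between cells), the actin channel (parallel ridges at the stated spacing,
#' oriented along each cell's major axis so that line scans along the minor
#' axis cross them perpendicularly), and a nuclei channel (one Gaussian blob
#' per cell). All channels are convolved with a Gaussian PSF and, if
#' requested, corrupted by Poisson shot noise plus additive read noise.
#' Images are quantised to integer counts (16-bit range).
#'
#' In the `"subconfluent"` regime every cell region is eroded by
#' `erode_margin_px`, opening border-wide separations between neighbours
#' (junction maturation experiments); in the `"confluent"` regime cells
#' share borders except where `gap_spec` carves corridors (junction opening
#' experiments).
#'
#' @param scene a `synthetic_scene` from [generate_monolayer()].
#' @param junction_positive_fraction fraction of each cell's border arc
#'   rendered junction-positive, in [0, 1].
#' @param gap_spec optional list of gaps, each `list(area_um2 =, center =)`
#'   with `center` an optional (row, col) in pixels; when `center` is NULL a
#'   seeded random interior border location is used.
#' @param fiber_spacing_um spacing of parallel actin ridges (>= 2 px).
#' @param channel_intensities see [default_channel_intensities()].
#' @param apply_noise logical; apply the Poisson-Gaussian camera model.
#' @param regime `"confluent"` or `"subconfluent"`.
#' @param erode_margin_px erosion margin for the sub-confluent regime.
#' @param n_positive_arcs number of positive arc intervals per cell.
#' @param noise_params see [default_noise_params()].
#' @return the scene with `images` (list junction/actin/nuclei of integer
#'   matrices), `rendered_label_map`, `rendered_outlines`,
#'   `junction_truth` (per cell: target and realized positive fraction and
#'   arc intervals), `gap_truth` (per gap: centre, realized area),
#'   `fiber_truth` (per cell: spacing, orientation, count).
#' @export
render_scene <- function(scene,
                         junction_positive_fraction = 1,
                         gap_spec = NULL,
                         fiber_spacing_um = 5,
                         channel_intensities = default_channel_intensities(),
                         apply_noise = TRUE,
                         regime = c("confluent", "subconfluent"),
                         erode_margin_px = 3L,
                         n_positive_arcs = 2L,
                         noise_params = scene$noise_params) {
  stopifnot(inherits(scene, "synthetic_scene"))
  regime <- match.arg(regime)
  f <- junction_positive_fraction
  if (!is.numeric(f) || f < 0 || f > 1)
    stop_mlq("junction_positive_fraction must be in [0, 1]",
             "invalid_parameter")
  px <- scene$pixel_size_um
  if (fiber_spacing_um < 2 * px)
    stop_mlq("fiber_spacing_um must be >= 2 pixels", "invalid_parameter")
  nr <- scene$field_shape[1L]; nc <- scene$field_shape[2L]
  ci <- utils::modifyList(default_channel_intensities(),
                          as.list(channel_intensities))
  np <- utils::modifyList(default_noise_params(), as.list(noise_params))

  with_seed(scene$seed + 1000003L, {
    ## --- rendered geometry -------------------------------------------------
    if (regime == "subconfluent") {
      m <- as.integer(erode_margin_px)
      brush <- EBImage::makeBrush(2L * m + 1L, shape = "disc")
      lab_r <- matrix(0L, nr, nc)
      for (k in seq_len(scene$n_cells)) {
        er <- EBImage::erode((scene$cell_label_map == k) * 1, brush)
        lab_r[er > 0] <- k
      }
      ## erosion also applies at the field edge, so edge-adjacent arcs face
      ## a background corridor like any other cell-cell separation
      lab_r[c(seq_len(m), nr - seq_len(m) + 1L), ] <- 0L
      lab_r[, c(seq_len(m), nc - seq_len(m) + 1L)] <- 0L
    } else {
      lab_r <- scene$cell_label_map
    }
    keep <- vapply(seq_len(scene$n_cells), function(k) sum(lab_r == k) >= 25,
                   logical(1))
    outlines_r <- vector("list", scene$n_cells)
    for (k in which(keep)) {
      outlines_r[[k]] <- tryCatch(
        trace_outline((lab_r == k) * 1, px, cell_id = k),
        monolayerq_error = function(e) NULL)
    }
    keep <- keep & !vapply(outlines_r, is.null, logical(1))

    ## --- junction channel --------------------------------------------------
    junction <- matrix(ci$ambient, nr, nc)
    junction[lab_r > 0] <- ci$junction_cytoplasm
    jt_rows <- list(); jt_intervals <- list()
    border_r <- 2  # paint radius (px): ~2 um junction band at 0.5 um/px
    off_b <- disk_offsets(border_r)
    for (k in which(keep)) {
      rs <- resample_ring(outlines_r[[k]]$vertices, step = 1)
      nsamp <- length(rs$arc)
      pos <- positive_arc_mask(rs$arc, rs$perimeter, f, n_positive_arcs)
      if (any(pos)) {
        pr <- round(rs$row[pos] + 0.5); pc <- round(rs$col[pos] + 0.5)
        for (d in seq_len(nrow(off_b))) {
          ir <- pmin(pmax(pr + off_b$dr[d], 1L), nr)
          ic <- pmin(pmax(pc + off_b$dc[d], 1L), nc)
          junction[cbind(ir, ic)] <- ci$junction_border
        }
      }
      jt_rows[[length(jt_rows) + 1L]] <- data.frame(
        cell_id = k, target_fraction = f,
        realized_fraction = sum(pos) / nsamp,
        border_length_um = rs$perimeter * px)
      jt_intervals[[as.character(k)]] <- arc_intervals(rs$arc, pos) * px
    }
    junction_truth <- if (length(jt_rows)) do.call(rbind, jt_rows) else
      data.frame(cell_id = integer(0), target_fraction = numeric(0),
                 realized_fraction = numeric(0), border_length_um = numeric(0))

    ## --- gaps --------------------------------------------------------------
    gap_truth <- data.frame(gap_id = integer(0), center_row = numeric(0),
                            center_col = numeric(0), area_um2 = numeric(0))
    if (!is.null(gap_spec) && length(gap_spec)) {
      mean_cell_px <- nr * nc / scene$n_cells
      ## interior border pixels (between two cells, away from the field edge)
      bmask <- border_pixels(lab_r)
      margin <- ceiling(sqrt(max(vapply(gap_spec, function(g) g$area_um2,
                                        numeric(1))) / pi) / px) + 6L
      idx <- which(bmask, arr.ind = TRUE)
      idx <- idx[idx[, 1L] > margin & idx[, 1L] <= nr - margin &
                 idx[, 2L] > margin & idx[, 2L] <= nc - margin, , drop = FALSE]
      placed <- matrix(numeric(0), 0, 3)  # row, col, radius (px)
      for (g in seq_along(gap_spec)) {
        area <- gap_spec[[g]]$area_um2
        r_px <- sqrt(area / pi) / px
        if (pi * r_px^2 > 0.25 * mean_cell_px)
          stop_mlq("gap larger than the available inter-cell corridor",
                   "infeasible_geometry")
        ctr <- gap_spec[[g]]$center
        if (is.null(ctr)) {
          if (nrow(idx) == 0L)
            stop_mlq("no interior border location available for gap",
                     "infeasible_geometry")
          ## keep gap regions mutually disjoint (with clearance for the
          ## staining-retraction annulus)
          for (try in seq_len(200L)) {
            pick <- idx[sample.int(nrow(idx), 1L), ]
            cand <- c(pick[1L] - 0.5, pick[2L] - 0.5)
            clear <- nrow(placed) == 0L ||
              all(sqrt((placed[, 1L] - cand[1L])^2 +
                       (placed[, 2L] - cand[2L])^2) >
                  placed[, 3L] + r_px + 6)
            if (clear) { ctr <- cand; break }
          }
          if (is.null(ctr))
            stop_mlq("could not place mutually disjoint gaps",
                     "infeasible_geometry")
        }
        placed <- rbind(placed, c(ctr, r_px))
        ## junction staining retracts from the gap edge: an annulus around
        ## the gap reverts to the cytoplasmic level before the gap proper
        ## is carved to background
        offs_a <- disk_offsets(r_px + 2)
        ir <- round(ctr[1L] + 0.5) + offs_a$dr
        ic <- round(ctr[2L] + 0.5) + offs_a$dc
        ok <- ir >= 1L & ir <= nr & ic >= 1L & ic <= nc
        junction[cbind(ir[ok], ic[ok])] <- ci$junction_cytoplasm
        offs <- disk_offsets(r_px)
        ir <- round(ctr[1L] + 0.5) + offs$dr; ic <- round(ctr[2L] + 0.5) + offs$dc
        ok <- ir >= 1L & ir <= nr & ic >= 1L & ic <= nc
        junction[cbind(ir[ok], ic[ok])] <- ci$ambient
        gap_truth <- rbind(gap_truth, data.frame(
          gap_id = g, center_row = ctr[1L], center_col = ctr[2L],
          area_um2 = sum(ok) * px^2))
      }
    }

    ## --- actin channel -----------------------------------------------------
    actin <- matrix(ci$ambient, nr, nc)
    actin[lab_r > 0] <- ci$actin_cytoplasm
    fiber_sigma_px <- 0.3 / px  # stress-fibre half-width ~0.3 um
    spacing_px <- fiber_spacing_um / px
    ft_rows <- list()
    for (k in which(keep)) {
      el <- equivalent_ellipse((lab_r == k) * 1, px)
      theta <- el$orientation  # major-axis direction; fibres run along it
      mdir <- c(-sin(theta), cos(theta))  # minor-axis (distance) direction
      idxk <- which(lab_r == k, arr.ind = TRUE)
      d <- (idxk[, 1L] - 0.5 - el$centroid["row"]) * mdir[1L] +
           (idxk[, 2L] - 0.5 - el$centroid["col"]) * mdir[2L]
      phase <- runif(1, 0, spacing_px)
      u <- (d - phase) / spacing_px
      frac <- u - round(u)  # signed distance to nearest fibre, in spacings
      amp <- ci$fiber_amplitude *
        exp(-(frac * spacing_px)^2 / (2 * fiber_sigma_px^2))
      actin[idxk] <- actin[idxk] + amp
      n_fibers <- length(unique(round(u)))
      ft_rows[[length(ft_rows) + 1L]] <- data.frame(
        cell_id = k, spacing_um = fiber_spacing_um,
        orientation = theta, n_fibers = n_fibers, phase_px = phase)
    }
    fiber_truth <- if (length(ft_rows)) do.call(rbind, ft_rows) else
      data.frame(cell_id = integer(0), spacing_um = numeric(0),
                 orientation = numeric(0), n_fibers = integer(0),
                 phase_px = numeric(0))

    ## --- nuclei channel ----------------------------------------------------
    nuclei <- matrix(ci$ambient, nr, nc)
    for (k in which(keep)) {
      el <- equivalent_ellipse((lab_r == k) * 1, px)
      sig <- max(2, el$minor_um / px / 6)
      offs <- disk_offsets(3 * sig)
      ir <- round(el$centroid["row"] + 0.5) + offs$dr
      ic <- round(el$centroid["col"] + 0.5) + offs$dc
      ok <- ir >= 1L & ir <= nr & ic >= 1L & ic <= nc
      d2 <- (offs$dr^2 + offs$dc^2)[ok]
      cells <- cbind(ir[ok], ic[ok])
      nuclei[cells] <- nuclei[cells] +
        ci$nucleus_amplitude * exp(-d2 / (2 * sig^2))
    }

    ## --- PSF + noise -------------------------------------------------------
    imgs <- list(junction = junction, actin = actin, nuclei = nuclei)
    if (np$psf_sigma_px > 0)
      imgs <- lapply(imgs, function(im)
        EBImage::gblur(im, sigma = np$psf_sigma_px, boundary = "replicate"))
    if (isTRUE(apply_noise))
      imgs <- lapply(imgs, function(im) {
        counts <- stats::rpois(length(im), pmax(im, 0) / np$gain) * np$gain
        matrix(counts + stats::rnorm(length(im), 0, np$read_sd),
               nrow(im), ncol(im))
      })
    imgs <- lapply(imgs, function(im)
      matrix(pmin(pmax(round(im), 0), 65535), nrow(im), ncol(im)))

    scene$images <- imgs
    scene$regime <- regime
    scene$rendered_label_map <- lab_r
    scene$rendered_outlines <- outlines_r[keep]
    scene$junction_truth <- junction_truth
    scene$junction_truth_intervals <- jt_intervals
    scene$gap_truth <- gap_truth
    scene$fiber_truth <- fiber_truth
    scene$noise_params <- np
    scene$apply_noise <- isTRUE(apply_noise)
    scene$channel_intensities <- ci
    scene
  })
}

## Mark border samples as junction-positive: `n_arcs` equal intervals of
## total fraction f, evenly spaced with a random phase.
#' @keywords internal
#' @noRd
positive_arc_mask <- function(arc, perimeter, f, n_arcs) {
  if (f >= 1) return(rep(TRUE, length(arc)))
  if (f <= 0) return(rep(FALSE, length(arc)))
  n_arcs <- max(1L, as.integer(n_arcs))
  phase <- runif(1, 0, perimeter)
  u <- ((arc - phase) %% perimeter) / perimeter  # in [0,1)
  frac_in_period <- (u * n_arcs) %% 1
  frac_in_period < f
}

## Arc intervals (start, end) of TRUE runs in a circular sample mask.
#' @keywords internal
#' @noRd
arc_intervals <- function(arc, pos) {
  if (!any(pos)) return(matrix(numeric(0), 0, 2))
  if (all(pos)) return(matrix(c(0, arc[length(arc)]), 1, 2))
  d <- diff(c(pos[length(pos)], pos))
  starts <- which(d == 1); ends <- which(d == -1) - 1L
  if (length(ends) && length(starts) && ends[1L] < starts[1L])
    ends <- c(ends[-1L], ends[1L])
  cbind(start = arc[starts], end = arc[ends])
}

## Pixels whose 4-neighbourhood contains a different positive label
## (interior cell-cell borders).
#' @keywords internal
#' @noRd
border_pixels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  b <- matrix(FALSE, nr, nc)
  b[-nr, ] <- b[-nr, ] | (lab[-nr, ] != lab[-1L, ] & lab[-nr, ] > 0 & lab[-1L, ] > 0)
  b[-1L, ] <- b[-1L, ] | (lab[-1L, ] != lab[-nr, ] & lab[-1L, ] > 0 & lab[-nr, ] > 0)
  b[, -nc] <- b[, -nc] | (lab[, -nc] != lab[, -1L] & lab[, -nc] > 0 & lab[, -1L] > 0)
  b[, -1L] <- b[, -1L] | (lab[, -1L] != lab[, -nc] & lab[, -1L] > 0 & lab[, -nc] > 0)
  b
}

#' Write a rendered dataset (TIFFs, truth tables, manifest) to disk
#'
#' One multipage 16-bit TIFF per field (page order junction, actin, nuclei)
#' plus CSV ground-truth tables pooled across fields and a flat key=value
#' manifest. Counts are stored as value/65535 in the TIFF and recovered
#' exactly by [read_image_stack()].
#'
#' @param scenes a rendered `synthetic_scene` or list of them.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest as a named character vector.
#' @export
write_dataset <- function(scenes, out_dir) {
  if (inherits(scenes, "synthetic_scene")) scenes <- list(scenes)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop_mlq(sprintf("cannot create output directory '%s'", out_dir),
             "io_error")
  if (length(scenes) == 0L) {
    warning("empty scene list: writing empty manifest only", call. = FALSE)
    writeLines("n_fields=0", file.path(out_dir, "manifest.txt"))
    return(invisible(c(n_fields = "0")))
  }
  morph <- list(); junc <- list(); gaps <- list(); fibs <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    if (is.null(sc$images))
      stop_mlq("scene has no rendered images; call render_scene() first",
               "invalid_parameter")
    fname <- sprintf("field_%02d.tif", i)
    tiff::writeTIFF(lapply(sc$images, function(m) m / 65535),
                    file.path(out_dir, fname), bits.per.sample = 16L)
    px <- sc$pixel_size_um
    lab <- sc$rendered_label_map
    ids <- sort(setdiff(unique(as.vector(lab)), 0))
    morph[[i]] <- do.call(rbind, lapply(ids, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      data.frame(field = i, cell_id = k,
                 area_um2 = nrow(idx) * px^2,
                 centroid_row = mean(idx[, 1L] - 0.5),
                 centroid_col = mean(idx[, 2L] - 0.5))
    }))
    add_field <- function(df) if (nrow(df)) cbind(field = i, df) else NULL
    junc[[i]] <- add_field(sc$junction_truth)
    gaps[[i]] <- add_field(sc$gap_truth)
    fibs[[i]] <- add_field(sc$fiber_truth)
  }
  wcsv <- function(lst, name) {
    df <- do.call(rbind, lst[!vapply(lst, is.null, logical(1))])
    if (is.null(df)) df <- data.frame(field = integer(0))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(morph, "morphology_truth.csv")
  wcsv(junc, "junction_truth.csv")
  wcsv(gaps, "gap_truth.csv")
  wcsv(fibs, "fiber_truth.csv")
  s1 <- scenes[[1L]]
  manifest <- c(n_fields = length(scenes),
                field_rows = s1$field_shape[1L],
                field_cols = s1$field_shape[2L],
                pixel_size_um = s1$pixel_size_um,
                channel_order = "junction,actin,nuclei",
                regime = if (is.null(s1$regime)) NA else s1$regime,
                seed = s1$seed,
                psf_sigma_px = s1$noise_params$psf_sigma_px,
                gain = s1$noise_params$gain,
                read_sd = s1$noise_params$read_sd,
                noise = as.character(isTRUE(s1$apply_noise)))
  writeLines(paste0(names(manifest), "=", manifest),
             file.path(out_dir, "manifest.txt"))
  invisible(manifest)
}
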