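## Junction-protein border profiling: raw intensity along the cell border,
## cytoplasm-referenced corrected profile, and percent-positive staining.
##
## The corrected value at border sample i is v_i = (I_i - Icyto) / I_i:
## the cytoplasm-subtracted intensity normalised pixel by pixel by the
## border intensity itself. Its sign marks junctional staining (positive,
## border brighter than cytoplasm) versus inter-cell gaps (negative), and
## it is bounded above by 1.

#' Sample junction-channel intensity along a cell border
#'
#' The outline is resampled at uniform arc-length steps; at each sample the
#' intensity is the mean over a band of +/- `band_halfwidth_px` pixels along
#' the local normal (bilinear interpolation).
#'
#' @param image junction-channel matrix.
#' @param outline a `cell_outline`.
#' @param band_halfwidth_px half-width of the sampling band in pixels.
#' @param step_px arc-length sampling step in pixels (default 1).
#' @return a `border_profile`: list with `cell_id`, `arc_um`, `raw`,
#'   `perimeter_um`, plus placeholders for the corrected profile.
#' @export
sample_border_intensity <- function(image, outline, band_halfwidth_px = 1L,
                                    step_px = 1) {
  stopifnot(inherits(outline, "cell_outline"))
  if (band_halfwidth_px < 0)
    stop_mlq("band_halfwidth_px must be >= 0", "invalid_parameter")
  v <- outline$vertices
  if (min(v) < -0.5 || max(v[, 1L]) > nrow(image) + 0.5 ||
      max(v[, 2L]) > ncol(image) + 0.5)
    stop_mlq("outline exits image bounds", "geometry_error")
  rs <- resample_ring(v, step = step_px)
  ## inward/outward normal = tangent rotated 90 degrees
  nr_ <- -rs$tcol; nc_ <- rs$trow
  offs <- seq(-band_halfwidth_px, band_halfwidth_px, by = 1)
  acc <- 0
  for (o in offs)
    acc <- acc + interp_bilinear(image, rs$row + o * nr_, rs$col + o * nc_)
  raw <- acc / length(offs)
  structure(list(cell_id = outline$cell_id,
                 arc_um = rs$arc * outline$pixel_size_um,
                 raw = raw,
                 perimeter_um = rs$perimeter * outline$pixel_size_um,
                 corrected = NULL, cytoplasm_reference = NA_real_),
            class = "border_profile")
}

#' Mean cytoplasmic intensity from seeded random interior regions
#'
#' Averages the image over `n_regions` random disks placed fully inside the
#' cell mask eroded by `band_halfwidth_px + region_radius_px`, so no disk
#' overlaps the border band.
#'
#' @param image intensity matrix.
#' @param mask binary mask of the cell.
#' @param n_regions number of disks (default 5).
#' @param region_radius_px disk radius in pixels (default 5).
#' @param band_halfwidth_px border-band half-width to stay clear of.
#' @param seed RNG seed for the disk placement.
#' @return scalar mean intensity.
#' @export
cytoplasm_reference <- function(image, mask, n_regions = 5L,
                                region_radius_px = 5L,
                                band_halfwidth_px = 1L, seed = 1L) {
  mask <- (as.matrix(mask) > 0) * 1
  er_r <- band_halfwidth_px + region_radius_px
  brush <- EBImage::makeBrush(2L * as.integer(er_r) + 1L, shape = "disc")
  inner <- EBImage::erode(mask, brush)
  cand <- which(inner > 0, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    stop_mlq("cell too small to place any cytoplasm region",
             "geometry_error")
  offs <- disk_offsets(region_radius_px)
  with_seed(seed, {
    pick <- cand[sample.int(nrow(cand), n_regions, replace = TRUE), ,
                 drop = FALSE]
    vals <- numeric(0)
    nr <- nrow(image); nc <- ncol(image)
    for (j in seq_len(nrow(pick))) {
      ir <- pick[j, 1L] + offs$dr; ic <- pick[j, 2L] + offs$dc
      ok <- ir >= 1L & ir <= nr & ic >= 1L & ic <= nc
      vals <- c(vals, image[cbind(ir[ok], ic[ok])])
    }
    mean(vals)
  })
}

#' Cytoplasm-referenced, border-normalised corrected profile
#'
#' v_i = (I_i - Icyto) / I_i per border sample; positive where the border is
#' brighter than the cytoplasm (junctional staining), negative where it is
#' darker (gap between cells). Samples with raw intensity below
#' `eps_fraction` of the profile maximum are marked invalid (NA).
#'
#' @param profile a `border_profile` from [sample_border_intensity()].
#' @param cyto_ref scalar mean cytoplasm intensity.
#' @param eps_fraction validity floor as a fraction of the profile maximum.
#' @return the profile with `corrected` and `cytoplasm_reference` filled in.
#' @export
corrected_profile <- function(profile, cyto_ref, eps_fraction = 1e-6) {
  stopifnot(inherits(profile, "border_profile"))
  raw <- profile$raw
  eps <- eps_fraction * max(raw, na.rm = TRUE)
  valid <- is.finite(raw) & raw >= eps & raw > 0
  if (!any(valid))
    stop_mlq("all border samples invalid", "empty_profile")
  v <- rep(NA_real_, length(raw))
  v[valid] <- (raw[valid] - cyto_ref) / raw[valid]
  profile$corrected <- v
  profile$cytoplasm_reference <- cyto_ref
  profile
}

#' Percent of border samples with positive corrected intensity
#'
#' 100 x (number of valid samples with v > 0) / (number of valid samples);
#' v = 0 counts as non-positive.
#'
#' @param profile a `border_profile` with a corrected profile, or a numeric
#'   vector of corrected values.
#' @param min_valid minimum number of valid samples required (default 8).
#' @return percentage in [0, 100].
#' @export
positivity_percentage <- function(profile, min_valid = 8L) {
  v <- if (inherits(profile, "border_profile")) profile$corrected else profile
  if (is.null(v)) stop_mlq("profile has no corrected values", "empty_profile")
  v <- v[is.finite(v)]
  if (length(v) < min_valid)
    stop_mlq(sprintf("only %d valid samples (< %d)", length(v), min_valid),
             "empty_profile")
  100 * sum(v > 0) / length(v)
}

#' Per-cell junction positivity for one image
#'
#' @param image junction-channel matrix.
#' @param label_map integer label image of cells (0 background).
#' @param pixel_size_um micrometres per pixel.
#' @param band_halfwidth_px border band half-width.
#' @param n_regions,region_radius_px cytoplasm sampling parameters.
#' @param seed seed for cytoplasm region placement (offset per cell).
#' @return data.frame (cell_id, positivity_percent, cytoplasm_reference,
#'   perimeter_um); failing cells skipped with a warning.
#' @export
junction_image_table <- function(image, label_map, pixel_size_um,
                                 band_halfwidth_px = 1L, n_regions = 5L,
                                 region_radius_px = 5L, seed = 1L) {
  ids <- sort(setdiff(unique(as.vector(label_map)), 0))
  rows <- list()
  for (k in ids) {
    row <- tryCatch({
      mask <- (label_map == k) * 1
      o <- trace_outline(mask, pixel_size_um, cell_id = k)
      pr <- sample_border_intensity(image, o, band_halfwidth_px)
      cr <- cytoplasm_reference(image, mask, n_regions, region_radius_px,
                                band_halfwidth_px, seed = seed + k)
      pr <- corrected_profile(pr, cr)
      data.frame(cell_id = k,
                 positivity_percent = positivity_percentage(pr),
                 cytoplasm_reference = cr,
                 perimeter_um = pr$perimeter_um)
    }, monolayerq_error = function(e) {
      warning(sprintf("junction analysis skipped cell %d: %s", k,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    rows[[length(rows) + 1L]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(cell_id = integer(0), positivity_percent = numeric(0),
                      cytoplasm_reference = numeric(0),
                      perimeter_um = numeric(0)))
  do.call(rbind, rows)
}

#' Junction positivity across conditions
#'
#' @param datasets named list (one element per condition); each element is a
#'   list of per-image inputs `list(image =, label_map =)`.
#' @param pixel_size_um micrometres per pixel.
#' @param ... passed to [junction_image_table()].
#' @return list with `cells` (condition, image_id, cell_id,
#'   positivity_percent) and `summary` (condition, n_cells, mean_percent,
#'   sem_percent; SEM is NA for n = 1).
#' @export
junction_condition_table <- function(datasets, pixel_size_um, ...) {
  cells <- list()
  for (cond in names(datasets)) {
    for (i in seq_along(datasets[[cond]])) {
      d <- datasets[[cond]][[i]]
      tab <- junction_image_table(d$image, d$label_map, pixel_size_um, ...)
      if (nrow(tab))
        cells[[length(cells) + 1L]] <- cbind(condition = cond, image_id = i,
                                             tab)
    }
  }
  if (!length(cells)) {
    warning("no valid cells in any condition", call. = FALSE)
    return(list(cells = data.frame(), summary = data.frame()))
  }
  cells <- do.call(rbind, cells)
  summary <- do.call(rbind, lapply(split(cells, cells$condition), function(d)
    data.frame(condition = d$condition[1L], n_cells = nrow(d),
               mean_percent = mean(d$positivity_percent),
               sem_percent = if (nrow(d) > 1L)
                 stats::sd(d$positivity_percent) / sqrt(nrow(d))
               else NA_real_)))
  rownames(summary) <- NULL
  list(cells = cells, summary = summary)
}
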