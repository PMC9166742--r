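## Intercellular gap quantification in confluent-monolayer junction images:
## the junction staining is binarized, closed morphologically, and
## background components enclosed by staining (not touching the image
## border) are counted and measured as gaps.

#' Segment intercellular gaps in a junction-channel image
#'
#' Foreground = junction staining binarized by `threshold_method`, then
#' morphologically closed with a disc of `closing_radius_px`. Gaps are the
#' connected background components that do not touch the image border, with
#' area >= `min_gap_area_um2`. Border-touching background is excluded
#' because it is out-of-monolayer background, not an enclosed intercellular
#' gap.
#'
#' The default `"median_fraction"` threshold calls a pixel background when
#' it is darker than `median_fraction` x the image median. Confluent
#' junction images have three intensity classes (dark gap corridors, the
#' diffuse cytoplasmic pool, bright border staining); the median sits in
#' the dominant cytoplasm class, so half of it separates true gaps from
#' stained monolayer regardless of how much border staining is present.
#' Two-class Otsu is also available but is bistable on such images: when
#' gaps are scarce it splits cytoplasm from border instead and misreads
#' every cell interior as background.
#'
#' @param image junction-channel matrix.
#' @param pixel_size_um micrometres per pixel.
#' @param min_gap_area_um2 smallest gap retained (default 5).
#' @param threshold_method `"median_fraction"` (default), `"otsu"`, or a
#'   fixed numeric threshold.
#' @param median_fraction fraction of the image median used by the
#'   `"median_fraction"` method (default 0.5).
#' @param closing_radius_px disc radius for morphological closing.
#' @return data.frame (gap_id, area_um2, centroid_row, centroid_col) with
#'   attribute `label_map` holding the gap label image.
#' @export
segment_gaps <- function(image, pixel_size_um, min_gap_area_um2 = 5,
                         threshold_method = "median_fraction",
                         median_fraction = 0.5, closing_radius_px = 2L) {
  rng <- range(image)
  if (diff(rng) == 0)
    stop_mlq("constant image: cannot threshold", "thresholding_error")
  if (is.numeric(threshold_method)) {
    thr <- threshold_method
  } else if (identical(threshold_method, "median_fraction")) {
    thr <- median_fraction * stats::median(image)
  } else if (identical(threshold_method, "otsu")) {
    sc <- (image - rng[1L]) / diff(rng)
    thr <- rng[1L] + diff(rng) *
      EBImage::otsu(EBImage::Image(sc), range = c(0, 1))
  } else {
    stop_mlq(sprintf("unknown threshold_method '%s'", threshold_method),
             "invalid_parameter")
  }
  fg <- (image > thr) * 1
  if (closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L,
                                shape = "disc")
    fg <- EBImage::closing(fg, brush)
  }
  bg <- EBImage::bwlabel(1 - fg)
  nr <- nrow(bg); nc <- ncol(bg)
  touching <- unique(c(bg[1L, ], bg[nr, ], bg[, 1L], bg[, nc]))
  ids <- setdiff(seq_len(max(bg)), c(0, touching))
  min_px <- min_gap_area_um2 / pixel_size_um^2
  rows <- list(); keep_map <- matrix(0L, nr, nc); next_id <- 0L
  for (k in ids) {
    idx <- which(bg == k, arr.ind = TRUE)
    if (nrow(idx) >= min_px) {
      next_id <- next_id + 1L
      keep_map[idx] <- next_id
      rows[[next_id]] <- data.frame(
        gap_id = next_id,
        area_um2 = nrow(idx) * pixel_size_um^2,
        centroid_row = mean(idx[, 1L] - 0.5),
        centroid_col = mean(idx[, 2L] - 0.5))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gap_id = integer(0), area_um2 = numeric(0),
               centroid_row = numeric(0), centroid_col = numeric(0))
  attr(out, "label_map") <- keep_map
  attr(out, "threshold") <- thr
  out
}

#' Summarise gaps: count, open-area percentage, size distribution
#'
#' Open-area percentage is 100 x total gap area / analyzed field area. The
#' histogram uses right-open bins, with the last bin right-closed; gaps
#' outside all bins are counted in an overflow bin with a warning.
#'
#' @param gaps data.frame from [segment_gaps()] (or with an `area_um2`
#'   column), possibly pooled over images.
#' @param field_area_um2 total analyzed field area (> 0).
#' @param bin_edges strictly increasing histogram bin edges in um^2.
#' @param condition optional condition label.
#' @param n_images number of images pooled.
#' @return a `gap_summary`: list with n_gaps, total_gap_area_um2,
#'   open_area_percent, size_histogram (data.frame lower, upper, count;
#'   final overflow row when needed), condition, n_images.
#' @export
gap_summary <- function(gaps, field_area_um2,
                        bin_edges = c(5, 10, 20, 50, 100, 200, 500, 1000),
                        condition = NA_character_, n_images = 1L) {
  if (!is.numeric(field_area_um2) || field_area_um2 <= 0)
    stop_mlq("field_area_um2 must be > 0", "invalid_parameter")
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop_mlq("bin_edges must be strictly increasing", "invalid_parameter")
  a <- gaps$area_um2
  nb <- length(bin_edges) - 1L
  counts <- integer(nb)
  overflow <- 0L
  for (x in a) {
    j <- findInterval(x, bin_edges, rightmost.closed = TRUE)
    if (j >= 1L && j <= nb) counts[j] <- counts[j] + 1L
    else overflow <- overflow + 1L
  }
  hist <- data.frame(lower = bin_edges[-length(bin_edges)],
                     upper = bin_edges[-1L], count = counts)
  if (overflow > 0L) {
    warning(sprintf("%d gap(s) outside histogram bins; counted as overflow",
                    overflow), call. = FALSE)
    hist <- rbind(hist, data.frame(lower = NA_real_, upper = NA_real_,
                                   count = overflow))
  }
  structure(list(n_gaps = length(a),
                 total_gap_area_um2 = sum(a),
                 open_area_percent = 100 * sum(a) / field_area_um2,
                 size_histogram = hist,
                 condition = condition,
                 n_images = as.integer(n_images)),
            class = "gap_summary")
}

#' @export
print.gap_summary <- function(x, ...) {
  cat(sprintf(
    "<gap_summary%s: %d gaps over %d image(s), total %.1f um^2, open area %.3f%%>\n",
    if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
    x$n_gaps, x$n_images, x$total_gap_area_um2, x$open_area_percent))
  invisible(x)
}

#' Gap analysis over a set of images per condition
#'
#' @param datasets named list (condition -> list of junction-channel
#'   matrices).
#' @param pixel_size_um micrometres per pixel.
#' @param ... passed to [segment_gaps()].
#' @param bin_edges histogram bin edges for [gap_summary()].
#' @return list with `gaps` (condition, image_id, gap_id, area_um2, ...)
#'   and `summary` (one `gap_summary` per condition).
#' @export
gap_condition_table <- function(datasets, pixel_size_um,
                                bin_edges = c(5, 10, 20, 50, 100, 200, 500,
                                              1000), ...) {
  all_gaps <- list(); summaries <- list()
  for (cond in names(datasets)) {
    imgs <- datasets[[cond]]
    rows <- list(); field_area <- 0
    for (i in seq_along(imgs)) {
      g <- segment_gaps(imgs[[i]], pixel_size_um, ...)
      field_area <- field_area + prod(dim(imgs[[i]])) * pixel_size_um^2
      if (nrow(g)) rows[[length(rows) + 1L]] <-
          cbind(condition = cond, image_id = i, as.data.frame(g))
    }
    pooled <- if (length(rows)) do.call(rbind, rows) else
      data.frame(condition = character(0), image_id = integer(0),
                 gap_id = integer(0), area_um2 = numeric(0))
    all_gaps[[cond]] <- pooled
    summaries[[cond]] <- gap_summary(pooled, field_area, bin_edges,
                                     condition = cond,
                                     n_images = length(imgs))
  }
  list(gaps = do.call(rbind, c(all_gaps, list(make.row.names = FALSE))),
       summary = summaries)
}
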