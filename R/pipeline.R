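## Configuration, I/O and end-to-end orchestration of the two-condition
## (e.g. 1G vs simulated microgravity) comparison workflow, plus a thin
## one-way ANOVA + Tukey HSD reporting layer.

#' Build a validated analysis configuration
#'
#' Defaults mirror the study sampling design: morphology and junction
#' metrics from ~50 cells spread over 8 fluorescence images per condition,
#' gap quantification over 30 images per condition.
#'
#' @param pixel_size_um micrometres per pixel (required; image metadata is
#'   never trusted for calibration).
#' @param conditions named list; each element may set
#'   `junction_positive_fraction`, `fiber_spacing_um`, `gap_area_range_um2`
#'   (length-2), and `max_gaps_per_image` for the synthetic generator.
#' @param n_images sub-confluent images per condition (default 8).
#' @param cells_per_image cells per sub-confluent image (default 6, giving
#'   ~50 cells over 8 images).
#' @param n_gap_images confluent images per condition for gap analysis
#'   (default 30).
#' @param field_shape image size in pixels.
#' @param seed master RNG seed.
#' @param analyses subset of c("morphology", "junctions", "gaps", "fibers").
#' @param band_halfwidth_px,cyto_n_regions,cyto_region_radius_px junction
#'   profiling parameters.
#' @param min_gap_area_um2,gap_threshold_method,gap_closing_radius_px,
#'   gap_bin_edges gap segmentation parameters.
#' @param fiber_baseline,fiber_min_separation_um,fiber_smooth_window_um,
#'   fiber_background_window_um line-scan parameters (the 3 um separation
#'   rule lives here).
#' @param apply_noise logical; camera noise in the synthetic renderer.
#' @param out_dir output directory or NA to skip writing.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(pixel_size_um = 0.5,
                            conditions = list(
                              `1G` = list(junction_positive_fraction = 0.8,
                                          fiber_spacing_um = 8,
                                          gap_area_range_um2 = c(20, 100),
                                          max_gaps_per_image = 1L),
                              uG = list(junction_positive_fraction = 0.3,
                                        fiber_spacing_um = 4,
                                        gap_area_range_um2 = c(50, 400),
                                        max_gaps_per_image = 3L)),
                            n_images = 8L, cells_per_image = 6L,
                            n_gap_images = 30L,
                            field_shape = c(256L, 256L),
                            seed = 1L,
                            analyses = c("morphology", "junctions", "gaps",
                                         "fibers"),
                            band_halfwidth_px = 1L,
                            cyto_n_regions = 5L, cyto_region_radius_px = 5L,
                            min_gap_area_um2 = 5,
                            gap_threshold_method = "median_fraction",
                            gap_closing_radius_px = 2L,
                            gap_bin_edges = c(5, 10, 20, 50, 100, 200, 500,
                                              1000),
                            fiber_baseline = "auto",
                            fiber_min_separation_um = 3.0,
                            fiber_smooth_window_um = 0.75,
                            fiber_background_window_um = 6,
                            apply_noise = TRUE,
                            out_dir = NA_character_) {
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop_mlq("pixel_size_um must be > 0", "invalid_parameter")
  if (fiber_min_separation_um <= 0)
    stop_mlq("fiber_min_separation_um must be > 0", "invalid_parameter")
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop_mlq("conditions must be a named list", "invalid_parameter")
  analyses <- match.arg(analyses, several.ok = TRUE)
  cfg <- list(pixel_size_um = pixel_size_um, conditions = conditions,
              n_images = as.integer(n_images),
              cells_per_image = as.integer(cells_per_image),
              n_gap_images = as.integer(n_gap_images),
              field_shape = as.integer(field_shape), seed = as.integer(seed),
              analyses = analyses,
              band_halfwidth_px = as.integer(band_halfwidth_px),
              cyto_n_regions = as.integer(cyto_n_regions),
              cyto_region_radius_px = as.integer(cyto_region_radius_px),
              min_gap_area_um2 = min_gap_area_um2,
              gap_threshold_method = gap_threshold_method,
              gap_closing_radius_px = as.integer(gap_closing_radius_px),
              gap_bin_edges = gap_bin_edges,
              fiber_baseline = fiber_baseline,
              fiber_min_separation_um = fiber_min_separation_um,
              fiber_smooth_window_um = fiber_smooth_window_um,
              fiber_background_window_um = fiber_background_window_um,
              apply_noise = isTRUE(apply_noise), out_dir = out_dir)
  class(cfg) <- "analysis_config"
  cfg
}

#' @keywords internal
#' @noRd
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(cfg[setdiff(names(cfg), "out_dir")], file = f)
  unname(tools::md5sum(f))
}

#' Read a multichannel TIFF image stack
#'
#' Pages are keyed by role according to `channel_map`. Pixel values are
#' returned as integer counts (stored value x 65535, rounded), matching
#' what [write_dataset()] wrote. Any calibration embedded in the file is
#' ignored; micrometre scaling always comes from the analysis
#' configuration.
#'
#' @param path TIFF file path.
#' @param channel_map character vector of roles in page order (default
#'   junction, actin, nuclei).
#' @return named list of integer matrices.
#' @export
read_image_stack <- function(path,
                             channel_map = c("junction", "actin", "nuclei")) {
  if (!file.exists(path))
    stop_mlq(sprintf("file not found: '%s'", path), "file_not_found")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop_mlq(sprintf("malformed TIFF '%s': %s", path,
                                       conditionMessage(e)), "malformed_tiff"))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(channel_map))
    stop_mlq(sprintf("'%s' has %d page(s) but channel_map names %d",
                     path, length(pages), length(channel_map)),
             "channel_mismatch")
  out <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # tolerate grey-stored-as-RGB
    round(p * 65535)
  })
  names(out) <- channel_map
  out
}

## Synthetic dataset for one condition under the configured sampling design.
#' @keywords internal
#' @noRd
simulate_condition <- function(cfg, cond, cond_index) {
  spec <- cfg$conditions[[cond]]
  f <- spec$junction_positive_fraction %||% 0.8
  spacing <- spec$fiber_spacing_um %||% 5
  grange <- spec$gap_area_range_um2 %||% c(20, 200)
  maxg <- spec$max_gaps_per_image %||% 2L
  base <- cfg$seed + 7919L * cond_index
  sub <- lapply(seq_len(cfg$n_images), function(i) {
    sc <- generate_monolayer(cfg$cells_per_image, cfg$field_shape,
                             cfg$pixel_size_um, seed = base + i)
    render_scene(sc, junction_positive_fraction = f,
                 fiber_spacing_um = spacing, apply_noise = cfg$apply_noise,
                 regime = "subconfluent")
  })
  conf <- lapply(seq_len(cfg$n_gap_images), function(i) {
    seed_i <- base + 100000L + i
    sc <- generate_monolayer(cfg$cells_per_image, cfg$field_shape,
                             cfg$pixel_size_um, seed = seed_i)
    gap_spec <- with_seed(seed_i + 500L, {
      ng <- sample.int(maxg + 1L, 1L) - 1L
      if (ng > 0) lapply(runif(ng, grange[1L], grange[2L]),
                         function(a) list(area_um2 = a, center = NULL))
      else NULL
    })
    render_scene(sc, junction_positive_fraction = 1, gap_spec = gap_spec,
                 fiber_spacing_um = spacing, apply_noise = cfg$apply_noise,
                 regime = "confluent")
  })
  list(subconfluent = sub, confluent = conf)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on a synthetic two-condition dataset
#'
#' Generates the configured synthetic dataset per condition (sub-confluent
#' fields for morphology/junction/fibre metrics, confluent fields for gap
#' metrics), runs every enabled analysis, and returns — and optionally
#' writes — long-format metric tables with provenance (config hash, seed).
#' Per-cell failures are logged and skipped; the run fails only when a
#' metric family produces no rows at all.
#'
#' @param config an [analysis_config()].
#' @return list with `metrics` (long data.frame: condition, image_id,
#'   cell_id, metric, value), `gap_summaries`, `junction_summary`,
#'   `fiber_summary`, `config_hash`, `log` (character vector of stage
#'   messages). When `config$out_dir` is set, CSVs, a run log and a config
#'   snapshot are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cfg <- config
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  hash <- config_hash(cfg)
  metrics <- list(); gap_summaries <- list()
  junction_summary <- NULL; fiber_summary <- NULL
  warn_count <- 0L
  withCallingHandlers({
    for (ci in seq_along(cfg$conditions)) {
      cond <- names(cfg$conditions)[ci]
      say("condition '%s': generating synthetic dataset", cond)
      ds <- simulate_condition(cfg, cond, ci)
      if ("morphology" %in% cfg$analyses) {
        say("condition '%s': morphology on %d image(s)", cond,
            length(ds$subconfluent))
        for (i in seq_along(ds$subconfluent)) {
          sc <- ds$subconfluent[[i]]
          tab <- morphology_table(sc$rendered_label_map, cfg$pixel_size_um)
          for (col in c("area_um2", "perimeter_um", "shape_index",
                        "tortuosity_index"))
            metrics[[length(metrics) + 1L]] <- data.frame(
              condition = cond, image_id = i, cell_id = tab$cell_id,
              metric = col, value = tab[[col]])
        }
      }
      if ("junctions" %in% cfg$analyses) {
        say("condition '%s': junction profiling", cond)
        jt <- junction_condition_table(
          stats::setNames(list(lapply(ds$subconfluent, function(sc)
            list(image = sc$images$junction,
                 label_map = sc$rendered_label_map))), cond),
          cfg$pixel_size_um, band_halfwidth_px = cfg$band_halfwidth_px,
          n_regions = cfg$cyto_n_regions,
          region_radius_px = cfg$cyto_region_radius_px,
          seed = cfg$seed + 31L * ci)
        if (nrow(jt$cells))
          metrics[[length(metrics) + 1L]] <- data.frame(
            condition = cond, image_id = jt$cells$image_id,
            cell_id = jt$cells$cell_id, metric = "positivity_percent",
            value = jt$cells$positivity_percent)
        junction_summary <- rbind(junction_summary, jt$summary)
      }
      if ("fibers" %in% cfg$analyses) {
        say("condition '%s': fibre line scans", cond)
        ft <- fiber_condition_table(
          stats::setNames(list(lapply(ds$subconfluent, function(sc)
            list(image = sc$images$actin,
                 label_map = sc$rendered_label_map))), cond),
          cfg$pixel_size_um, baseline = cfg$fiber_baseline,
          min_separation_um = cfg$fiber_min_separation_um,
          background_window_um = cfg$fiber_background_window_um,
          smooth_window_um = cfg$fiber_smooth_window_um)
        metrics[[length(metrics) + 1L]] <- data.frame(
          condition = cond, image_id = ft$cells$image_id,
          cell_id = ft$cells$cell_id, metric = "density_per_um",
          value = ft$cells$density_per_um)
        fiber_summary <- rbind(fiber_summary, ft$summary)
      }
      if ("gaps" %in% cfg$analyses) {
        say("condition '%s': gap segmentation on %d image(s)", cond,
            length(ds$confluent))
        gt <- gap_condition_table(
          stats::setNames(list(lapply(ds$confluent,
                                      function(sc) sc$images$junction)),
                          cond),
          cfg$pixel_size_um, bin_edges = cfg$gap_bin_edges,
          min_gap_area_um2 = cfg$min_gap_area_um2,
          threshold_method = cfg$gap_threshold_method,
          closing_radius_px = cfg$gap_closing_radius_px)
        if (nrow(gt$gaps))
          metrics[[length(metrics) + 1L]] <- data.frame(
            condition = cond, image_id = gt$gaps$image_id,
            cell_id = gt$gaps$gap_id, metric = "gap_area_um2",
            value = gt$gaps$area_um2)
        gap_summaries[[cond]] <- gt$summary[[cond]]
      }
    }
  }, warning = function(w) {
    warn_count <<- warn_count + 1L
    log <<- c(log, paste("warning:", conditionMessage(w)))
    invokeRestart("muffleWarning")
  })
  if (!length(metrics))
    stop_mlq("pipeline produced no results", "empty_result")
  metrics <- do.call(rbind, metrics)
  metrics$config_hash <- hash
  metrics$seed <- cfg$seed
  say("done: %d metric rows, %d warning(s)", nrow(metrics), warn_count)
  out <- list(metrics = metrics, gap_summaries = gap_summaries,
              junction_summary = junction_summary,
              fiber_summary = fiber_summary,
              config_hash = hash, log = log)
  if (!is.na(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
                     row.names = FALSE)
    if (!is.null(junction_summary))
      utils::write.csv(junction_summary,
                       file.path(cfg$out_dir, "junction_summary.csv"),
                       row.names = FALSE)
    if (!is.null(fiber_summary))
      utils::write.csv(fiber_summary,
                       file.path(cfg$out_dir, "fiber_summary.csv"),
                       row.names = FALSE)
    if (length(gap_summaries)) {
      gs <- do.call(rbind, lapply(gap_summaries, function(g)
        data.frame(condition = g$condition, n_gaps = g$n_gaps,
                   total_gap_area_um2 = g$total_gap_area_um2,
                   open_area_percent = g$open_area_percent,
                   n_images = g$n_images)))
      utils::write.csv(gs, file.path(cfg$out_dir, "gap_summary.csv"),
                       row.names = FALSE)
    }
    writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
    dput(unclass(cfg), file.path(cfg$out_dir, "config_snapshot.R"))
  }
  out
}

#' One-way ANOVA with Tukey HSD across conditions
#'
#' Thin reporting layer over `stats::aov` and `stats::TukeyHSD`: F
#' statistic, per-pair adjusted p values, significance stars
#' (* p < 0.05, ** p < 0.01, *** p < 0.001, **** p < 0.0001), and
#' mean +/- SEM per group.
#'
#' @param table long-format data.frame with a `condition` column.
#' @param metric metric name to filter on when the table has a `metric`
#'   column; otherwise ignored.
#' @param value_col name of the value column (default "value").
#' @return list with `metric`, `f_statistic`, `p_value`, `groups`
#'   (condition, n, mean, sem) and `pairs` (comparison, diff, p_adj,
#'   stars).
#' @export
compare_groups <- function(table, metric = NULL, value_col = "value") {
  d <- table
  if (!is.null(metric) && "metric" %in% names(d))
    d <- d[d$metric == metric, , drop = FALSE]
  if (!all(c("condition", value_col) %in% names(d)))
    stop_mlq("table must have 'condition' and value columns",
             "invalid_input")
  d <- d[is.finite(d[[value_col]]), , drop = FALSE]
  counts <- table(d$condition)
  counts <- counts[counts > 0]
  if (length(counts) < 2L || any(counts < 2L))
    stop_mlq("need >= 2 groups with >= 2 observations each",
             "invalid_input")
  d$condition <- factor(as.character(d$condition))
  fit <- stats::aov(stats::reformulate("condition", value_col), data = d)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$condition
  stars <- function(p) ifelse(p < 1e-4, "****", ifelse(p < 1e-3, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
  groups <- do.call(rbind, lapply(split(d[[value_col]], d$condition),
    function(v) data.frame(n = length(v), mean = mean(v),
                           sem = stats::sd(v) / sqrt(length(v)))))
  groups <- cbind(condition = rownames(groups), groups)
  rownames(groups) <- NULL
  list(metric = metric %||% value_col,
       f_statistic = an[["F value"]][1L],
       p_value = an[["Pr(>F)"]][1L],
       groups = groups,
       pairs = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"],
                          p_adj = tk[, "p adj"],
                          stars = stars(tk[, "p adj"]),
                          row.names = NULL))
}
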