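# End-to-end batch pipeline: preprocess -> enhance -> segment ->
# extract -> evaluate, over a directory of images with optional
# metadata and ground-truth masks, producing per-image artifacts, a
# consolidated CSV and a config sidecar for reproducibility.

#' Build and validate a pipeline configuration
#'
#' Every stage parameter is validated up front; a run's config is
#' serialised as JSON beside its outputs.
#'
#' @param input_dir directory containing the images and (optionally)
#'   `metadata.csv` plus `<id>_lesion.png` truth masks.
#' @param output_dir directory for artifacts and reports.
#' @param tolerance,connectivity,seed_offset,breast_threshold
#'   preprocessing parameters (see [remove_pectoral()]).
#' @param se_shape,se_radius structuring element for enhancement;
#'   `se_radius = NULL` scales the default with image side.
#' @param method one of "kmeans", "kmeans-spatial", "meanshift",
#'   "meanshift-spatial", "ncuts".
#' @param k cluster count (k-means methods) or segment count (ncuts).
#' @param spatial_weight spatial K-means weight.
#' @param range_bandwidth,spatial_bandwidth mean-shift bandwidths.
#' @param seed master RNG seed; each image uses `seed + its index`.
#' @param eme_blocks c(k1, k2) EME block grid.
#' @param psnr_mode "standard" or "unsquared_peak".
#' @param min_area minimum abnormal-component area; NULL scales with
#'   image side.
#' @param write_artifacts write per-image PNGs (default TRUE).
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            tolerance = 16, connectivity = 8L,
                            seed_offset = 5L, breast_threshold = 40,
                            se_shape = "disk", se_radius = NULL,
                            method = "kmeans", k = 4L,
                            spatial_weight = 100,
                            range_bandwidth = 25, spatial_bandwidth = 8,
                            seed = 1L, eme_blocks = c(8L, 8L),
                            psnr_mode = "standard", min_area = NULL,
                            write_artifacts = TRUE) {
  stopifnot(tolerance >= 0, connectivity %in% c(4L, 8L), seed_offset >= 0,
            breast_threshold >= 0, breast_threshold <= 255,
            se_shape %in% c("disk", "square"),
            method %in% c("kmeans", "kmeans-spatial", "meanshift",
                          "meanshift-spatial", "ncuts"),
            k >= 1, spatial_weight >= 0, range_bandwidth > 0,
            spatial_bandwidth > 0, length(eme_blocks) == 2L,
            psnr_mode %in% c("standard", "unsquared_peak"))
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              tolerance = tolerance, connectivity = as.integer(connectivity),
              seed_offset = as.integer(seed_offset),
              breast_threshold = breast_threshold, se_shape = se_shape,
              se_radius = se_radius, method = method, k = as.integer(k),
              spatial_weight = spatial_weight,
              range_bandwidth = range_bandwidth,
              spatial_bandwidth = spatial_bandwidth, seed = as.integer(seed),
              eme_blocks = as.integer(eme_blocks), psnr_mode = psnr_mode,
              min_area = min_area, write_artifacts = isTRUE(write_artifacts))
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_log <- function(fmt, ...) message(sprintf(fmt, ...))

run_one_image <- function(img, cfg, view, laterality, img_seed) {
  t0 <- proc.time()[["elapsed"]]
  pre <- remove_pectoral(img, tolerance = cfg$tolerance,
                         connectivity = cfg$connectivity,
                         seed_offset = cfg$seed_offset,
                         breast_threshold = cfg$breast_threshold,
                         view = view, laterality = laterality)
  se <- if (is.null(cfg$se_radius)) default_se(img)
        else structuring_element(cfg$se_shape, cfg$se_radius)
  enhanced <- enhance_contrast(pre$cleaned, se)
  # clustering sees the whole enhanced frame (the abnormal-region rule
  # then restricts to the breast); masked clustering remains available
  # through the segmenters' mask argument
  roi <- pre$breast_mask & !pre$pectoral_mask
  seg <- switch(cfg$method,
    "kmeans" = kmeans_segment(enhanced, cfg$k, seed = img_seed),
    "kmeans-spatial" = kmeans_spatial_segment(enhanced, cfg$k,
                                              spatial_weight = cfg$spatial_weight,
                                              seed = img_seed),
    "meanshift" = mean_shift_segment(enhanced, cfg$range_bandwidth),
    "meanshift-spatial" = mean_shift_spatial_segment(enhanced,
                                                     cfg$spatial_bandwidth,
                                                     cfg$range_bandwidth),
    "ncuts" = normalized_cuts_segment(enhanced, n_segments = cfg$k))
  abnormal <- extract_abnormal_region(seg$labels, enhanced, roi,
                                      min_area = cfg$min_area)
  pipeline_log("stage times: total %.2fs (method %s, k=%d)",
               proc.time()[["elapsed"]] - t0, cfg$method, cfg$k)
  list(pre = pre, enhanced = enhanced, labels = seg$labels,
       abnormal = abnormal, se = se)
}

#' Run the full three-stage pipeline over a dataset
#'
#' Reads `metadata.csv` from the input directory when present (falling
#' back to every `.png`/`.pgm` image, treated as MLO with automatic
#' orientation), processes each image through pectoral removal,
#' morphological enhancement and segmentation, scores against
#' `<id>_lesion.png` truth masks when they exist, and writes
#' `results.csv` (per-image rows formatted to 6 decimal places, then
#' per-BI-RADS-category mean rows), a `config.json` sidecar, and
#' optional per-image artifact PNGs.  Identical config + seed produces
#' bit-identical CSV output.  Per-image failures are logged and
#' skipped; the run fails only if every image fails.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the per-image results data.frame.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  meta_path <- file.path(cfg$input_dir, "metadata.csv")
  if (file.exists(meta_path)) {
    meta <- load_metadata(meta_path)
  } else {
    files <- list.files(cfg$input_dir, pattern = "\\.(png|pgm)$")
    files <- files[!grepl("_(breast|pectoral|lesion|mask)\\.png$", files)]
    if (length(files) == 0L) stop("no input images found", call. = FALSE)
    meta <- data.frame(id = tools::file_path_sans_ext(files), view = "MLO",
                       laterality = NA_character_, birads = NA_integer_,
                       path = files, stringsAsFactors = FALSE)
  }
  rows <- list()
  n_fail <- 0L
  for (i in seq_len(nrow(meta))) {
    rec <- meta[i, ]
    res <- tryCatch({
      img <- read_image(file.path(cfg$input_dir, rec$path))
      lat <- if (is.na(rec$laterality)) NULL else rec$laterality
      out <- run_one_image(img, cfg, rec$view, lat, cfg$seed + i)
      truth_path <- file.path(cfg$input_dir, paste0(rec$id, "_lesion.png"))
      A_T <- if (file.exists(truth_path)) read_mask(truth_path) else NULL
      row <- evaluate(A_S = out$abnormal, A_T = A_T,
                      reference = out$pre$cleaned, enhanced = out$enhanced,
                      original = out$pre$cleaned,
                      eme_blocks = cfg$eme_blocks, psnr_mode = cfg$psnr_mode,
                      id = rec$id, category = rec$birads)
      if (cfg$write_artifacts) {
        write_image(out$pre$cleaned, file.path(cfg$output_dir, paste0(rec$id, "_cleaned.png")))
        write_image(out$enhanced, file.path(cfg$output_dir, paste0(rec$id, "_enhanced.png")))
        write_mask(out$pre$pectoral_mask, file.path(cfg$output_dir, paste0(rec$id, "_pectoral.png")))
        write_mask(out$abnormal, file.path(cfg$output_dir, paste0(rec$id, "_abnormal.png")))
        lab <- out$labels; lab[is.na(lab)] <- 0L
        kmax <- max(1L, max(lab))
        write_image(as_gray(lab * (255 / kmax)),
                    file.path(cfg$output_dir, paste0(rec$id, "_labels.png")))
      }
      row
    }, error = function(e) {
      pipeline_log("image %s failed: %s", rec$id, conditionMessage(e))
      NULL
    })
    if (is.null(res)) n_fail <- n_fail + 1L else rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L) stop("all images failed", call. = FALSE)
  results <- do.call(rbind, rows)
  report <- results
  metric_cols <- setdiff(names(report), c("id", "category"))
  if (any(!is.na(report$category))) {
    agg <- lapply(split(report, report$category), function(g) {
      m <- g[1, , drop = FALSE]
      m$id <- sprintf("mean_birads_%s", g$category[1L])
      for (cn in metric_cols) m[[cn]] <- mean(g[[cn]], na.rm = TRUE)
      m
    })
    report <- rbind(report, do.call(rbind, agg))
  }
  for (cn in metric_cols)
    report[[cn]] <- ifelse(is.na(report[[cn]]), "",
                           formatC(report[[cn]], digits = 6L, format = "f"))
  utils::write.csv(report, file.path(cfg$output_dir, "results.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(cfg$output_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  pipeline_log("pipeline complete: %d image(s) processed, %d failed",
               nrow(results), n_fail)
  invisible(results)
}
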