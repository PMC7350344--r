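# Orchestration of the full method: per tray (median projection -> grayscale
# -> frame crop -> mixture segmentation -> cleanup -> measurement), per plant
# (cumulation -> Otsu split -> cylinder traits) and per batch (pooled trait
# table, optional validation against ground truth).

config_schema <- function() {
  list(
    imaging = list(spatial_median = "logical"),
    frame = list(required = "logical", rho_res_px = "numeric",
                 theta_res_deg = "numeric", min_votes_frac = "numeric",
                 max_tilt_deg = "numeric", safety_margin_px = "numeric",
                 edge_low = "numeric", edge_high = "numeric"),
    seg = list(K = "numeric", feature_space = "character",
               root_components = "ANY", min_posterior = "numeric",
               min_contrast = "numeric", seed = "numeric",
               max_samples = "numeric", max_iter = "numeric", tol = "numeric"),
    dirt = list(min_elongation = "numeric", max_area_px = "numeric",
                min_speck_px = "numeric", fill_hole_px = "numeric"),
    measure = list(method = "character", end_correction = "logical",
                   bin_width_mm = "numeric", max_diameter_mm = "numeric"),
    trait = list(otsu_mode = "character"),
    seed = "numeric", debug = "logical", log_level = "character")
}

#' Default pipeline configuration
#'
#' Nested list of all module parameters with their defaults: K = 3 mixture
#' components on grayscale intensity with the darkest component as root
#' (maximum-a-posteriori rule), Hough frame detection with 1 px / 0.5 degree
#' resolution and votes >= 0.3 of the smaller image dimension, shape-based
#' dirt removal (elongation >= 3 or area > 50000 px), and the Kimura length
#' estimator with end correction on 0.1 mm diameter classes.
#'
#' @return A named list (see [config_schema] keys).
#' @export
default_config <- function() {
  list(
    imaging = list(spatial_median = FALSE),
    frame = list(required = TRUE, rho_res_px = 1, theta_res_deg = 0.5,
                 min_votes_frac = 0.3, max_tilt_deg = 5, safety_margin_px = 3,
                 edge_low = 0.1, edge_high = 0.3),
    seg = list(K = 3, feature_space = "gray", root_components = "darkest",
               min_posterior = 0.5, min_contrast = 0.2, seed = 1,
               max_samples = 50000, max_iter = 300, tol = 1e-6),
    dirt = list(min_elongation = 3, max_area_px = 50000,
                min_speck_px = 25, fill_hole_px = 100),
    measure = list(method = "kimura", end_correction = TRUE,
                   bin_width_mm = 0.1, max_diameter_mm = 10),
    trait = list(otsu_mode = "per_plant"),
    seed = 1, debug = FALSE, log_level = "info")
}

check_keys <- function(value, schema, path) {
  if (is.character(schema)) return(invisible(TRUE))
  unknown <- setdiff(names(value), names(schema))
  if (length(unknown))
    abort_validation(sprintf("unknown config key(s): %s",
                             paste(paste0(path, unknown), collapse = ", ")))
  for (nm in names(value)) check_keys(value[[nm]], schema[[nm]], paste0(path, nm, "."))
  invisible(TRUE)
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys are rejected; missing keys are filled from
#' [default_config()].
#'
#' @param config A (possibly partial) nested configuration list.
#' @return The completed configuration.
#' @export
validate_config <- function(config = list()) {
  check_keys(config, config_schema(), "")
  def <- default_config()
  for (grp in names(def)) {
    if (!is.list(def[[grp]])) {
      if (!is.null(config[[grp]])) def[[grp]] <- config[[grp]]
    } else if (!is.null(config[[grp]])) {
      for (key in names(config[[grp]])) def[[grp]][[key]] <- config[[grp]][[key]]
    }
  }
  if (!(def$seg$min_posterior >= 0 && def$seg$min_posterior < 1))
    abort_validation("seg.min_posterior must be in [0, 1)")
  if (!def$measure$method %in% c("kimura", "chain"))
    abort_validation("measure.method must be 'kimura' or 'chain'")
  def
}

log_line <- function(config, stage, msg) {
  if (identical(config$log_level, "quiet")) return(invisible(NULL))
  message(sprintf("[rootmorph] %s: %s", stage, msg))
}

# 3x3 spatial median, optional extra smoothing step
spatial_median3 <- function(image) {
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- px
  pad[1, ] <- pad[2, ]; pad[h + 2, ] <- pad[h + 1, ]
  pad[, 1] <- pad[, 2]; pad[, w + 2] <- pad[, w + 1]
  arr <- array(0, c(h, w, 9))
  q <- 0
  for (dj in 0:2) for (di in 0:2) {
    q <- q + 1
    arr[, , q] <- pad[(1:h) + di, (1:w) + dj]
  }
  raster_image(cpp_stack_median(arr), image$dpi)
}

#' Run the pipeline on one tray
#'
#' median projection -> grayscale -> frame detection and crop -> mixture
#' fit / posterior classification -> speck/hole cleanup -> shape-based dirt
#' removal -> skeleton measurement -> diameter-length histogram.
#'
#' If the frame is not found and `frame$required` is `FALSE`, the full image
#' is processed with a warning; otherwise the error propagates. With
#' `config$debug = TRUE` intermediate artifacts (projected image, masks,
#' removed-dirt stats, frame geometry) are attached as the `"intermediates"`
#' attribute.
#'
#' @param stack A [tray_stack()].
#' @param config Configuration from [validate_config()].
#' @return A [dl_histogram()] for the tray.
#' @export
run_tray <- function(stack, config = default_config()) {
  cfg <- validate_config(config)
  tray_seed <- derive_seed(cfg$seed, paste0(stack$plant_id, "/", stack$tray_id))
  img <- to_grayscale(median_project(stack))
  if (isTRUE(cfg$imaging$spatial_median)) img <- spatial_median3(img)

  cropped <- tryCatch({
    edges <- detect_edges(img, cfg$frame$edge_low, cfg$frame$edge_high)
    min_votes <- cfg$frame$min_votes_frac * min(image_shape(img))
    lines <- hough_lines(edges, rho_res = cfg$frame$rho_res_px,
                         theta_res = cfg$frame$theta_res_deg * pi / 180,
                         min_votes = min_votes)
    frame <- fit_frame(lines, image_shape(img),
                       max_tilt = cfg$frame$max_tilt_deg * pi / 180,
                       safety_margin_px = cfg$frame$safety_margin_px)
    list(image = crop_interior(img, frame), frame = frame)
  }, rootmorph_frame_error = function(e) {
    if (isTRUE(cfg$frame$required))
      abort_rm(sprintf("tray '%s': %s", stack$tray_id, conditionMessage(e)),
               "rootmorph_frame_error")
    warning(sprintf("tray '%s': %s; processing the full image", stack$tray_id,
                    conditionMessage(e)))
    list(image = img, frame = NULL)
  })
  work <- cropped$image

  samples <- sample_pixels(work, max_samples = cfg$seg$max_samples,
                           seed = derive_seed(tray_seed, "sample"))
  model <- fit_mixture(samples, K = cfg$seg$K,
                       seed = derive_seed(tray_seed, "em"),
                       max_iter = cfg$seg$max_iter, tol = cfg$seg$tol)
  root_k <- if (identical(cfg$seg$root_components, "darkest"))
    darkest_components(model, 1) else as.integer(cfg$seg$root_components)
  # a tray with no roots fits a mixture of background shades only: demand a
  # minimum intensity contrast between the root component and the brightest
  # component before classifying anything as root
  contrast <- max(model$means[, 1]) - min(model$means[root_k, 1])
  if (contrast < cfg$seg$min_contrast) {
    log_line(cfg, "tray", sprintf(
      "'%s': no component darker than background by %.2f; empty root mask",
      stack$tray_id, cfg$seg$min_contrast))
    mask <- binary_mask(matrix(FALSE, nrow(work$pixels), ncol(work$pixels)),
                        work$dpi)
  } else {
    post <- posterior_map(work, model)
    mask <- classify_root_pixels(post, root_k, cfg$seg$min_posterior)
  }
  mask_pre_dirt <- clean_mask(mask, cfg$dirt$min_speck_px, cfg$dirt$fill_hole_px)
  dirt <- remove_dirt(mask_pre_dirt, cfg$dirt$min_elongation, cfg$dirt$max_area_px)
  mask <- dirt$mask
  log_line(cfg, "tray", sprintf(
    "'%s': %d root px, %d component(s) kept, %d removed as dirt",
    stack$tray_id, sum(mask$pixels), nrow(dirt$kept), nrow(dirt$removed)))

  hist <- measure_mask(mask, method = cfg$measure$method,
                       end_correction = cfg$measure$end_correction,
                       bin_width_mm = cfg$measure$bin_width_mm,
                       max_diameter_mm = cfg$measure$max_diameter_mm,
                       plant_id = stack$plant_id)
  if (isTRUE(cfg$debug))
    attr(hist, "intermediates") <- list(projected = img, cropped = work,
                                        frame = cropped$frame, model = model,
                                        mask = mask, mask_pre_dirt = mask_pre_dirt,
                                        dirt_removed = dirt$removed)
  hist
}

#' Run the pipeline for one plant
#'
#' Runs every tray, cumulates the histograms, splits fibrous vs storage with
#' Otsu's method, and computes cylinder traits. A degenerate (unimodal)
#' histogram classifies all mass as fibrous and flags the plant instead of
#' failing.
#'
#' @param stacks List of [tray_stack()] objects belonging to one plant.
#' @param config Configuration list.
#' @return A `root_traits` object (histogram attached as attribute
#'   `"histogram"`).
#' @export
run_plant <- function(stacks, config = default_config()) {
  cfg <- validate_config(config)
  if (length(stacks) < 1) abort_validation("a plant needs at least one tray")
  hists <- lapply(stacks, run_tray, config = cfg)
  hist <- cumulate(hists, plant_id = stacks[[1]]$plant_id)
  traits <- tryCatch(
    cylinder_traits(hist, otsu_split(hist)),
    rootmorph_degenerate_error = function(e)
      cylinder_traits(hist, NULL, flags = "degenerate histogram: all fibrous"))
  attr(traits, "histogram") <- hist
  traits
}

#' Read an input manifest
#'
#' CSV with columns `plant_id`, `cultivar`, `treatment`, `experiment`,
#' `tray_id`, `images` (path(s), `;`-separated), `dpi`. Every plant needs at
#' least one tray, every tray at least one image, and paths must be unique.
#'
#' @param path Manifest CSV path.
#' @return A data.frame.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "cultivar", "treatment", "experiment", "tray_id", "images", "dpi")
  missing <- setdiff(need, names(df))
  if (length(missing))
    abort_validation(sprintf("manifest lacks column(s): %s", paste(missing, collapse = ", ")))
  if (nrow(df) < 1) abort_validation("manifest is empty")
  paths <- unlist(strsplit(df$images, ";", fixed = TRUE))
  if (anyDuplicated(paths))
    abort_validation("manifest image paths are not unique")
  df
}

#' Run a batch of plants from a manifest
#'
#' Per-plant traits pooled across experiments with identifiers retained. A
#' failing plant is logged and flagged; remaining plants are still processed.
#'
#' @param manifest data.frame from [read_manifest()] (or of the same shape).
#' @param config Configuration list.
#' @param loader Function `(manifest_rows) -> list of tray_stack` used to
#'   materialise one plant's trays; the default reads image files via
#'   [load_stack()]. Tests and simulations may supply generated stacks.
#' @return A list with `traits` (data.frame, one row per plant), `failed`
#'   (data.frame of plant_id/reason), and `config`.
#' @export
run_batch <- function(manifest, config = default_config(), loader = NULL) {
  cfg <- validate_config(config)
  if (is.null(loader))
    loader <- function(rows) lapply(seq_len(nrow(rows)), function(i)
      load_stack(strsplit(rows$images[i], ";", fixed = TRUE)[[1]],
                 dpi = rows$dpi[i], tray_id = rows$tray_id[i],
                 plant_id = rows$plant_id[i]))
  plants <- unique(manifest$plant_id)
  rows_out <- list(); failed <- list()
  for (pid in plants) {
    rows <- manifest[manifest$plant_id == pid, , drop = FALSE]
    res <- tryCatch({
      stacks <- loader(rows)
      traits <- run_plant(stacks, cfg)
      df <- as.data.frame(traits)
      df$cultivar <- rows$cultivar[1]
      df$treatment <- rows$treatment[1]
      df$experiment <- rows$experiment[1]
      df
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log_line(cfg, "plant", sprintf("'%s' FAILED: %s", pid, conditionMessage(res)))
      failed[[length(failed) + 1]] <- data.frame(plant_id = pid,
                                                 reason = conditionMessage(res))
    } else rows_out[[length(rows_out) + 1]] <- res
  }
  traits <- if (length(rows_out)) pool_experiments(rows_out) else NULL
  failed <- if (length(failed)) do.call(rbind, failed)
            else data.frame(plant_id = character(0), reason = character(0))
  list(traits = traits, failed = failed, config = cfg)
}

#' Write a trait table / validation report
#'
#' @param traits Trait data.frame from [run_batch()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traits_csv <- function(traits, path) {
  write.csv(traits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traits_csv
#' @param report A `validation_report` from [validate_traits()].
#' @export
write_validation_json <- function(report, path) {
  jsonlite::write_json(list(r_squared = report$r_squared, n = report$n,
                            per_plant = report$per_plant),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a binary mask as a 1-bit-style PNG for inspection
#'
#' @param mask A [binary_mask()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask$pixels * 1, path)
  invisible(path)
}
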