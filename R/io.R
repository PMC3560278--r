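#' Write a scatter pattern to a single-channel image file
#'
#' Writes `intensity / max(intensity)` quantized to the requested bit depth.
#' TIFF supports 8 or 16 bits; PNG is written at 8 bits.
#'
#' @param pattern a `scatter_pattern` or numeric matrix.
#' @param path output path ending in `.tif`/`.tiff` or `.png`.
#' @param bits 8 or 16 (TIFF only; PNG always 8).
#' @return `path`, invisibly.
#' @export
write_pattern_image <- function(pattern, path, bits = 16L) {
  I <- if (inherits(pattern, "scatter_pattern")) pattern$intensity else pattern
  if (!is.matrix(I)) stop("`pattern` must be a matrix or scatter_pattern",
                          call. = FALSE)
  mx <- max(I)
  if (mx <= 0) stop("pattern is identically zero", call. = FALSE)
  img <- I / mx
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!bits %in% c(8L, 16L)) stop("`bits` must be 8 or 16", call. = FALSE)
    tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a scatter-pattern image
#'
#' Reads a single-channel 8- or 16-bit TIFF or PNG into a `scatter_pattern`
#' with intensities rescaled to `[0, 1]`. Multi-channel (e.g. RGB) images are
#' rejected. Optical metadata not stored in the file is filled with package
#' defaults, with a warning.
#'
#' @param path image path.
#' @param pixel_pitch detector pixel pitch in micrometres; warned-about
#'   default if omitted.
#' @param config an [optical_config()]; warned-about default if omitted.
#' @param label optional class label to attach.
#' @return A `scatter_pattern`.
#' @export
read_pattern_image <- function(path, pixel_pitch = NULL, config = NULL,
                               label = NULL) {
  if (!file.exists(path))
    stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported image format: ", path, call. = FALSE)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 1)
      stop("multi-channel image not supported (", dim(img)[3],
           " channels): ", path, call. = FALSE)
    img <- img[, , 1]
  }
  if (is.null(pixel_pitch) || is.null(config))
    warning("optical metadata not stored in ", basename(path),
            "; applying package defaults", call. = FALSE)
  structure(list(intensity = img,
                 pixel_pitch = pixel_pitch %||% 2,
                 config = config %||% optical_config(),
                 label = label),
            class = "scatter_pattern")
}

#' Write / read a feature table as CSV
#'
#' The header row holds `source_id`, `label`, then the ordered feature ids;
#' numeric values round-trip to at least 12 significant digits.
#'
#' @param features a feature table (data.frame from
#'   [extract_feature_table()]) or numeric matrix.
#' @param path CSV path.
#' @return `write_feature_table()`: `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  if (!is.data.frame(features)) {
    features <- as.data.frame(as.matrix(features))
  }
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @return `read_feature_table()`: a data.frame; if the file has no `label`
#'   column the table simply lacks one (labels are never fabricated).
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path,
                               call. = FALSE)
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stop("malformed feature CSV ", path,
                                          ": ", conditionMessage(e),
                                          call. = FALSE))
  df
}

#' Save / load a trained colony SVM as portable JSON
#'
#' All numbers needed for prediction (support vectors, dual coefficients,
#' offset, kernel settings, feature scaler and ids) are stored in plain JSON;
#' a loaded model predicts bit-identically to the original.
#'
#' @param model a `colony_svm`.
#' @param path JSON path.
#' @return `save_model()`: `path`, invisibly; `load_model()`: a
#'   `colony_svm`.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "colony_svm"))
    stop("`model` must be a colony_svm", call. = FALSE)
  payload <- list(
    format = "colonyscatter_svm", version = 1L,
    kernel = model$kernel, cost = model$cost, gamma = model$gamma,
    sv = model$sv, coefs = model$coefs, rho = model$rho,
    mu = model$mu, sigma = model$sigma,
    positive_class = model$positive_class,
    negative_class = model$negative_class,
    classes = model$classes, feature_ids = model$feature_ids,
    training_accuracy = model$training_accuracy
  )
  if (!is.null(model$selection))
    payload$selection <- list(k = model$selection$k,
                              ranking = model$selection$ranking)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "colonyscatter_svm"))
    stop("not a colonyscatter model file: ", path, call. = FALSE)
  out <- structure(list(
    kernel = p$kernel, cost = p$cost, gamma = p$gamma,
    sv = matrix(unlist(p$sv), nrow = length(p$coefs)),
    coefs = as.numeric(p$coefs), rho = as.numeric(p$rho),
    mu = as.numeric(p$mu), sigma = as.numeric(p$sigma),
    positive_class = p$positive_class, negative_class = p$negative_class,
    classes = p$classes, feature_ids = p$feature_ids,
    training_accuracy = p$training_accuracy
  ), class = "colony_svm")
  if (!is.null(p$selection))
    out$selection <- list(k = as.integer(p$selection$k),
                          ranking = as.integer(p$selection$ranking))
  out
}

#' Full run configuration with defaults
#'
#' Bundles every tunable block of the pipeline (phantom classes, optics,
#' features, classifier, morphometry) plus the global seed into one nested
#' list that serialises losslessly to JSON. [read_run_config()] rejects
#' unknown keys, so a config file cannot silently misspell a parameter.
#'
#' @param ... overrides as `block$name = value` nested lists, e.g.
#'   `optics = list(z = 10)`.
#' @param seed global seed.
#' @return An object of class `run_config` (nested list).
#' @export
make_run_config <- function(..., seed = 42L) {
  base <- list(
    seed = as.integer(seed),
    phantom = list(
      good = unclass(phantom_params("good")),
      bad = unclass(phantom_params("bad"))
    ),
    optics = unclass(optical_config()),
    features = list(n_max = 17L, k = 161L, log_compress = TRUE),
    classifier = list(kernel = "linear", cost = 1),
    morphometry = list(z_step = 2, noise_sd = 0,
                       good_fraction = 0.9, bad_fraction = 0.5)
  )
  ov <- list(...)
  for (blk in names(ov)) {
    if (!blk %in% names(base))
      stop("unknown config block: ", blk, call. = FALSE)
    for (key in names(ov[[blk]])) {
      if (!key %in% names(base[[blk]]))
        stop("unknown config key: ", blk, "$", key, call. = FALSE)
      base[[blk]][[key]] <- ov[[blk]][[key]]
    }
  }
  structure(base, class = "run_config")
}

#' @rdname make_run_config
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname make_run_config
#' @export
read_run_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- unclass(make_run_config())
  unknown_top <- setdiff(names(p), names(ref))
  if (length(unknown_top))
    stop("unknown config keys: ", paste(unknown_top, collapse = ", "),
         call. = FALSE)
  for (blk in setdiff(names(p), "seed")) {
    bad <- setdiff(names(p[[blk]]), names(ref[[blk]]))
    if (length(bad))
      stop("unknown config keys in `", blk, "`: ",
           paste(bad, collapse = ", "), call. = FALSE)
    for (key in names(p[[blk]])) ref[[blk]][[key]] <- p[[blk]][[key]]
  }
  if (!is.null(p$seed)) ref$seed <- as.integer(p$seed)
  structure(ref, class = "run_config")
}

# reconstruct parameter objects from a run_config
config_phantom_params <- function(config, class_label) {
  p <- config$phantom[[class_label]]
  p$class_label <- class_label
  do.call(phantom_params, p)
}

config_optics <- function(config) {
  do.call(optical_config, config$optics)
}
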