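# Raster and manifest IO. Images are 8-bit RGB PNG or TIFF; masks are
# single-channel 0/255 PNG/TIFF; fiber instance labels 16-bit single-channel
# TIFF; ground truth as a JSON sidecar; the study manifest as CSV.

.fmt_of <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "tiff"
  else if (ext == "png") "png"
  else stop("unsupported image format: .", ext, " (use png or tiff)",
            call. = FALSE)
}

#' Read / write an 8-bit RGB field image
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param image a [field_image()] or RGB raster (0..255) for writing.
#' @param ... metadata passed to [field_image()] when reading.
#' @return `read_field_image()` returns a [field_image()].
#' @export
read_field_image <- function(path, ...) {
  .assert(file.exists(path), "image not found: ", path)
  arr <- switch(.fmt_of(path),
                png = png::readPNG(path),
                tiff = tiff::readTIFF(path))
  if (length(dim(arr)) == 2L) stop("expected an RGB image: ", path, call. = FALSE)
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3]  # drop alpha
  field_image(round(arr * 255), ...)
}

#' @rdname read_field_image
#' @export
write_field_image <- function(image, path) {
  px <- .pixels(image) / 255
  switch(.fmt_of(path),
         png = png::writePNG(px, target = path),
         tiff = tiff::writeTIFF(px, where = path, bits.per.sample = 8L))
  invisible(path)
}

#' Read / write a boolean mask raster (0/255 single channel)
#'
#' @param mask logical matrix; @param path png/tiff path.
#' @return `read_mask()` returns a logical matrix.
#' @export
write_mask <- function(mask, path) {
  .assert(is.matrix(mask), "mask must be a matrix")
  m <- (mask > 0) * 1
  switch(.fmt_of(path),
         png = png::writePNG(m, target = path),
         tiff = tiff::writeTIFF(m, where = path, bits.per.sample = 8L))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  .assert(file.exists(path), "mask not found: ", path)
  arr <- switch(.fmt_of(path),
                png = png::readPNG(path),
                tiff = tiff::readTIFF(path))
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  arr > 0.5
}

#' Write fiber instance labels as 16-bit single-channel TIFF
#'
#' @param labels integer matrix (0 = interstitium).
#' @param path `.tif`/`.tiff` path.
#' @export
write_labels <- function(labels, path) {
  .assert(.fmt_of(path) == "tiff", "labels are written as 16-bit TIFF")
  .assert(max(labels) < 65536, "more than 65535 labels")
  tiff::writeTIFF(labels / 65535, where = path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  arr <- tiff::readTIFF(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  matrix(as.integer(round(arr * 65535)), nrow(arr), ncol(arr))
}

#' Materialize a synthetic study to disk
#'
#' Renders every field of a [generate_study()] design: the RGB image, the
#' ground-truth label raster, a JSON ground-truth sidecar per field, and a
#' `manifest.csv` (animal, condition, field, seed, file paths) tying the
#' study together.
#'
#' @param study a [generate_study()] object.
#' @param dir output directory (created if missing).
#' @param format `"png"` (default) or `"tiff"` for the RGB images.
#' @return Invisibly, the manifest data frame (with path columns).
#' @export
write_study <- function(study, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  .assert(inherits(study, "synthetic_study"), "study must be a synthetic_study")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- study$manifest
  m$image <- file.path(dir, sprintf("%s_f%02d.%s", m$animal, m$field,
                                    if (format == "png") "png" else "tif"))
  m$labels <- file.path(dir, sprintf("%s_f%02d_labels.tif", m$animal, m$field))
  m$truth <- file.path(dir, sprintf("%s_f%02d_truth.json", m$animal, m$field))
  for (i in seq_len(nrow(m))) {
    sec <- generate_section(study$specs[[i]])
    write_field_image(sec$image, m$image[i])
    write_labels(sec$truth$labels, m$labels[i])
    tr <- sec$truth
    jsonlite::write_json(
      list(animal = m$animal[i], condition = m$condition[i],
           field = m$field[i], seed = m$seed[i],
           fiber_types = tr$types,
           true_total_fraction = tr$true_total_fraction,
           true_type1_fraction = tr$true_type1_fraction,
           true_type2b_fraction = tr$true_type2b_fraction,
           uncalibrated = study$specs[[i]]$uncalibrated),
      m$truth[i], auto_unbox = TRUE, digits = NA, na = "null")
  }
  utils::write.csv(m, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(m)
}

#' Analyze a manifest of stained-section images on disk
#'
#' File-based counterpart of [viability_study()]: reads a CSV manifest with
#' columns `animal`, `condition`, `field`, `image` (path) and optionally
#' `labels` (path to an instance raster used as `instance_source`), runs
#' segmentation and morphometry per field, averages per animal, normalizes
#' to the control group, and runs the statistics layer.
#'
#' @param manifest path to a manifest CSV, or an equivalent data frame.
#' @param control_condition label of the control group.
#' @param thresholds a [channel_thresholds()].
#' @param alpha significance level.
#' @param typing passed to [segment_field()].
#' @param use_labels use the manifest's `labels` rasters as fiber instances
#'   when present (default `TRUE`).
#' @return A `viability_study`-like list: `fields`, `animals`, `normalized`,
#'   `groups`, `stats`.
#' @export
analyze_manifest <- function(manifest, control_condition = "Control",
                             thresholds = channel_thresholds(), alpha = 0.05,
                             typing = "otsu", use_labels = TRUE) {
  if (is.character(manifest)) {
    .assert(file.exists(manifest), "manifest not found: ", manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  .assert(all(c("animal", "condition", "field", "image") %in% names(manifest)),
          "manifest needs columns animal, condition, field, image")
  frows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    if (!file.exists(row$image))
      stop("manifest row ", i, " (animal ", row$animal,
           "): image not readable: ", row$image, call. = FALSE)
    img <- read_field_image(row$image, animal = row$animal,
                            condition = row$condition, field = row$field)
    inst <- NULL
    if (use_labels && "labels" %in% names(manifest) && nzchar(row$labels %||% "")
        && file.exists(row$labels))
      inst <- read_labels(row$labels)
    masks <- segment_field(img, thresholds = thresholds, instances = inst,
                           typing = typing)
    fv <- field_viability(masks)
    fv$animal <- row$animal; fv$condition <- row$condition; fv$field <- row$field
    frows[[i]] <- fv
  }
  fields <- do.call(rbind, frows)
  animals <- do.call(rbind, lapply(split(fields, fields$animal), function(sub)
    animal_mean(sub, animal = sub$animal[1], condition = sub$condition[1])))
  rownames(animals) <- NULL
  animals <- animals[order(match(animals$animal, unique(manifest$animal))), ]
  rownames(animals) <- NULL
  normalized <- normalize_to_control(animals, control_condition)
  groups <- summarize_groups(normalized)
  report <- tryCatch(run_study_stats(normalized, alpha = alpha),
                     error = function(e) NULL)
  list(fields = fields, animals = animals, normalized = normalized,
       groups = groups, stats = report)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a
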