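#' Construct a microscope field image
#'
#' A `field_image` is one photographed microscope field: an 8-bit RGB raster
#' (height x width x 3 array of integers in 0..255) plus the metadata needed
#' to place it in a study (animal id, experimental condition, field index).
#'
#' @param pixels numeric array of dimension `c(height, width, 3)` with values
#'   in `[0, 255]`. Values are rounded to integers.
#' @param animal animal identifier (character scalar or `NA`).
#' @param condition experimental condition label (e.g. `"Control"`, `"8I"`).
#' @param field field index within the slide.
#' @param magnification optional free-text magnification tag (e.g. `"600x"`).
#'
#' @return An object of class `field_image`: a list with elements `pixels`
#'   and `meta`.
#' @export
#' @examples
#' img <- field_image(array(200, dim = c(4, 4, 3)), animal = "a1")
#' dim(img$pixels)
field_image <- function(pixels, animal = NA_character_, condition = NA_character_,
                        field = NA_integer_, magnification = NA_character_) {
  pixels <- .validate_pixels(pixels)
  structure(
    list(
      pixels = pixels,
      meta = list(animal = as.character(animal),
                  condition = as.character(condition),
                  field = as.integer(field),
                  magnification = as.character(magnification))
    ),
    class = "field_image"
  )
}

.validate_pixels <- function(pixels) {
  if (inherits(pixels, "field_image")) return(pixels$pixels)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("image must be an RGB raster: a height x width x 3 array", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  px <- round(pixels)
  storage.mode(px) <- "integer"
  px
}

# Accept either a field_image or a bare raster everywhere user-facing.
.pixels <- function(image) .validate_pixels(image)

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<field_image> %d x %d px, 8-bit RGB\n", d[1], d[2]))
  m <- x$meta
  cat(sprintf("  animal: %s  condition: %s  field: %s\n",
              m$animal, m$condition, m$field))
  invisible(x)
}
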