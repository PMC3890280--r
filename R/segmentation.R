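#' RGB channel-interval thresholds for positive (formazan) staining
#'
#' The positive-stain predicate used in NADH-TR morphometry: a pixel is
#' positive when every channel lies inside its closed interval
#' `[low, high]`. The defaults are the published instrument settings for
#' blue-purple formazan — red 160/0, green 130/0, blue 175/66, read as
#' high/low bounds on the 0..255 RGB scale — i.e. low red and green (the
#' chromophore absorbs there) and mid-to-high blue.
#'
#' @param red,green,blue integer vectors `c(low, high)` with
#'   `0 <= low <= high <= 255`.
#' @return An object of class `channel_thresholds`.
#' @seealso [segment_positive()]
#' @export
#' @examples
#' channel_thresholds()                       # published defaults
#' channel_thresholds(blue = c(50, 200))      # widen the blue window
channel_thresholds <- function(red = c(0L, 160L), green = c(0L, 130L),
                               blue = c(66L, 175L)) {
  chk <- function(v, nm) {
    .assert(is.numeric(v) && length(v) == 2L && !anyNA(v),
            nm, " must be c(low, high)")
    v <- as.integer(round(v))
    .assert(v[1] <= v[2], nm, ": low must be <= high")
    .assert(v[1] >= 0L && v[2] <= 255L, nm, " bounds must lie in [0, 255]")
    v
  }
  structure(list(red = chk(red, "red"), green = chk(green, "green"),
                 blue = chk(blue, "blue")),
            class = "channel_thresholds")
}

#' @export
print.channel_thresholds <- function(x, ...) {
  cat(sprintf("<channel_thresholds> red [%d, %d]  green [%d, %d]  blue [%d, %d]\n",
              x$red[1], x$red[2], x$green[1], x$green[2], x$blue[1], x$blue[2]))
  invisible(x)
}

#' Threshold an RGB field for positive (formazan) staining
#'
#' Applies the channel-interval predicate pixelwise: positive iff
#' red, green and blue each lie inside their closed `[low, high]` interval.
#' Bounds are inclusive, so 8-bit images segment deterministically.
#'
#' @param image a [field_image()] or a height x width x 3 raster in 0..255.
#' @param thresholds a [channel_thresholds()] object.
#' @return Logical matrix (height x width); `TRUE` = positive stain.
#' @export
#' @examples
#' img <- array(0L, dim = c(2, 2, 3))
#' img[, , 1] <- 100; img[, , 2] <- 80; img[, , 3] <- 120
#' segment_positive(img)         # all TRUE under the defaults
segment_positive <- function(image, thresholds = channel_thresholds()) {
  px <- .pixels(image)
  .assert(inherits(thresholds, "channel_thresholds"),
          "thresholds must be a channel_thresholds object")
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  r >= thresholds$red[1]   & r <= thresholds$red[2] &
  g >= thresholds$green[1] & g <= thresholds$green[2] &
  b >= thresholds$blue[1]  & b <= thresholds$blue[2]
}

#' Delineate total muscle-fiber area
#'
#' Fiber pixels are darker than the pale interstitium/background. The mask is
#' `luminance < luminance_factor * ref`, where `ref` is a high percentile of
#' the field's luminance (the background level), followed by morphological
#' closing and hole filling. When a field contains no pale background at all
#' (e.g. wall-to-wall stained tissue) the percentile reference would sit on
#' tissue itself; `bg_floor` guards against that: the reference is never
#' taken below it, so uniformly dark fields segment as all-fiber and
#' uniformly pale fields as empty.
#'
#' @param image a [field_image()] or RGB raster.
#' @param luminance_factor fraction of the background reference below which a
#'   pixel counts as tissue (default 0.92).
#' @param bg_quantile percentile of luminance used as the background
#'   reference (default 0.99).
#' @param bg_floor minimum admissible background reference on the 0..255 luma
#'   scale (default 180).
#' @param close_radius radius (px) of the disc used for morphological
#'   closing; 0 disables (default 2).
#' @param fill_holes fill enclosed holes (unstained patches inside fibers)?
#'   Default `TRUE`.
#' @param min_size drop connected components smaller than this many pixels
#'   (default 0 = keep all).
#' @return Logical matrix; `TRUE` = fiber.
#' @export
segment_fibers <- function(image, luminance_factor = 0.92, bg_quantile = 0.99,
                           bg_floor = 180, close_radius = 2,
                           fill_holes = TRUE, min_size = 0) {
  px <- .pixels(image)
  lum <- .luminance(px)
  ref <- max(stats::quantile(lum, bg_quantile, names = FALSE), bg_floor)
  mask <- lum < luminance_factor * ref
  if (!any(mask)) return(mask)
  if (close_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L, shape = "disc")
    mask <- EBImage::closing(mask * 1, brush) > 0.5
  }
  if (fill_holes) mask <- EBImage::fillHull(mask * 1) > 0.5
  if (min_size > 0) {
    lab <- EBImage::bwlabel(mask * 1)
    keep <- which(tabulate(lab[lab > 0]) >= min_size)
    mask <- matrix(lab %in% keep, nrow = nrow(mask))
  }
  mask
}

# Exact Otsu threshold for a small sample of per-fiber means: choose the cut
# between consecutive sorted values maximizing between-class variance.
# Returns the smallest value assigned to the upper (denser) class; if every
# value is identical there is nothing to split and all belong to the upper
# class (tie rule: Type I).
.otsu_split <- function(v) {
  u <- sort(unique(v))
  if (length(u) == 1L) return(u[1])
  s <- sort(v); n <- length(s)
  cums <- cumsum(s); tot <- cums[n]
  k <- seq_len(n - 1L)
  m1 <- cums[k] / k
  m2 <- (tot - cums[k]) / (n - k)
  bcv <- k * (n - k) * (m1 - m2)^2   # /n^2 omitted: monotone
  kb <- which.max(bcv)
  s[kb + 1L]                          # first member of the dense class
}

#' Classify labeled fibers as Type I or Type IIb by stain density
#'
#' NADH-TR stains mitochondria-rich slow oxidative (Type I) fibers intensely
#' and mitochondria-poor fast glycolytic (Type IIb) fibers lightly. Each
#' fiber instance is scored by its mean optical density (255 - luma) over its
#' positively stained pixels — the stain colour, not the stained *area*, is
#' what distinguishes the types — falling back to all fiber pixels when a
#' fiber has no positive pixel. The per-fiber scores are split into two
#' classes; the denser class is Type I. Ties at the threshold go to Type I.
#'
#' @param image a [field_image()] or RGB raster.
#' @param instances integer matrix of fiber instance labels (0 = no fiber).
#' @param method `"otsu"` (default): exact Otsu split of the per-fiber score
#'   distribution; `"fixed"`: compare scores against `threshold`. Otsu
#'   assumes both types are present in the field; use `"fixed"` for
#'   single-type fields.
#' @param threshold fixed optical-density threshold (0..255 scale); scores
#'   `>= threshold` are Type I. Required for `method = "fixed"`.
#' @param thresholds positive-stain thresholds used to pick the scored pixels.
#' @return A list with logical masks `type1`, `type2b` and a data frame
#'   `fibers` (columns `fiber`, `n_px`, `n_positive`, `mean_density`, `type`).
#' @export
classify_fiber_types <- function(image, instances,
                                 method = c("otsu", "fixed"), threshold = NULL,
                                 thresholds = channel_thresholds()) {
  method <- match.arg(method)
  px <- .pixels(image)
  .assert(is.matrix(instances) || (is.array(instances) && length(dim(instances)) == 2L),
          "instances must be an integer label matrix")
  .assert(all(dim(instances) == dim(px)[1:2]), "instances shape must match image")
  ids <- sort(unique(as.integer(instances[instances > 0])))
  .assert(length(ids) >= 1L, "instance raster contains no fiber")
  if (method == "fixed")
    .assert(is.numeric(threshold) && length(threshold) == 1L,
            "method = \"fixed\" needs a numeric threshold")

  od <- 255 - .luminance(px)
  pos <- segment_positive(px, thresholds)
  lab <- as.integer(instances)

  n_px <- tabulate(lab, nbins = max(ids))[ids]
  pos_lab <- lab[pos]
  n_pos <- tabulate(pos_lab, nbins = max(ids))[ids]
  # grouped sums of optical density (rowsum orders groups by sorted label)
  sum_pos <- if (length(pos_lab))
    as.numeric(rowsum(od[pos], group = pos_lab, reorder = TRUE)) else numeric(0)
  pos_ids <- if (length(pos_lab)) sort(unique(pos_lab)) else integer(0)
  infib <- lab > 0L
  sum_all <- as.numeric(rowsum(as.numeric(od[infib]), group = lab[infib],
                               reorder = TRUE))

  score <- sum_all / n_px                      # fallback: all fiber pixels
  if (length(pos_ids)) {
    idx <- match(pos_ids, ids)
    score[idx] <- sum_pos / n_pos[idx]         # preferred: positive pixels
  }

  thr <- if (method == "otsu") .otsu_split(score) else threshold
  type <- ifelse(score >= thr, "TypeI", "TypeIIb")

  is_t1 <- logical(max(ids))
  is_t1[ids[type == "TypeI"]] <- TRUE
  type1 <- matrix(lab > 0L & is_t1[pmax(lab, 1L)], nrow(od), ncol(od))
  type2b <- (instances > 0L) & !type1

  list(type1 = type1, type2b = type2b,
       fibers = data.frame(fiber = ids, n_px = n_px, n_positive = n_pos,
                           mean_density = score, type = type,
                           stringsAsFactors = FALSE))
}

#' Segment a field into fiber, positive-stain and fiber-type masks
#'
#' Composes the full per-field segmentation: fiber delineation, fiber
#' instance labeling, per-fiber type classification and positive-stain
#' thresholding. The positive mask is intersected with the fiber mask so
#' `positive` is always a subset of `fiber`, and the two type masks always
#' partition the fiber mask.
#'
#' @param image a [field_image()] or RGB raster.
#' @param thresholds a [channel_thresholds()] object.
#' @param instances optional known fiber instance labels (e.g. generator
#'   ground truth). When `NULL`, instances are recovered from the image:
#'   [segment_fibers()], then connected components split by watershed on the
#'   distance map.
#' @param fiber_params list of arguments passed on to [segment_fibers()].
#' @param typing `"otsu"` or `"fixed"`; see [classify_fiber_types()].
#' @param type_threshold threshold for `typing = "fixed"`.
#' @param watershed split touching components by watershed? Default `TRUE`
#'   (only used when instances are recovered from the image).
#' @return An object of class `field_masks`: list with logical masks `fiber`,
#'   `positive`, `type1`, `type2b`, the integer `instances` raster, the
#'   per-fiber table `fibers`, and a logical `empty` flag.
#' @export
segment_field <- function(image, thresholds = channel_thresholds(),
                          instances = NULL, fiber_params = list(),
                          typing = c("otsu", "fixed"), type_threshold = NULL,
                          watershed = TRUE) {
  typing <- match.arg(typing)
  px <- .pixels(image)
  h <- dim(px)[1]; w <- dim(px)[2]

  if (is.null(instances)) {
    fiber <- do.call(segment_fibers, c(list(px), fiber_params))
    if (any(fiber)) {
      instances <- if (watershed)
        .label_watershed(fiber) else EBImage::bwlabel(fiber * 1)
      instances <- matrix(as.integer(instances), h, w)
    } else {
      instances <- matrix(0L, h, w)
    }
  } else {
    .assert(all(dim(instances) == c(h, w)), "instances shape must match image")
    instances <- matrix(as.integer(instances), h, w)
    fiber <- instances > 0L
  }

  empty <- !any(fiber)
  if (empty) {
    warning("field contains no fiber pixels; returning empty masks")
    f <- matrix(FALSE, h, w)
    return(structure(list(fiber = f, positive = f, type1 = f, type2b = f,
                          instances = instances,
                          fibers = data.frame(), empty = TRUE),
                     class = "field_masks"))
  }

  cls <- classify_fiber_types(px, instances, method = typing,
                              threshold = type_threshold,
                              thresholds = thresholds)
  positive <- segment_positive(px, thresholds) & fiber

  structure(list(fiber = fiber, positive = positive,
                 type1 = cls$type1, type2b = cls$type2b,
                 instances = instances, fibers = cls$fibers, empty = FALSE),
            class = "field_masks")
}

# Connected components split on the interstitial ridge: watershed of the
# distance map, which separates touching convex blobs at their waist.
.label_watershed <- function(mask) {
  dm <- EBImage::distmap(mask * 1)
  EBImage::watershed(dm, tolerance = 1)
}

#' @export
print.field_masks <- function(x, ...) {
  cat(sprintf("<field_masks> %d x %d px, %d fibers, fiber area %d px, positive %d px\n",
              nrow(x$fiber), ncol(x$fiber), nrow(x$fibers),
              sum(x$fiber), sum(x$positive)))
  invisible(x)
}
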