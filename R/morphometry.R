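#' Area-fraction viability of one field
#'
#' The core morphometric statistic: viability is the area of positive
#' (formazan) staining as a proportion of the area of muscle fibers —
#' computed for all fibers together and for each fiber type separately
#' (positive area within the type over that type's fiber area). A fraction
#' whose denominator is zero (e.g. no Type I fiber in the field) is
#' undefined and returned as `NA`, never as 0.
#'
#' @param masks a `field_masks` object from [segment_field()], or any list
#'   with logical matrices `fiber`, `positive`, `type1`, `type2b` of a common
#'   shape satisfying positive ⊆ fiber and type1/type2b partitioning fiber.
#' @return One-row data frame of class `field_viability`: pixel counts
#'   (`fiber_px`, `positive_px`, `type1_px`, `type1_positive_px`,
#'   `type2b_px`, `type2b_positive_px`) and fractions (`total_fraction`,
#'   `type1_fraction`, `type2b_fraction`).
#' @export
#' @examples
#' m <- list(fiber  = matrix(TRUE, 10, 10),
#'           positive = matrix(c(TRUE, FALSE), 10, 10),
#'           type1 = matrix(TRUE, 10, 10), type2b = matrix(FALSE, 10, 10))
#' field_viability(m)$total_fraction   # 0.5
field_viability <- function(masks) {
  req <- c("fiber", "positive", "type1", "type2b")
  .assert(all(req %in% names(masks)), "masks must contain ", paste(req, collapse = ", "))
  dims <- lapply(masks[req], dim)
  .assert(length(unique(dims)) == 1L, "mask shapes are inconsistent")
  fiber <- masks$fiber; positive <- masks$positive & fiber
  t1 <- masks$type1; t2 <- masks$type2b

  frac <- function(num, den) if (den == 0L) NA_real_ else num / den
  n_fib <- sum(fiber); n_pos <- sum(positive)
  n_t1 <- sum(t1); n_t1p <- sum(positive & t1)
  n_t2 <- sum(t2); n_t2p <- sum(positive & t2)

  structure(data.frame(
    fiber_px = n_fib, positive_px = n_pos,
    type1_px = n_t1, type1_positive_px = n_t1p,
    type2b_px = n_t2, type2b_positive_px = n_t2p,
    total_fraction = frac(n_pos, n_fib),
    type1_fraction = frac(n_t1p, n_t1),
    type2b_fraction = frac(n_t2p, n_t2)),
    class = c("field_viability", "data.frame"))
}

#' Average field viabilities into one per-animal record
#'
#' Each measurement (total, Type I, Type IIb) is the unweighted arithmetic
#' mean over the fields where it is defined; fields with an undefined
#' measurement (zero denominator) are excluded from that measurement only,
#' with a warning.
#'
#' @param fields a data frame of stacked [field_viability()] rows (or a list
#'   of them).
#' @param animal,condition identifiers recorded in the result.
#' @return One-row data frame of class `animal_viability`: `animal`,
#'   `condition`, `total`, `type1`, `type2b` (mean raw fractions) and
#'   `n_fields_total`, `n_fields_type1`, `n_fields_type2b` (contributing
#'   field counts).
#' @export
animal_mean <- function(fields, animal = NA_character_, condition = NA_character_) {
  if (is.list(fields) && !is.data.frame(fields))
    fields <- do.call(rbind, fields)
  .assert(is.data.frame(fields) && nrow(fields) >= 1L, "need at least one field")
  .assert(all(c("total_fraction", "type1_fraction", "type2b_fraction") %in%
              names(fields)), "fields must carry viability fractions")
  if (all(is.na(fields$total_fraction)))
    stop("all fields have undefined total viability", call. = FALSE)

  avg <- function(v, what) {
    n_na <- sum(is.na(v))
    if (n_na > 0)
      warning(sprintf("%d field(s) excluded from %s mean (no such fibers)",
                      n_na, what))
    if (n_na == length(v)) return(c(NA_real_, 0))
    c(mean(v, na.rm = TRUE), length(v) - n_na)
  }
  tt <- avg(fields$total_fraction, "total")
  a1 <- avg(fields$type1_fraction, "Type I")
  a2 <- avg(fields$type2b_fraction, "Type IIb")

  structure(data.frame(
    animal = as.character(animal), condition = as.character(condition),
    total = tt[1], type1 = a1[1], type2b = a2[1],
    n_fields_total = as.integer(tt[2]),
    n_fields_type1 = as.integer(a1[2]),
    n_fields_type2b = as.integer(a2[2]),
    stringsAsFactors = FALSE),
    class = c("animal_viability", "data.frame"))
}

#' Express per-animal viability as percent of the untreated-control mean
#'
#' For each measurement separately (total, Type I, Type IIb), the mean raw
#' fraction over the control animals defines 100%; every animal's value is
#' `100 * raw / control_mean` for the matching measurement. The control
#' group's normalized mean is therefore exactly 100.0 for all three
#' measurements by construction.
#'
#' @param animals data frame of stacked [animal_mean()] rows.
#' @param control_condition label of the untreated control group.
#' @return The input with `total`, `type1`, `type2b` replaced by normalized
#'   percents; class `normalized_viability`. Control means used are attached
#'   as attribute `control_means`.
#' @export
normalize_to_control <- function(animals, control_condition = "Control") {
  .assert(is.data.frame(animals) && nrow(animals) >= 1L, "empty animal table")
  ctrl <- animals[animals$condition == control_condition, , drop = FALSE]
  .assert(nrow(ctrl) >= 1L, "no animal with control condition ",
          deparse(control_condition))
  out <- animals
  cm <- c(total = NA_real_, type1 = NA_real_, type2b = NA_real_)
  for (m in c("total", "type1", "type2b")) {
    cmean <- mean(ctrl[[m]], na.rm = TRUE)
    if (!is.finite(cmean) || cmean == 0)
      stop("control mean for ", m, " is zero or undefined; cannot normalize",
           call. = FALSE)
    cm[m] <- cmean
    out[[m]] <- 100 * animals[[m]] / cmean
  }
  structure(out, control_means = cm,
            class = c("normalized_viability", "data.frame"))
}

#' Group summary: mean ± s.e.m. of normalized viability
#'
#' Per condition and measurement: mean, standard error of the mean (sample
#' SD with `n - 1` over the square root of `n`), and `n` animals.
#'
#' @param normalized a [normalize_to_control()] table (or any animal-level
#'   data frame with `condition`, `total`, `type1`, `type2b`).
#' @return Long-format data frame of class `group_summary` with columns
#'   `condition`, `measurement` (`total`, `type1`, `type2b`), `mean`, `sem`,
#'   `n`.
#' @export
summarize_groups <- function(normalized) {
  .assert(is.data.frame(normalized) && nrow(normalized) >= 1L, "empty table")
  conds <- unique(normalized$condition)
  rows <- list()
  for (cond in conds) {
    sub <- normalized[normalized$condition == cond, , drop = FALSE]
    for (m in c("total", "type1", "type2b")) {
      v <- sub[[m]][!is.na(sub[[m]])]
      n <- length(v)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, measurement = m,
        mean = if (n) mean(v) else NA_real_,
        sem = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_,
        n = n, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("group_summary", "data.frame"))
}

#' @export
print.group_summary <- function(x, digits = 1, ...) {
  cat("Normalized muscle fiber viability (% of control), mean ± s.e.m.\n")
  wide <- stats::reshape(
    transform(as.data.frame(x),
              cell = sprintf(paste0("%.", digits, "f ± %.", digits, "f (n=%d)"),
                             mean, sem, n))[, c("condition", "measurement", "cell")],
    idvar = "condition", timevar = "measurement", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}
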