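# Study-level synthesis and measurement. Field images are rendered on
# demand from lightweight per-field specs (a 512x512 study of 240 fields
# would otherwise hold ~1.5 GB of rasters in memory at once).

# Per-animal jitter of the per-type target stained fractions.
#
# Per-animal biological variation is additive on the percent-of-control
# scale (the study's group s.e.m. are a roughly constant 3-6 points across
# all injury levels). Draws are centred to zero mean within the group, so
# the realized group-level ground truth equals the preset exactly while the
# between-animal spread is preserved, and rejection-resampled until every
# animal's stained fraction is feasible ([0, 1] after multiplying by the
# control coverage) — which mildly shrinks the spread for groups near the
# floor or ceiling.
.jitter_retentions <- function(preset, n, sd, coverage) {
  if (sd == 0) return(rep(preset, n))
  for (try in 1:1000) {
    z <- stats::rnorm(n, 0, sd)
    z <- z - mean(z)
    eff <- preset + z
    if (all(eff >= 0 & eff * coverage <= 1)) return(eff)
  }
  stop("could not draw feasible between-animal retentions (sd too large ",
       "for preset ", preset, ")", call. = FALSE)
}

#' Generate a multi-animal, multi-field synthetic study
#'
#' Lays out a full study: per condition, `n` animals; per animal, per-type
#' stain retentions jittered around the condition preset (shared by all of
#' the animal's fields, as in a real animal); per field, an independent
#' seeded section spec. All randomness flows from the single top-level
#' `seed`. Fields are *not* rendered here — each manifest row carries a
#' complete [synthetic_section_spec()]; render with [generate_section()] or
#' measure directly with [measure_study()].
#'
#' @param design named integer vector: condition label -> number of
#'   animals, e.g. `c(Control = 6, "8I" = 6)`.
#' @param fields_per_animal fields photographed per animal (default 10).
#' @param seed top-level integer seed.
#' @param animal_sd between-animal SD of the per-type retention, on the
#'   fraction-of-control scale (default 0.09, giving group s.e.m. of ~3-6
#'   percentage points at n = 6).
#' @param overrides named list of [synthetic_section_spec()] arguments
#'   applied to every field (e.g. `list(width_px = 256, noise_sd = 0)`).
#' @return Object of class `synthetic_study`: list with `manifest` (data
#'   frame: `animal`, `condition`, `field`, `seed`) and `specs` (list of
#'   per-field `synthetic_section_spec`, parallel to the manifest rows).
#' @export
#' @examples
#' st <- generate_study(c(Control = 2, `9I` = 2), fields_per_animal = 2,
#'                      seed = 1, overrides = list(width_px = 96, height_px = 96,
#'                                                 n_fibers = 12))
#' st$manifest
generate_study <- function(design, fields_per_animal = 10, seed = 1,
                           animal_sd = 0.09, overrides = list()) {
  .assert(length(design) >= 1L && !is.null(names(design)) &&
          all(nzchar(names(design))), "design must be a named vector")
  .assert(all(design >= 1), "each condition needs n_animals >= 1")
  .assert(.is_count(fields_per_animal), "fields_per_animal must be >= 1")

  specs <- list(); rows <- list()
  .with_seed(seed, {
    for (cond in names(design)) {
      base <- do.call(condition_preset, c(list(cond), overrides))
      n_an <- as.integer(design[[cond]])
      eff1 <- .jitter_retentions(base$retention_type1, n_an, animal_sd,
                                 base$control_coverage)
      eff2 <- .jitter_retentions(base$retention_type2b, n_an, animal_sd,
                                 base$control_coverage)
      for (a in seq_len(n_an)) {
        animal_id <- paste(cond, a, sep = "_")
        # the animal's condition re-expressed as its own stained fractions,
        # keeping the per-field spec's retention inside [0, 1]
        q1 <- .clip(eff1[a] * base$control_coverage, 0, 1)
        q2 <- .clip(eff2[a] * base$control_coverage, 0, 1)
        for (f in seq_len(fields_per_animal)) {
          fseed <- sample.int(.Machine$integer.max - 1L, 1L)
          spec <- base
          spec$retention_type1 <- q1
          spec$retention_type2b <- q2
          spec$control_coverage <- 1
          spec$seed <- fseed
          specs[[length(specs) + 1L]] <- spec
          rows[[length(rows) + 1L]] <- data.frame(
            animal = animal_id, condition = cond, field = f, seed = fseed,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  structure(list(manifest = do.call(rbind, rows), specs = specs,
                 seed = as.integer(seed), animal_sd = animal_sd),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<synthetic_study> %d conditions, %d animals, %d fields (seed %d)\n",
              length(unique(m$condition)), length(unique(m$animal)), nrow(m),
              x$seed))
  print(table(condition = m$condition[!duplicated(m$animal)]))
  invisible(x)
}

#' Measure a synthetic study through the segmentation pipeline
#'
#' Renders each field, segments it ([segment_field()]), computes field
#' viability and per-animal means. `instance_source = "truth"` hands the
#' generator's fiber geometry to the segmenter (the rendered background
#' gives no luminance cue where stain is lost, so image-derived outlines
#' are only reliable on near-fully-stained fields); the positive-stain
#' measurement is always taken from the rendered image by colour
#' thresholding. `instance_source = "image"` recovers instances from the
#' image alone.
#'
#' @param study a [generate_study()] object.
#' @param thresholds a [channel_thresholds()].
#' @param instance_source `"truth"` (default) or `"image"`.
#' @param typing passed to [segment_field()].
#' @param progress print a dot per field (default `FALSE`).
#' @return List with data frames `fields` (per-field viability + truth
#'   fractions) and `animals` (per-animal means, [animal_mean()] rows).
#' @export
measure_study <- function(study, thresholds = channel_thresholds(),
                          instance_source = c("truth", "image"),
                          typing = "otsu", progress = FALSE) {
  .assert(inherits(study, "synthetic_study"), "study must be a synthetic_study")
  instance_source <- match.arg(instance_source)
  m <- study$manifest
  frows <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    sec <- generate_section(study$specs[[i]])
    inst <- if (instance_source == "truth") sec$truth$labels else NULL
    masks <- segment_field(sec$image, thresholds = thresholds,
                           instances = inst, typing = typing)
    fv <- field_viability(masks)
    fv$animal <- m$animal[i]; fv$condition <- m$condition[i]
    fv$field <- m$field[i]
    fv$true_total_fraction <- sec$truth$true_total_fraction
    fv$true_type1_fraction <- sec$truth$true_type1_fraction
    fv$true_type2b_fraction <- sec$truth$true_type2b_fraction
    frows[[i]] <- fv
    if (progress) {
      cat(".")
      if (i %% 60 == 0 || i == nrow(m)) cat(" ", i, "/", nrow(m), "\n", sep = "")
    }
  }
  fields <- do.call(rbind, frows)
  animals <- do.call(rbind, lapply(split(fields, fields$animal), function(sub)
    animal_mean(sub, animal = sub$animal[1], condition = sub$condition[1])))
  animals <- animals[order(match(animals$animal, unique(m$animal))), ]
  rownames(animals) <- NULL
  list(fields = fields, animals = animals)
}

#' Simulate and analyze a complete viability study end to end
#'
#' One-call pipeline: synthesize a study at the condition presets, run
#' segmentation and morphometry on every field, normalize to the control
#' group, summarize groups, and run the statistical layer. This is the
#' package's top-level entry point for parameter-recovery experiments.
#'
#' @param conditions condition labels (see [condition_preset()]); must
#'   include `control_condition`.
#' @param n_animals animals per condition (default 6).
#' @param fields_per_animal fields per animal (default 10).
#' @param seed top-level seed.
#' @param control_condition label of the normalization reference.
#' @param alpha significance level for the statistics layer.
#' @param overrides per-field spec overrides, as in [generate_study()].
#' @param animal_sd between-animal retention SD, as in [generate_study()].
#' @param instance_source,typing passed to [measure_study()].
#' @param stats run the statistical layer (default `TRUE`; needs >= 2
#'   animals per condition for the balanced ANOVA).
#' @param progress print per-field progress.
#' @return Object of class `viability_study`: `study` (the generated
#'   design), `fields`, `animals` (raw fractions), `normalized` (percent of
#'   control), `groups` (a [summarize_groups()] table), `stats` (a
#'   [run_study_stats()] report), and the call parameters.
#' @export
#' @examples
#' vs <- viability_study(c("Control", "9I"), n_animals = 2,
#'                       fields_per_animal = 2, seed = 1,
#'                       overrides = list(width_px = 96, height_px = 96,
#'                                        n_fibers = 12),
#'                       stats = FALSE)
#' vs$groups
viability_study <- function(conditions = c("Control", "4I", "6I", "8I", "9I"),
                            n_animals = 6, fields_per_animal = 10, seed = 1,
                            control_condition = "Control", alpha = 0.05,
                            overrides = list(), animal_sd = 0.09,
                            instance_source = "truth", typing = "otsu",
                            stats = TRUE, progress = FALSE) {
  .assert(control_condition %in% conditions,
          "conditions must include the control condition")
  design <- stats::setNames(rep(as.integer(n_animals), length(conditions)),
                            conditions)
  study <- generate_study(design, fields_per_animal = fields_per_animal,
                          seed = seed, animal_sd = animal_sd,
                          overrides = overrides)
  meas <- measure_study(study, instance_source = instance_source,
                        typing = typing, progress = progress)
  normalized <- normalize_to_control(meas$animals,
                                     control_condition = control_condition)
  groups <- summarize_groups(normalized)
  report <- if (isTRUE(stats) && length(conditions) >= 2L)
    tryCatch(run_study_stats(normalized, alpha = alpha),
             error = function(e) e) else NULL

  structure(list(study = study, fields = meas$fields, animals = meas$animals,
                 normalized = normalized, groups = groups, stats = report,
                 seed = as.integer(seed), alpha = alpha,
                 control_condition = control_condition),
            class = "viability_study")
}

#' @export
print.viability_study <- function(x, ...) {
  m <- x$study$manifest
  cat(sprintf("Muscle fiber viability study (synthetic): %d animals x %d fields, seed %d\n\n",
              length(unique(m$animal)), max(m$field), x$seed))
  print(x$groups)
  invisible(x)
}

#' @export
summary.viability_study <- function(object, ...) {
  print(object)
  if (inherits(object$stats, "stats_report")) {
    cat("\n")
    print(object$stats)
  }
  invisible(object)
}

#' @export
plot.viability_study <- function(x, measurement = "total", ...) {
  g <- x$groups[x$groups$measurement == measurement, ]
  hours <- .ischemia_hours(g$condition)
  ok <- !is.na(hours)
  g <- g[ok, ]; hours <- hours[ok]
  o <- order(hours)
  graphics::plot(hours[o], g$mean[o], type = "b", pch = 19,
                 xlab = "Ischemia (h)",
                 ylab = sprintf("%s viability (%% of control)", measurement),
                 ylim = range(c(g$mean - g$sem, g$mean + g$sem, 0, 100)), ...)
  graphics::arrows(hours[o], g$mean[o] - g$sem[o],
                   hours[o], g$mean[o] + g$sem[o],
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}
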