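# Small in-code fixtures shared across test files.

# Uniform-colour RGB raster.
flat_rgb <- function(rgb, h = 8, w = 8) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# Small, fast synthetic section spec; noise off unless asked for.
tiny_spec <- function(..., seed = 1) {
  args <- list(width_px = 96, height_px = 96, n_fibers = 12,
               interstitium_width_px = 2, patch_scale_px = 4,
               noise_sd = 0, illumination_gradient = 0, seed = seed)
  user <- list(...)
  args[names(user)] <- user
  do.call(synthetic_section_spec, args)
}

# Independent oracle for the positive predicate: naive per-pixel double loop.
naive_positive <- function(px, thr) {
  h <- dim(px)[1]; w <- dim(px)[2]
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    v <- px[i, j, ]
    out[i, j] <- v[1] >= thr$red[1] && v[1] <= thr$red[2] &&
                 v[2] >= thr$green[1] && v[2] <= thr$green[2] &&
                 v[3] >= thr$blue[1] && v[3] <= thr$blue[2]
  }
  out
}

# Random 8-bit RGB image spanning the threshold boundaries.
random_rgb <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Naive two-pass Pearson oracle, independent of stats::cor.test.
naive_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
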