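# Table-level Monte Carlo harnesses for the statistical layer. These work on
# simulated animal-level viability tables directly (no images), so they are
# cheap enough for repeated simulation.

#' Printed study table: group means and s.e.m. of normalized viability
#'
#' The reference ischemia-study table (percent of control, n = 6 per group)
#' used to calibrate simulations: Type IIb, Type I and total fiber
#' viability for untreated control and 4, 6, 8, 9 hours of ischemia.
#'
#' @return Data frame with columns `condition`, `hours`, `measurement`,
#'   `mean`, `sem`, `n`.
#' @export
ischemia_reference_table <- function() {
  cond <- c("Control", "4I", "6I", "8I", "9I")
  hours <- c(0, 4, 6, 8, 9)
  means <- rbind(c(100.0, 100.0, 100.0),
                 c(61.9, 58.8, 60.5),
                 c(46.4, 39.5, 43.8),
                 c(29.1, 20.1, 24.3),
                 c(15.5,  9.5, 12.1))
  sems <- rbind(c(5.7, 4.1, 3.9),
                c(4.3, 5.9, 5.6),
                c(4.2, 5.2, 5.4),
                c(3.5, 6.2, 5.7),
                c(3.9, 3.1, 2.9))
  meas <- c("type2b", "type1", "total")
  do.call(rbind, lapply(1:3, function(j)
    data.frame(condition = cond, hours = hours, measurement = meas[j],
               mean = means[, j], sem = sems[, j], n = 6L,
               stringsAsFactors = FALSE)))
}

# Draw one simulated animal-level table from group means/SDs.
.simulate_table <- function(ref, n) {
  conds <- unique(ref$condition)
  out <- expand.grid(animal = seq_len(n), condition = conds,
                     stringsAsFactors = FALSE)
  for (m in unique(ref$measurement)) {
    sub <- ref[ref$measurement == m, ]
    mu <- sub$mean[match(out$condition, sub$condition)]
    sdv <- sub$sem[match(out$condition, sub$condition)] * sqrt(sub$n[1])
    out[[m]] <- stats::rnorm(nrow(out), mu, sdv)
  }
  out$animal <- paste(out$condition, out$animal, sep = "_")
  out
}

#' Family-wise error of Scheffé pairwise tests under the global null
#'
#' Simulates studies with `k` identical group means and counts how often at
#' least one pairwise Scheffé comparison (one-way layout) is declared
#' significant. Scheffé protects all contrasts, so for pairwise use the
#' family-wise error should stay at or below `alpha`.
#'
#' @param k number of groups; @param n animals per group.
#' @param reps simulated studies.
#' @param alpha level per family.
#' @param sd common within-group SD.
#' @param seed RNG seed.
#' @return List: `fwer` (fraction of studies with any significant pair),
#'   `se` (binomial standard error), `reps`.
#' @export
simulate_scheffe_null <- function(k = 7, n = 6, reps = 1000, alpha = 0.05,
                                  sd = 10, seed = 1) {
  .with_seed(seed, {
    hits <- 0L
    for (r in seq_len(reps)) {
      y <- matrix(stats::rnorm(k * n, 0, sd), k, n)
      gm <- rowMeans(y)
      ms <- sum((y - gm)^2) / (k * (n - 1))
      sc <- scheffe_posthoc(stats::setNames(gm, paste0("g", 1:k)), n = n,
                            ms_res = ms, df_res = k * (n - 1), alpha = alpha)
      if (any(sc$significant)) hits <- hits + 1L
    }
    p <- hits / reps
    list(fwer = p, se = sqrt(p * (1 - p) / reps), reps = reps)
  })
}

#' Sensitivity of consecutive-duration Scheffé comparisons
#'
#' Monte Carlo power harness at the reference study's effect sizes: each
#' replicate draws an animal-level table (per-animal values normal around
#' the printed group means with SD = printed s.e.m. x sqrt(n)), runs the
#' two-way (condition x measurement) ANOVA, and tests the consecutive
#' ischemia-duration pairs (Control-4I, 4I-6I, 6I-8I, 8I-9I) with Scheffé
#' on the condition marginal means.
#'
#' @param ref reference table, default [ischemia_reference_table()].
#' @param n animals per group.
#' @param reps simulated studies.
#' @param alpha level.
#' @param seed RNG seed.
#' @return List: `pair_power` (named per-pair significance rates),
#'   `all_consecutive` (fraction of replicates with every consecutive pair
#'   significant), `reps`.
#' @export
simulate_consecutive_power <- function(ref = ischemia_reference_table(),
                                       n = 6, reps = 200, alpha = 0.05,
                                       seed = 1) {
  ord <- unique(ref[order(ref$hours), "condition"])
  pairs <- cbind(ord[-length(ord)], ord[-1])
  pair_names <- paste(pairs[, 1], pairs[, 2], sep = "-")
  .with_seed(seed, {
    hit <- stats::setNames(numeric(nrow(pairs)), pair_names)
    all_hit <- 0L
    for (r in seq_len(reps)) {
      tab <- .simulate_table(ref, n)
      rep_stats <- run_study_stats(tab, alpha = alpha)
      sc <- rep_stats$scheffe
      key <- function(i, j) sc$significant[(sc$group_i == i & sc$group_j == j) |
                                           (sc$group_i == j & sc$group_j == i)]
      ok <- vapply(seq_len(nrow(pairs)),
                   function(p) any(key(pairs[p, 1], pairs[p, 2])), TRUE)
      hit <- hit + ok
      if (all(ok)) all_hit <- all_hit + 1L
    }
    list(pair_power = hit / reps, all_consecutive = all_hit / reps, reps = reps)
  })
}
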