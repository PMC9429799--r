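# Smoothed time-course analysis of the selection outcome (SMART).
#
# Each trial contributes one (fixation duration, outcome) point.  Per
# participant the binary outcome is kernel-smoothed over fixation duration;
# the group time course is a weighted average of participant curves with
# weights given by each participant's kernel density of data around a time
# point; inference uses a weighted paired t statistic per time point and a
# cluster-based permutation test on supra-threshold runs.

#' SMART analysis configuration
#'
#' Defaults are the study's analysis settings: a 1-ms grid on 100-750 ms
#' fixation duration, a Gaussian smoothing kernel of SD 48 ms, 1000
#' permutations, two-sided alpha 0.05.
#'
#' @param t_min,t_max Analysis window in ms.
#' @param step Grid step in ms.
#' @param kernel_sd Gaussian kernel SD in ms ("width" of the kernel is read
#'   as its SD, not FWHM).
#' @param n_permutations Number of label permutations per test (>= 100).
#' @param alpha Two-sided cluster-forming alpha.
#' @param seed Seed for the permutation draws.
#' @return A list of class `smart_config`.
#' @export
smart_config <- function(t_min = 100, t_max = 750, step = 1, kernel_sd = 48,
                         n_permutations = 1000, alpha = 0.05, seed = 1L) {
  stopifnot(t_max > t_min, step > 0, kernel_sd > 0, n_permutations >= 100,
            alpha > 0, alpha < 1)
  structure(list(grid = seq(t_min, t_max, by = step), kernel_sd = kernel_sd,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 seed = as.integer(seed)),
            class = "smart_config")
}

#' Kernel-smoothed outcome time course for one participant
#'
#' Nadaraya-Watson smoothing of the trial outcomes over fixation duration:
#' `curve(t) = sum_i K(t - rt_i) y_i / sum_i K(t - rt_i)` with a Gaussian
#' kernel, and `weight(t) = sum_i K(t - rt_i)` (the participant's data
#' density, used for the weighted group aggregation).  The curve is `NA`
#' where the weight underflows to zero.
#'
#' @param rt Fixation durations in ms.
#' @param y Outcomes (0/1 or logical; e.g. face chosen).
#' @param config A [smart_config()].
#' @return List with `curve` and `weight`, both over `config$grid`.
#' @export
smooth_participant <- function(rt, y, config = smart_config()) {
  stopifnot(length(rt) == length(y), length(rt) >= 1)
  y <- as.numeric(y)
  K <- exp(-outer(config$grid, rt, "-")^2 / (2 * config$kernel_sd^2))
  weight <- rowSums(K)
  curve <- ifelse(weight > 0, as.vector(K %*% y) / weight, NA_real_)
  list(curve = curve, weight = weight)
}

#' Weighted group time course
#'
#' Pointwise weighted mean of participant curves, weighting each participant
#' by their kernel data density at that point; participants with no weight
#' at a point are excluded there, and points where no participant has weight
#' are `NA`.
#'
#' @param curves Participants x grid matrix of smoothed curves.
#' @param weights Participants x grid matrix of kernel weights.
#' @return Numeric vector over the grid.
#' @export
weighted_group_timecourse <- function(curves, weights) {
  stopifnot(is.matrix(curves), is.matrix(weights),
            all(dim(curves) == dim(weights)), nrow(curves) >= 2)
  w <- weights
  w[is.na(curves) | w <= 0] <- 0
  cw <- curves * w
  cw[w == 0] <- 0
  tot <- colSums(w)
  ifelse(tot > 0, colSums(cw) / tot, NA_real_)
}

# Weighted paired t statistics over the grid for participant difference
# curves d (P x G) with weights w (P x G).  Weights are normalized per point
# to sum to the number of contributing participants, so the statistic
# reduces to the ordinary paired t for equal weights.  Returns t, df and the
# per-point count; points with fewer than 2 contributing participants get
# NA.  `signs` (n x P) computes the statistics under n sign-flip
# permutations at once.
weighted_t_grid <- function(d, w, signs = NULL) {
  w[is.na(d) | w <= 0] <- 0
  d[w == 0] <- 0
  n_g <- colSums(w > 0)
  totw <- colSums(w)
  ok <- n_g >= 2
  wt <- sweep(w, 2, ifelse(totw > 0, n_g / totw, 0), `*`) # normalized weights
  S2 <- colSums(wt * d * d)
  if (is.null(signs)) {
    m <- colSums(wt * d) / n_g
    s2 <- (S2 - n_g * m^2) / (n_g - 1)
    s2[s2 < 0] <- 0
    tval <- ifelse(ok & s2 > 0, m / sqrt(s2 / n_g), NA_real_)
    list(t = tval, df = n_g - 1, n = n_g, ok = ok)
  } else {
    M <- (signs %*% (wt * d))
    M <- sweep(M, 2, n_g, `/`)
    S2m <- matrix(S2, nrow(M), ncol(M), byrow = TRUE)
    Ng <- matrix(n_g, nrow(M), ncol(M), byrow = TRUE)
    s2 <- (S2m - Ng * M^2) / (Ng - 1)
    s2[s2 < 0] <- 0
    Tm <- M / sqrt(s2 / Ng)
    Tm[, !ok] <- NA
    Tm[!is.finite(Tm)] <- NA
    list(t = Tm, df = n_g - 1, n = n_g, ok = ok)
  }
}

# Maximal runs of consecutive supra-threshold points; returns a data frame
# of clusters with summed |t| strengths.
find_clusters <- function(tval, thresh, grid) {
  above <- !is.na(tval) & abs(tval) >= thresh
  if (!any(above)) {
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      strength = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  data.frame(start_ms = grid[starts[idx]], end_ms = grid[ends[idx]],
             strength = vapply(idx, function(i)
               sum(abs(tval[starts[i]:ends[i]])), 0.0))
}

max_cluster_strength_rows <- function(Tm, thresh_vec) {
  # Tm: permutations x grid; thresh_vec: per-point threshold
  A <- abs(Tm) >= matrix(thresh_vec, nrow(Tm), ncol(Tm), byrow = TRUE)
  A[is.na(A)] <- FALSE
  V <- abs(Tm)
  V[!A] <- 0
  out <- numeric(nrow(Tm))
  for (i in seq_len(nrow(Tm))) {
    x <- V[i, ]
    if (all(x == 0)) next
    cs <- cumsum(x)
    zero <- which(x == 0)
    # runs of nonzero values lie between consecutive zeros; their sums are
    # differences of the cumulative sum at the zero positions
    out[i] <- max(diff(c(0, cs[zero], cs[length(cs)])), 0)
  }
  out
}

#' Cluster-based permutation test between two time courses
#'
#' Smooths nothing itself: takes per-participant curves and weights for two
#' paired conditions (or one condition against a constant baseline),
#' computes the weighted paired t statistic at every grid point, forms
#' clusters as maximal runs of points with `|t|` above the two-sided
#' `alpha` threshold, and evaluates each cluster's strength (summed `|t|`)
#' against the permutation distribution of maximal cluster strengths
#' obtained by randomly swapping the two conditions' curves (with their
#' weights) within participants.  The critical value `t_crit` is the 95th
#' percentile of that distribution, and each cluster's p value is its
#' position in the distribution (floored at `1/(n_permutations + 1)`).
#'
#' @param curves_a,weights_a Participants x grid matrices for condition A.
#' @param curves_b,weights_b Matrices for condition B, or `NULL` to test
#'   condition A against `baseline`.
#' @param config A [smart_config()].
#' @param baseline Constant reference level for the one-condition test
#'   (default 0.5, chance level for a binary choice).
#' @return A list of class `smart_result`: `grid`, `group_a`, `group_b`,
#'   `t` (pointwise statistic), `clusters` (data frame with start/end ms,
#'   strength, p, significant), `t_crit`, `perm_max` (permutation
#'   distribution), `ci_halfwidth`, `config`.
#' @export
cluster_permutation_test <- function(curves_a, weights_a, curves_b = NULL,
                                     weights_b = NULL,
                                     config = smart_config(),
                                     baseline = 0.5) {
  stopifnot(is.matrix(curves_a), nrow(curves_a) >= 2)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  P <- nrow(curves_a)
  if (is.null(curves_b)) {
    d <- curves_a - baseline
    w <- weights_a
    group_b <- rep(baseline, ncol(curves_a))
  } else {
    stopifnot(all(dim(curves_b) == dim(curves_a)))
    d <- curves_a - curves_b
    # a point contributes through both conditions; weight = summed density
    w <- weights_a + weights_b
    w[is.na(curves_a) | is.na(curves_b)] <- 0
    group_b <- weighted_group_timecourse(curves_b, weights_b)
  }
  obs <- weighted_t_grid(d, w)
  thresh <- qt(1 - config$alpha / 2, pmax(obs$df, 1))
  clusters <- find_clusters(obs$t, thresh, config$grid)

  set.seed(config$seed)
  signs <- matrix(sample(c(-1, 1), config$n_permutations * P, replace = TRUE),
                  config$n_permutations, P)
  perm <- weighted_t_grid(d, w, signs = signs)
  perm_max <- max_cluster_strength_rows(perm$t, thresh)
  t_crit <- unname(quantile(perm_max, 0.95, type = 7))

  if (nrow(clusters) > 0) {
    clusters$p <- vapply(clusters$strength, function(s)
      (sum(perm_max >= s) + 1) / (config$n_permutations + 1), 0.0)
    clusters$significant <- clusters$strength >= t_crit
    clusters <- clusters[order(-clusters$strength), ]
    rownames(clusters) <- NULL
  } else {
    clusters$p <- numeric(0)
    clusters$significant <- logical(0)
  }

  ci <- difference_ci_internal(d, w, config)
  structure(list(grid = config$grid,
                 group_a = weighted_group_timecourse(curves_a, weights_a),
                 group_b = group_b,
                 t = obs$t,
                 n_contributing = obs$n,
                 clusters = clusters,
                 t_crit = t_crit,
                 perm_max = perm_max,
                 ci_halfwidth = ci,
                 config = config),
            class = "smart_result")
}

difference_ci_internal <- function(d, w, config) {
  w2 <- w
  w2[is.na(d) | w2 <= 0] <- 0
  d2 <- d; d2[w2 == 0] <- 0
  n_g <- colSums(w2 > 0)
  totw <- colSums(w2)
  wt <- sweep(w2, 2, ifelse(totw > 0, n_g / totw, 0), `*`)
  m <- ifelse(n_g > 0, colSums(wt * d2) / pmax(n_g, 1), NA_real_)
  s2 <- (colSums(wt * d2 * d2) - n_g * m^2) / pmax(n_g - 1, 1)
  s2[s2 < 0] <- 0
  se <- sqrt(s2 / pmax(n_g, 1))
  half <- qt(0.975, pmax(n_g - 1, 1)) * se / 2
  half[n_g < 2] <- NA_real_
  half
}

#' 95% confidence band of a paired time-course difference
#'
#' Per grid point: the two-sided critical t times the weighted SE of the
#' paired difference, halved so the band can be drawn around each of the two
#' curves being compared.
#'
#' @inheritParams cluster_permutation_test
#' @return Numeric vector of CI half-widths over the grid.
#' @export
difference_ci <- function(curves_a, weights_a, curves_b = NULL,
                          weights_b = NULL, config = smart_config(),
                          baseline = 0.5) {
  if (is.null(curves_b)) {
    d <- curves_a - baseline
    w <- weights_a
  } else {
    d <- curves_a - curves_b
    w <- weights_a + weights_b
    w[is.na(curves_a) | is.na(curves_b)] <- 0
  }
  difference_ci_internal(d, w, config)
}

#' @export
print.smart_result <- function(x, ...) {
  cat(sprintf("SMART cluster permutation test (%d-%d ms, %d permutations)\n",
              min(x$grid), max(x$grid), x$config$n_permutations))
  cat(sprintf("t_crit (95th pct of permuted max cluster strength): %.2f\n",
              x$t_crit))
  if (nrow(x$clusters) == 0) cat("no clusters\n") else print(x$clusters)
  invisible(x)
}

#' Run a SMART contrast on a session
#'
#' Smooths the face-choice outcome over fixation duration per participant
#' within each named condition group and runs the cluster permutation test
#' between the two groups (or against chance if `conditions_b` is `NULL`).
#' The four study contrasts are face-vs-noise inspection within outline
#' (`"FO"` vs `"NO"`), within preview (`"FP"` vs `"NP"`), and
#' preview-vs-outline within face (`"FP"` vs `"FO"`) and within noise
#' inspection (`"NP"` vs `"NO"`).
#'
#' @param session A `ddm_session`.
#' @param conditions_a,conditions_b Character vectors of condition codes
#'   pooled for each side; `conditions_b = NULL` tests side A against
#'   chance (0.5).
#' @param config A [smart_config()].
#' @return A `smart_result`.
#' @export
smart_contrast <- function(session, conditions_a, conditions_b = NULL,
                           config = smart_config()) {
  stopifnot(inherits(session, "ddm_session"))
  tr <- session$trials
  pids <- session$participants
  mk <- function(conds) {
    cur <- matrix(NA_real_, length(pids), length(config$grid))
    wgt <- matrix(0, length(pids), length(config$grid))
    for (i in seq_along(pids)) {
      sub <- tr[tr$participant_id == pids[i] & tr$condition %in% conds, ]
      if (nrow(sub) == 0) next
      sm <- smooth_participant(sub$fixation_duration_ms,
                               sub$choice == "face", config)
      cur[i, ] <- sm$curve
      wgt[i, ] <- sm$weight
    }
    list(curves = cur, weights = wgt)
  }
  a <- mk(conditions_a)
  if (is.null(conditions_b)) {
    cluster_permutation_test(a$curves, a$weights, config = config)
  } else {
    b <- mk(conditions_b)
    cluster_permutation_test(a$curves, a$weights, b$curves, b$weights,
                             config = config)
  }
}
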