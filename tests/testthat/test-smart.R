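test_that("participant smoothing matches hand-computed kernel arithmetic", {
  cfg <- smart_config(n_permutations = 200)
  # constant outcomes give a constant curve
  sm1 <- smooth_participant(c(200, 400, 600), c(1, 1, 1), cfg)
  expect_true(all(abs(sm1$curve - 1) < 1e-12))
  # single trial: curve 1 everywhere defined, weight peaked at the trial
  sm2 <- smooth_participant(400, 1, cfg)
  expect_true(all(sm2$curve[!is.na(sm2$curve)] == 1))
  expect_equal(cfg$grid[which.max(sm2$weight)], 400)
  # two trials: midpoint is exactly 1/2 by symmetry; off-center points equal
  # the explicit kernel ratio
  sm3 <- smooth_participant(c(300, 500), c(1, 0), cfg)
  at <- function(t_ms) which(cfg$grid == t_ms)
  expect_equal(sm3$curve[at(400)], 0.5, tolerance = 1e-12)
  k1 <- exp(-(350 - 300)^2 / (2 * 48^2))
  k2 <- exp(-(350 - 500)^2 / (2 * 48^2))
  expect_equal(sm3$curve[at(350)], k1 / (k1 + k2), tolerance = 1e-12)
  # order invariance and range
  sm4 <- smooth_participant(c(500, 300), c(0, 1), cfg)
  expect_equal(sm4$curve, sm3$curve)
  expect_true(all(sm3$curve >= 0 & sm3$curve <= 1, na.rm = TRUE))
})

test_that("a narrow kernel interpolates the per-trial outcomes", {
  cfg <- smart_config(kernel_sd = 1)
  rt <- c(200, 350, 500, 650)
  y <- c(1, 0, 1, 0)
  sm <- smooth_participant(rt, y, cfg)
  expect_equal(sm$curve[match(rt, cfg$grid)], y, tolerance = 1e-6)
})

test_that("weighted group aggregation is a convex pointwise combination", {
  cfg <- smart_config()
  g <- length(cfg$grid)
  same <- matrix(0.7, 3, g)
  wts <- matrix(runif(3 * g, 0.5, 2), 3, g)
  expect_equal(weighted_group_timecourse(same, wts), rep(0.7, g))
  cur <- rbind(rep(0, g), rep(1, g))
  wt <- rbind(rep(1, g), rep(3, g))
  expect_equal(weighted_group_timecourse(cur, wt), rep(0.75, g))
  set.seed(2)
  cur2 <- matrix(runif(5 * g), 5, g)
  wt2 <- matrix(runif(5 * g, 0, 2), 5, g)
  gc <- weighted_group_timecourse(cur2, wt2)
  expect_true(all(gc <= apply(cur2, 2, max) + 1e-12 &
                    gc >= apply(cur2, 2, min) - 1e-12))
})

# build a synthetic two-condition dataset: P participants, n trials per
# condition, face probability p_b(t) for condition B
sim_smart_data <- function(P, n, effect_window = NULL, amp = 0,
                           seed = 1, cfg = smart_config(n_permutations = 200)) {
  set.seed(seed)
  mk <- function(amp_fun) {
    curves <- matrix(NA_real_, P, length(cfg$grid))
    weights <- matrix(0, P, length(cfg$grid))
    for (p in seq_len(P)) {
      rt <- runif(n, 120, 730)
      pr <- 0.5 + amp_fun(rt)
      y <- rbinom(n, 1, pmin(pmax(pr, 0), 1))
      sm <- smooth_participant(rt, y, cfg)
      curves[p, ] <- sm$curve
      weights[p, ] <- sm$weight
    }
    list(curves = curves, weights = weights)
  }
  null_fun <- function(rt) 0
  eff_fun <- if (is.null(effect_window)) null_fun else
    function(rt) amp * (rt >= effect_window[1] & rt <= effect_window[2])
  list(a = mk(null_fun), b = mk(eff_fun), cfg = cfg)
}

test_that("identical conditions yield no significant cluster and a covering CI", {
  d <- sim_smart_data(8, 80, seed = 3)
  res <- cluster_permutation_test(d$a$curves, d$a$weights, d$a$curves,
                                  d$a$weights, d$cfg)
  expect_equal(nrow(res$clusters), 0)
  expect_true(all(res$ci_halfwidth >= 0, na.rm = TRUE))
})

test_that("an injected effect is detected where it was injected", {
  d <- sim_smart_data(10, 150, effect_window = c(400, 600), amp = 0.3,
                      seed = 4)
  res <- cluster_permutation_test(d$b$curves, d$b$weights, d$a$curves,
                                  d$a$weights, d$cfg)
  expect_gt(nrow(res$clusters), 0)
  top <- res$clusters[1, ]
  expect_true(top$significant)
  expect_lt(top$p, 0.05)
  expect_true(top$start_ms < 600 && top$end_ms > 400)
})

test_that("permutation inference is deterministic under the seed and p-values are floored", {
  d <- sim_smart_data(6, 60, effect_window = c(300, 700), amp = 0.35,
                      seed = 5)
  r1 <- cluster_permutation_test(d$b$curves, d$b$weights, d$a$curves,
                                 d$a$weights, d$cfg)
  r2 <- cluster_permutation_test(d$b$curves, d$b$weights, d$a$curves,
                                 d$a$weights, d$cfg)
  expect_identical(r1$perm_max, r2$perm_max)
  expect_identical(r1$clusters, r2$clusters)
  expect_true(all(r1$clusters$p >= 1 / (d$cfg$n_permutations + 1)))
})

test_that("baseline mode tests a single time course against chance", {
  d <- sim_smart_data(8, 120, effect_window = c(100, 750), amp = 0.25,
                      seed = 6)
  res <- cluster_permutation_test(d$b$curves, d$b$weights, config = d$cfg)
  expect_gt(nrow(res$clusters), 0)
  expect_true(res$clusters$significant[1])
  null_res <- cluster_permutation_test(d$a$curves, d$a$weights,
                                       config = d$cfg)
  if (nrow(null_res$clusters) > 0)
    expect_true(all(null_res$clusters$strength <=
                      max(null_res$perm_max) + 1e-9))
})

test_that("under the null the cluster test keeps its nominal error rate", {
  cfg <- smart_config(n_permutations = 120)
  hits <- 0
  n_sim <- 60
  for (i in seq_len(n_sim)) {
    d <- sim_smart_data(8, 60, seed = 100 + i, cfg = cfg)
    dd <- sim_smart_data(8, 60, seed = 500 + i, cfg = cfg)
    res <- cluster_permutation_test(d$a$curves, d$a$weights, dd$a$curves,
                                    dd$a$weights, cfg)
    if (any(res$clusters$significant)) hits <- hits + 1
  }
  # binomial(60, 0.05): 3 expected; allow up to ~3 SD
  expect_lte(hits / n_sim, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("doubling the participants shrinks the difference CI by about sqrt(2)", {
  d <- sim_smart_data(8, 100, seed = 7)
  ci1 <- difference_ci(d$a$curves, d$a$weights, d$b$curves, d$b$weights,
                       d$cfg)
  ci2 <- difference_ci(rbind(d$a$curves, d$a$curves),
                       rbind(d$a$weights, d$a$weights),
                       rbind(d$b$curves, d$b$curves),
                       rbind(d$b$weights, d$b$weights), d$cfg)
  # correct for the critical-t change between df 7 and df 15 and the
  # Bessel factor (duplicated data halve the df used by the variance)
  ratio <- (ci1 * qt(0.975, 15)) / (ci2 * qt(0.975, 7))
  expect_equal(median(ratio, na.rm = TRUE), sqrt(2) * sqrt(15 / 14),
               tolerance = 0.02)
})

test_that("smart_contrast wires sessions into the permutation test", {
  ex <- small_experiment(n_participants = 3, trials_per_condition = 96)
  cfg <- smart_config(n_permutations = 120)
  res <- smart_contrast(ex$session, c("FP"), c("NP"), cfg)
  expect_s3_class(res, "smart_result")
  expect_length(res$group_a, length(cfg$grid))
  res_base <- smart_contrast(ex$session, c("FP", "FO"), NULL, cfg)
  expect_true(all(res_base$group_b == 0.5))
})
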