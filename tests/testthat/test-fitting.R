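test_that("KS statistic equals brute-force evaluation at all jump sides", {
  # two-trial hand case: face at 0.4 s, noise at 0.3 s, symmetric prediction
  trials <- data.frame(choice = c("face", "noise"),
                       fixation_duration_ms = c(400, 300))
  p <- ddm_params(a = 2, zr = 0.5, v = 0, t0 = 0.1)
  s <- sort(c(0.4, -0.3))
  G <- predicted_joint_cdf(p, s)
  brute <- max(abs(G[1] - 0), abs(G[1] - 0.5), abs(G[2] - 0.5),
               abs(G[2] - 1))
  expect_equal(ks_statistic(trials, p), brute, tolerance = 1e-12)
})

test_that("a sample at the predicted quantiles has a vanishing KS distance", {
  p <- ddm_params(a = 1.3, zr = 0.5, v = 0.5, t0 = 0.2, sv = 0.2,
                  st0 = 0.06)
  n <- 50
  qs <- (seq_len(n)) / (n + 1)
  inv <- vapply(qs, function(q)
    uniroot(function(s) predicted_joint_cdf(p, s) - q, c(-10, 10),
            tol = 1e-10)$root, 0.0)
  expect_lte(ks_statistic(inv, p), 1 / (n + 1) + 1e-6)
})

test_that("KS distance of a large simulated sample is within the DKW band", {
  p <- ddm_params(a = 1, zr = 0.5, v = 0.4, t0 = 0.2, sv = 0.3, sz = 0.1,
                  st0 = 0.08)
  set.seed(12)
  sim <- simulate_trials(1e4, p)
  trials <- data.frame(choice = ifelse(sim$upper, "face", "noise"),
                       fixation_duration_ms = sim$rt * 1000)
  expect_lt(ks_statistic(trials, p), 0.025)
})

test_that("information weights are normalized, ordered and shift-invariant", {
  w <- information_weights(rep(100, 8))
  expect_equal(w, rep(0.125, 8))
  w2 <- information_weights(c(m1 = 0, m2 = 2))
  expect_equal(unname(w2), c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  b <- c(310.2, 305.7, 320.0, 311.4)
  expect_equal(information_weights(b), information_weights(b + 57.3),
               tolerance = 1e-12)
  expect_true(all(information_weights(b) >= 0))
  expect_equal(sum(information_weights(b)), 1)
})

test_that("model selection picks the highest mean weight and breaks ties to small k", {
  labels <- names(all_variants())
  w <- matrix(0.1, 1, 8, dimnames = list(NULL, labels))
  w[, "t0+v"] <- 0.3
  expect_equal(select_model(w)$variant$label, "t0+v")
  weq <- matrix(0.125, 1, 8, dimnames = list(NULL, labels))
  expect_message(sel <- select_model(weq), "tie")
  expect_equal(sel$variant$label, "none")
  expect_true(sel$tie)
})

test_that("outlier trimming removes the documented tail counts", {
  set.seed(3)
  conds <- rep(c("FP", "FO", "NP", "NO"), each = 25)
  tr <- data.frame(
    participant_id = "p01",
    inspection_identity = ifelse(substr(conds, 1, 1) == "F", "face",
                                 "noise"),
    preview = ifelse(substr(conds, 2, 2) == "P", "preview", "outline"),
    condition = conds,
    choice = sample(c("face", "noise"), 100, replace = TRUE),
    fixation_duration_ms = runif(100, 200, 900),
    stringsAsFactors = FALSE) # 100 trials, 25 per condition
  untrimmed <- trim_outliers(tr, 0)
  attr(untrimmed, "removed") <- NULL
  expect_identical(untrimmed, tr)
  trimmed <- trim_outliers(tr, 0.1) # floor(25*0.05) = 1 per tail per cell
  expect_equal(nrow(trimmed), 100 - 8)
  removed <- attr(trimmed, "removed")
  for (cc in c("FP", "FO", "NP", "NO")) {
    full <- tr$fixation_duration_ms[tr$condition == cc]
    gone <- removed$fixation_duration_ms[removed$condition == cc]
    expect_setequal(gone, c(min(full), max(full)))
  }
  # 100 trials in one cell at fraction 0.05: floor(2.5) = 2 per tail
  one <- tr
  one$condition <- "FP"; one$inspection_identity <- "face"
  one$preview <- "preview"
  t2 <- trim_outliers(one, 0.05)
  expect_equal(nrow(t2), 96)
})

test_that("ml objective is +Inf with a fast guess and finite otherwise", {
  ex <- small_experiment(n_participants = 1, trials_per_condition = 64)
  tr <- ex$session$trials
  truth <- ex$params[, c("condition", "a", "zr", "v", "t0", "sv", "sz",
                         "st0")]
  nll <- ml_objective(tr, truth)
  expect_true(is.finite(nll))
  fast <- tr[1, ]
  fast$fixation_duration_ms <- (truth$t0[1] - truth$st0[1] / 2) * 1000 - 5
  nll2 <- ml_objective(rbind(fast, tr), truth)
  expect_true(is.infinite(nll2) && nll2 > 0)
  expect_equal(attr(nll2, "zero_trials"), 1L)
})

test_that("the KS objective prefers the generating parameters over perturbed ones", {
  cfg <- synthetic_config(n_participants = 1, trials_per_condition = 256)
  ex <- simulate_experiment(cfg, seed = 31)
  tr <- ex$session$trials
  agg <- function(params) {
    ks <- vapply(seq_len(nrow(params)), function(i) {
      pr <- params[i, ]
      ks_statistic(tr[tr$condition == pr$condition, ],
                   unlist(pr[c("a", "zr", "v", "t0", "sv", "sz", "st0")]))
    }, 0.0)
    mean(ks)
  }
  perturbed <- ex$params
  perturbed$v <- perturbed$v + 0.5
  expect_lt(agg(ex$params), agg(perturbed))
})

test_that("variant fits are deterministic and recover simulated parameters", {
  cfg <- synthetic_config(n_participants = 1, trials_per_condition = 192)
  ex <- simulate_experiment(cfg, seed = 8)
  tr <- ex$session$trials
  opts <- study_fit_options(seed = 4)
  f1 <- fit_variant(tr, variant_spec(c("v", "t0")), opts)
  f2 <- fit_variant(tr, variant_spec(c("v", "t0")), opts)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$params, f2$params)
  expect_equal(f1$bic, -2 * f1$log_likelihood + f1$k * log(f1$n_trials))
  truth <- ex$params
  expect_lt(mean(abs(f1$params$v - truth$v)), 0.45)
  expect_lt(mean(abs(f1$params$t0 - truth$t0)), 0.045)
  expect_false(f1$boundary_warning)
})

test_that("the trial floor guards underpowered fits", {
  ex <- small_experiment(n_participants = 1, trials_per_condition = 16)
  expect_error(fit_variant(ex$session$trials, variant_spec("v"),
                           fit_options(trial_floor = 40)),
               "floor")
})

test_that("richer variants attain objectives at least as good as nested ones", {
  cfg <- synthetic_config(n_participants = 1, trials_per_condition = 128)
  ex <- simulate_experiment(cfg, seed = 13)
  opts <- study_fit_options(seed = 2, maxit = 400)
  fits <- fit_all_variants(ex$session$trials, opts)
  expect_length(fits, 8)
  objs <- vapply(fits, `[[`, 0.0, "objective")
  free_sets <- lapply(all_variants(), `[[`, "free")
  for (i in seq_along(free_sets)) {
    for (j in seq_along(free_sets)) {
      if (i == j || !all(free_sets[[i]] %in% free_sets[[j]])) next
      # variant j nests variant i
      expect_lt(objs[j], objs[i] + 0.01)
    }
  }
})
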