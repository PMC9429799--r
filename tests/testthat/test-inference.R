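test_that("cell means equal hand-counted proportions on a small fixture", {
  # 16 trials: one participant, 4 per condition with known face choices
  conds <- rep(c("FP", "FO", "NP", "NO"), each = 4)
  faces <- c(3, 2, 1, 0) # face choices per condition
  choice <- unlist(lapply(seq_along(faces), function(i)
    c(rep("face", faces[i]), rep("noise", 4 - faces[i]))))
  tr <- data.frame(
    participant_id = "p01",
    inspection_identity = ifelse(substr(conds, 1, 1) == "F", "face",
                                 "noise"),
    preview = ifelse(substr(conds, 2, 2) == "P", "preview", "outline"),
    choice = choice,
    fixation_duration_ms = 300 + seq_len(16),
    stringsAsFactors = FALSE)
  tab <- cell_means(new_session(tr), "face_choice", "2x2")
  expect_equal(nrow(tab$missing), 0)
  got <- tab$cells
  key <- paste0(
    ifelse(got$inspection_identity == "face", "F", "N"),
    ifelse(got$preview == "preview", "P", "O"))
  expect_equal(got$value[match(c("FP", "FO", "NP", "NO"), key)],
               faces / 4)
  expect_true(all(got$value >= 0 & got$value <= 1))
})

test_that("empty choice cells are flagged per participant", {
  ex <- small_experiment(n_participants = 2, trials_per_condition = 48)
  tr <- ex$session$trials
  tr$choice[tr$participant_id == "p01" & tr$condition == "FP"] <- "face"
  tab <- cell_means(new_session(tr), "fixation_duration", "2x2x2")
  miss <- tab$missing
  expect_true(any(miss$participant == "p01" &
                    miss$inspection_identity == "face" &
                    miss$preview == "preview" & miss$choice == "noise"))
})

test_that("contrast-based ANOVA matches the sums-of-squares decomposition", {
  set.seed(21)
  n <- 6
  cells <- expand.grid(participant = sprintf("s%d", 1:n),
                       A = c("a1", "a2"), B = c("b1", "b2"),
                       stringsAsFactors = FALSE)
  cells$value <- rnorm(nrow(cells)) +
    2 * (cells$A == "a1") + 0.5 * (cells$A == "a1") * (cells$B == "b2")
  res <- rm_anova(cells, factors = c("A", "B"))
  expect_equal(res$effects$F, res$effects$t^2, tolerance = 1e-12)

  # independent oracle: classical repeated-measures aov
  oracle <- summary(aov(value ~ A * B + Error(participant / (A * B)),
                        data = cells))
  getF <- function(strata, term) {
    tab <- oracle[[strata]][[1]]
    tab[trimws(rownames(tab)) == term, c("F value", "Pr(>F)")]
  }
  fa <- getF("Error: participant:A", "A")
  fb <- getF("Error: participant:B", "B")
  fab <- getF("Error: participant:A:B", "A:B")
  eff <- res$effects
  expect_equal(eff$F[eff$effect == "A"], fa[[1]], tolerance = 1e-8)
  expect_equal(eff$p[eff$effect == "A"], fa[[2]], tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "B"], fb[[1]], tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "A:B"], fab[[1]], tolerance = 1e-8)
  expect_equal(eff$p[eff$effect == "A:B"], fab[[2]], tolerance = 1e-8)
})

test_that("a pure main effect produces a null interaction", {
  cells <- expand.grid(participant = sprintf("s%d", 1:5),
                       A = c("a1", "a2"), B = c("b1", "b2"),
                       stringsAsFactors = FALSE)
  base <- stats::setNames(rnorm(5), sprintf("s%d", 1:5))
  cells$value <- base[cells$participant] + 3 * (cells$A == "a1")
  res <- rm_anova(cells, factors = c("A", "B"))
  eff <- res$effects
  expect_gt(eff$F[eff$effect == "A"], 1e6)
  expect_lt(eff$F[eff$effect == "A:B"], 1e-12)
  expect_lt(eff$F[eff$effect == "B"], 1e-12)
})

test_that("the 2x2x2 ANOVA yields seven effects and handles missing cells explicitly", {
  ex <- small_experiment(n_participants = 4, trials_per_condition = 64)
  tab <- cell_means(ex$session, "fixation_duration", "2x2x2")
  if (nrow(tab$missing) == 0) {
    res <- rm_anova(tab)
    expect_equal(nrow(res$effects), 7)
  }
  # force a missing cell
  tr <- ex$session$trials
  tr$choice[tr$participant_id == "p01" & tr$condition == "FP"] <- "face"
  tab2 <- cell_means(new_session(tr), "fixation_duration", "2x2x2")
  expect_error(rm_anova(tab2), "p01")
  res2 <- rm_anova(tab2, na.action = "exclude")
  expect_true("p01" %in% res2$excluded)
  expect_equal(res2$n, 3)
})

test_that("one-sample t is null for antisymmetric samples", {
  x <- 0.5 + c(-0.2, -0.1, 0.1, 0.2)
  res <- one_sample_t(x, 0.5)
  expect_equal(res$t, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  # hand-computed paired t
  y <- c(1, 2, 4)
  m <- mean(y); se <- sd(y) / sqrt(3)
  res2 <- one_sample_t(y, 0)
  expect_equal(res2$t, m / se, tolerance = 1e-12)
  expect_equal(res2$p, 2 * pt(-abs(m / se), 2), tolerance = 1e-12)
})

test_that("Wilcoxon exact p equals full sign enumeration at n = 6", {
  enumerate_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- signs %*% r
    p_le <- mean(Ws <= W)
    p_ge <- mean(Ws >= W)
    min(1, 2 * min(p_le, p_ge))
  }
  fixtures <- list(c(0.61, 0.55, 0.48, 0.7, 0.52, 0.66) - 0.5,
                   c(0.2, -0.1, 0.05, 0.3, -0.25, 0.15),
                   c(0.1, 0.1, -0.1, 0.2, 0.3, -0.2)) # with ties
  for (d in fixtures) {
    got <- wilcoxon_signed_rank(d, 0)
    expect_equal(got$method, "exact")
    expect_equal(got$p, enumerate_p(d), tolerance = 1e-12)
  }
  # zero differences dropped; all-zero sample degenerates to p = 1
  expect_equal(wilcoxon_signed_rank(rep(0.5, 4), 0.5)$p, 1)
  mixed <- wilcoxon_signed_rank(c(0.5, 0.5, 0.6, 0.4, 0.7), 0.5)
  expect_equal(mixed$n, 3L)
})

test_that("parameter effects reproduce input column means and run the 2x2 battery", {
  ex <- small_experiment(n_participants = 5, trials_per_condition = 48)
  fp <- ex$params[, c("participant_id", "condition", "a", "zr", "v", "t0",
                      "sv", "sz", "st0")]
  pe <- parameter_effects(fp)
  expect_setequal(names(pe), c("v", "t0"))
  for (cc in c("FP", "FO", "NP", "NO")) {
    expect_equal(pe$v$means$mean[pe$v$means$condition == cc],
                 mean(fp$v[fp$condition == cc]))
  }
  expect_equal(nrow(pe$v$anova$effects), 3)
  expect_named(pe$v$t_vs_zero, c("FP", "FO", "NP", "NO"))
})
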