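# Group-level statistics: participant x cell summary tables, all-two-level
# repeated-measures ANOVAs via within-participant contrasts, paired and
# one-sample t tests, and an exact Wilcoxon signed-rank test.

#' Participant x cell summary table
#'
#' Per participant, the mean of a measure in each design cell: the 2 x 2
#' design crosses inspection identity and preview; the 2 x 2 x 2 design adds
#' the selection outcome (choice) as a third factor.  Cells a participant
#' never realized (e.g. no noise choices in a condition) are flagged.
#'
#' @param session A `ddm_session`.
#' @param measure `"fixation_duration"` (mean ms) or `"face_choice"`
#'   (proportion of face choices; only meaningful for the 2 x 2 design).
#' @param design `"2x2"` or `"2x2x2"`.
#' @return A list of class `cell_table`: `cells` (long data frame with
#'   participant, factor columns, `value`, `n`), `factors` (factor names),
#'   `missing` (data frame of flagged empty cells).
#' @export
cell_means <- function(session,
                       measure = c("fixation_duration", "face_choice"),
                       design = c("2x2", "2x2x2")) {
  stopifnot(inherits(session, "ddm_session"))
  measure <- match.arg(measure)
  design <- match.arg(design)
  if (measure == "face_choice" && design == "2x2x2")
    stop("cell_means: face_choice is only defined for the 2x2 design",
         call. = FALSE)
  tr <- session$trials
  factors <- c("inspection_identity", "preview")
  if (design == "2x2x2") factors <- c(factors, "choice")
  levs <- list(inspection_identity = c("face", "noise"),
               preview = c("preview", "outline"),
               choice = c("face", "noise"))[factors]
  full <- expand.grid(c(list(participant = session$participants), levs),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  key <- function(df) do.call(paste, c(df[c("participant", factors)],
                                       sep = "\r"))
  tr$participant <- tr$participant_id
  val <- if (measure == "fixation_duration") tr$fixation_duration_ms
         else as.numeric(tr$choice == "face")
  agg_mean <- tapply(val, key(tr), mean)
  agg_n <- tapply(val, key(tr), length)
  full$value <- as.vector(agg_mean[key(full)])
  full$n <- as.vector(agg_n[key(full)])
  full$n[is.na(full$n)] <- 0L
  missing <- full[is.na(full$value), c("participant", factors)]
  rownames(missing) <- NULL
  structure(list(cells = full, factors = factors, measure = measure,
                 design = design, missing = missing),
            class = "cell_table")
}

#' Repeated-measures ANOVA for all-two-level within designs
#'
#' Each main effect and interaction of a fully within-participant design
#' with two-level factors is computed from the corresponding
#' within-participant contrast: the per-participant contrast scores are
#' tested against zero with a paired t test, and `F = t^2` with
#' df = (1, n - 1).  This is algebraically the classical repeated-measures
#' decomposition for such designs.
#'
#' @param table A [cell_means()] result, or a long data frame with a
#'   `participant` column, two-level factor columns and a `value` column.
#' @param factors Factor column names (taken from the `cell_table` if one is
#'   given).
#' @param na.action `"error"` (default): missing cells raise an error naming
#'   the participants to exclude; `"exclude"`: listwise-delete those
#'   participants and record them in the result.
#' @return A list of class `rm_anova`: `effects` (data frame with effect,
#'   F, df1, df2, p, t, contrast mean), `n` (participants used),
#'   `excluded` (participant ids dropped).
#' @export
rm_anova <- function(table, factors = NULL,
                     na.action = c("error", "exclude")) {
  na.action <- match.arg(na.action)
  if (inherits(table, "cell_table")) {
    cells <- table$cells
    factors <- table$factors
  } else {
    cells <- as.data.frame(table)
    if (is.null(factors))
      factors <- setdiff(names(cells), c("participant", "value", "n"))
  }
  for (f in factors) {
    if (length(unique(cells[[f]])) != 2)
      stop("rm_anova: factor ", f, " is not two-level", call. = FALSE)
  }
  bad <- unique(cells$participant[is.na(cells$value)])
  if (length(bad) > 0) {
    if (na.action == "error")
      stop("rm_anova: missing cells for participant(s) ",
           paste(bad, collapse = ", "),
           "; exclude them or use na.action = 'exclude'", call. = FALSE)
    cells <- cells[!(cells$participant %in% bad), ]
  }
  participants <- unique(cells$participant)
  n <- length(participants)
  if (n < 2) stop("rm_anova: fewer than 2 complete participants",
                  call. = FALSE)

  # signs +1 for the first level of each factor, -1 for the second
  signs <- lapply(factors, function(f) {
    lev <- unique(cells[[f]])
    ifelse(cells[[f]] == lev[1], 1, -1)
  })
  names(signs) <- factors

  subsets <- unlist(lapply(seq_along(factors), function(k)
    utils::combn(factors, k, simplify = FALSE)), recursive = FALSE)
  eff <- lapply(subsets, function(ss) {
    sgn <- Reduce(`*`, signs[ss])
    sc <- tapply(cells$value * sgn, cells$participant, mean)[participants]
    m <- mean(sc); s_sd <- sd(sc)
    if (s_sd > 0) {
      tstat <- m / (s_sd / sqrt(n))
      p <- 2 * pt(-abs(tstat), n - 1)
    } else { # degenerate zero-variance contrast
      tstat <- if (abs(m) < 1e-300) 0 else sign(m) * Inf
      p <- if (tstat == 0) 1 else 0
    }
    data.frame(effect = paste(ss, collapse = ":"),
               F = tstat^2, df1 = 1, df2 = n - 1,
               p = p, t = tstat,
               contrast_mean = m)
  })
  structure(list(effects = do.call(rbind, eff), n = n,
                 excluded = if (na.action == "exclude") bad else character(0)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (within-participant contrasts, n = %d)\n",
              x$n))
  if (length(x$excluded) > 0)
    cat("excluded (missing cells):", paste(x$excluded, collapse = ", "), "\n")
  df <- x$effects
  df$F <- round(df$F, 2); df$p <- signif(df$p, 3)
  print(df[, c("effect", "F", "df1", "df2", "p")], row.names = FALSE)
  invisible(x)
}

#' Paired / one-sample t test wrapper
#'
#' Two-sided one-sample t test of `values` against `reference` (equivalently
#' a paired t test when `values` are within-participant differences).
#'
#' @param values Numeric vector (>= 2 observations).
#' @param reference Null value (default 0).
#' @return List with `t`, `df`, `p`, `mean`, `se`.
#' @export
one_sample_t <- function(values, reference = 0) {
  stopifnot(length(values) >= 2)
  tt <- t.test(values, mu = reference)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean = mean(values), se = sd(values) / sqrt(length(values)))
}

#' Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of `values` against `reference`.  Zero
#' differences are dropped.  For n <= 25 remaining observations the p value
#' is exact, from the full distribution of the positive-rank sum (computed
#' by a generating-function recursion that accommodates ties via midranks);
#' for larger n the normal approximation with continuity and tie correction
#' is used.  If all differences are zero the degenerate result p = 1 is
#' returned.
#'
#' @param values Numeric vector.
#' @param reference Null location (default 0.5, chance level for choice
#'   proportions).
#' @return List with `W` (positive-rank sum), `n` (nonzero differences),
#'   `p`, `method`.
#' @export
wilcoxon_signed_rank <- function(values, reference = 0.5) {
  d <- values - reference
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(W = 0, n = 0L, p = 1, method = "degenerate"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    # distribution of the positive-rank sum over all 2^n sign assignments:
    # polynomial product of (1 + x^{2 r_i}) on doubled ranks (integers even
    # with midranks)
    r2 <- round(2 * r)
    tot <- sum(r2)
    poly <- numeric(tot + 1)
    poly[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), poly[seq_len(tot + 1 - ri)])
      poly <- poly + shifted
    }
    probs <- poly / 2^n
    W2 <- round(2 * W)
    p_le <- sum(probs[seq_len(W2 + 1)])
    p_ge <- sum(probs[(W2 + 1):(tot + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(W = W, n = as.integer(n), p = p, method = method)
}

#' Statistical battery over fitted diffusion parameters
#'
#' For each fitted parameter that varies across conditions in the selected
#' variant (always drift rate and non-decision time in the winning variant;
#' boundary separation when free): condition means and SEs, a 2 x 2
#' repeated-measures ANOVA (inspection identity x preview), and for drift
#' rates a per-condition one-sample t test against zero.
#'
#' @param fits_params Data frame with columns `participant_id`, `condition`
#'   and fitted parameter columns (e.g. stacked `variant_fit$params` with a
#'   participant column), as produced by the pipeline.
#' @param parameters Which parameters to analyze (default: those with any
#'   between-condition variation).
#' @return A list of class `parameter_effects`: per parameter, `means`
#'   (condition means/SEs), `anova` (an `rm_anova`), and for `v`
#'   `t_vs_zero` (per-condition one-sample t results).
#' @export
parameter_effects <- function(fits_params, parameters = NULL) {
  stopifnot(all(c("participant_id", "condition") %in% names(fits_params)))
  cand <- intersect(c("v", "t0", "a"), names(fits_params))
  if (is.null(parameters)) {
    parameters <- cand[vapply(cand, function(nm) {
      spread <- tapply(fits_params[[nm]],
                       fits_params$participant_id,
                       function(x) diff(range(x)))
      any(spread > 1e-12)
    }, TRUE)]
  }
  out <- list()
  for (nm in parameters) {
    cells <- data.frame(
      participant = fits_params$participant_id,
      inspection_identity = ifelse(substr(fits_params$condition, 1, 1) == "F",
                                   "face", "noise"),
      preview = ifelse(substr(fits_params$condition, 2, 2) == "P",
                       "preview", "outline"),
      value = fits_params[[nm]],
      stringsAsFactors = FALSE)
    means <- do.call(rbind, lapply(CONDITIONS, function(cc) {
      x <- fits_params[[nm]][fits_params$condition == cc]
      data.frame(condition = cc, mean = mean(x),
                 se = sd(x) / sqrt(length(x)))
    }))
    res <- list(means = means,
                anova = rm_anova(cells,
                                 factors = c("inspection_identity",
                                             "preview")))
    if (nm == "v") {
      res$t_vs_zero <- lapply(stats::setNames(CONDITIONS, CONDITIONS),
                              function(cc)
        one_sample_t(fits_params$v[fits_params$condition == cc], 0))
    }
    out[[nm]] <- res
  }
  structure(out, class = "parameter_effects")
}

#' @export
print.parameter_effects <- function(x, ...) {
  for (nm in names(x)) {
    cat("--", nm, "--\n")
    print(x[[nm]]$means, row.names = FALSE, digits = 3)
    print(x[[nm]]$anova)
  }
  invisible(x)
}
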