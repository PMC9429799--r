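# Per-participant fitting of the eight-variant diffusion-model family.
#
# The fit criterion is the Kolmogorov-Smirnov distance between the empirical
# and predicted CDFs of the signed response variable (+RT for face choices,
# -RT for noise choices), aggregated over the four conditions as a
# trial-count-weighted sum.  Model comparison uses BIC information weights,
# with the BIC computed from the marginal first-passage log-likelihood
# evaluated at the KS-fitted parameters.

signed_seconds <- function(trials) {
  s <- trials$fixation_duration_ms / 1000
  ifelse(trials$choice == "face", s, -s)
}

#' Kolmogorov-Smirnov distance between data and model
#'
#' Maps each trial to the signed response variable (+RT in seconds for face
#' choices, -RT for noise choices), builds the empirical CDF and returns the
#' supremum distance to the model CDF of [predicted_joint_cdf()], evaluating
#' on both sides of every empirical jump.
#'
#' @param trials Either a data frame with columns `choice` and
#'   `fixation_duration_ms`, or a numeric vector of signed response times in
#'   seconds.
#' @param params A [ddm_params()] object.
#' @param n_sv,n_sz,n_st0 Quadrature node counts passed to
#'   [predicted_joint_cdf()].
#' @return KS distance in \[0, 1\].
#' @export
ks_statistic <- function(trials, params, n_sv = 15, n_sz = 7, n_st0 = 7) {
  s <- if (is.numeric(trials)) trials else signed_seconds(trials)
  if (length(s) < 1) stop("ks_statistic: no trials", call. = FALSE)
  s <- sort(s)
  n <- length(s)
  G <- predicted_joint_cdf(params, s, n_sv = n_sv, n_sz = n_sz,
                           n_st0 = n_st0)
  max(abs(G - seq_len(n) / n), abs(G - (seq_len(n) - 1) / n))
}

#' Options controlling the variant fits
#'
#' Defaults follow the package's standard settings: 5 jittered restarts of a
#' Nelder-Mead simplex on box-transformed parameters, full quadrature
#' (15 Gauss-Hermite nodes for drift variability, 7 Gauss-Legendre nodes
#' each for starting-point and non-decision-time variability) and KS
#' evaluation at every empirical jump.  The simulation studies in the
#' package run with the documented `fast = TRUE` preset (2 restarts, 6/3/3
#' nodes, 96 evaluation points per condition), chosen once for desk-scale
#' study sizes; see the methods vignette.
#'
#' @param n_restarts Number of optimizer starts (first start deterministic,
#'   later ones jittered under `seed`).
#' @param n_sv,n_sz,n_st0 Quadrature node counts used during optimization.
#' @param max_points Maximum number of KS evaluation points per condition
#'   (`Inf` = all empirical jump points; smaller values subsample the order
#'   statistics evenly).
#' @param maxit Nelder-Mead iteration cap per start (`NULL`: 200 x number of
#'   free parameters).
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param trial_floor Minimum trials per condition required to attempt a fit.
#' @param seed Seed controlling restart jitter (fits are deterministic given
#'   the seed).
#' @param fast If `TRUE`, switch the speed-sensitive defaults to the fast
#'   preset.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(n_restarts = if (fast) 2L else 5L,
                        n_sv = if (fast) 6L else 15L,
                        n_sz = if (fast) 3L else 7L,
                        n_st0 = if (fast) 3L else 7L,
                        max_points = if (fast) 96L else Inf,
                        maxit = NULL, reltol = 1e-6,
                        trial_floor = 40L, seed = 1L, fast = FALSE) {
  structure(list(n_restarts = n_restarts, n_sv = n_sv, n_sz = n_sz,
                 n_st0 = n_st0, max_points = max_points, maxit = maxit,
                 reltol = reltol, trial_floor = trial_floor,
                 seed = as.integer(seed)),
            class = "fit_options")
}

# --- parameter vector encoding -------------------------------------------
# Unconstrained optimization vector <-> condition-wise parameter matrix.
# log transform for a and t0, logit for zr; sz and st0 are parameterized as
# fractions of their legal range given zr and min(t0), so every vector
# decodes to a legal parameter set.

theta_template <- function(variant) {
  nm <- c(if ("a" %in% variant$free) paste0("a.", CONDITIONS) else "a",
          "zr",
          if ("v" %in% variant$free) paste0("v.", CONDITIONS) else "v",
          if ("t0" %in% variant$free) paste0("t0.", CONDITIONS) else "t0",
          "sv", "sz_f", "st0_f")
  nm
}

# Decode into a 4 x 7 matrix (rows = conditions); kept free of data.frame
# overhead because it sits on the optimizer's hot path.
decode_theta <- function(theta, variant) {
  grab <- function(par) {
    if (par %in% variant$free) unname(theta[paste0(par, ".", CONDITIONS)])
    else rep(unname(theta[par]), 4)
  }
  a <- exp(grab("a"))
  zr <- plogis(unname(theta[["zr"]]))
  v <- grab("v")
  t0 <- exp(grab("t0"))
  sv <- exp(unname(theta[["sv"]]))
  sz <- plogis(unname(theta[["sz_f"]])) * 2 * min(zr, 1 - zr) * 0.98
  st0 <- plogis(unname(theta[["st0_f"]])) * 2 * min(t0) * 0.98
  m <- cbind(a = a, zr = zr, v = v, t0 = t0, sv = sv, sz = sz, st0 = st0)
  rownames(m) <- CONDITIONS
  m
}

theta_to_params <- function(theta, variant) {
  m <- decode_theta(theta, variant)
  cbind(data.frame(condition = CONDITIONS, stringsAsFactors = FALSE),
        as.data.frame(m, row.names = FALSE))
}

encode_start <- function(variant, a, zr, v, t0, sv, sz_f, st0_f) {
  grab <- function(par, val) {
    val <- rep(val, length.out = 4)
    if (par %in% variant$free) val else mean(val)
  }
  theta <- c(log(grab("a", a)), qlogis(zr), grab("v", v),
             log(grab("t0", t0)), log(sv), qlogis(sz_f), qlogis(st0_f))
  names(theta) <- theta_template(variant)
  theta
}

# Evenly subsampled order statistics with exact empirical CDF brackets.
ks_points <- function(s_sorted, max_points) {
  n <- length(s_sorted)
  if (n <= max_points) {
    list(s = s_sorted, lo = (seq_len(n) - 1) / n, hi = seq_len(n) / n)
  } else {
    idx <- unique(round(seq(1, n, length.out = max_points)))
    list(s = s_sorted[idx], lo = (idx - 1) / n, hi = idx / n)
  }
}

condition_ks <- function(pts, p, opts) {
  nd <- variability_nodes(p, opts$n_sv, opts$n_sz, opts$n_st0)
  G <- joint_cdf_grid_cpp(pts$s, p[["a"]], nd$vn, nd$vw, nd$wn, nd$ww,
                          nd$tn, nd$tw)
  max(abs(G - pts$lo), abs(G - pts$hi))
}

#' Fit one model variant to one participant
#'
#' Minimizes the trial-count-weighted sum of per-condition KS distances over
#' the variant's free parameters, from multiple start points (one
#' deterministic data-driven start plus seeded jittered restarts), using a
#' Nelder-Mead simplex on box-transformed parameters.  Also computes, at the
#' fitted parameters, the marginal log-likelihood of all trials and the BIC
#' `-2 logLik + k log(n)`.
#'
#' @param trials Data frame of one participant's trials (columns `condition`,
#'   `choice`, `fixation_duration_ms`), or a `ddm_session` with a single
#'   participant.
#' @param variant A [variant_spec()].
#' @param options A [fit_options()].
#' @param start Optional named start vector on the internal transformed
#'   scale (used by [fit_all_variants()] for warm starts).
#' @return A list of class `variant_fit`: `variant`, `params` (4-row data
#'   frame), `ks_by_condition`, `objective`, `log_likelihood`,
#'   `n_zero_density`, `bic`, `k`, `n_trials`, `restarts` (per-restart
#'   objectives and convergence codes), `converged`, `boundary_warning`.
#' @export
fit_variant <- function(trials, variant, options = fit_options(),
                        start = NULL) {
  if (inherits(trials, "ddm_session")) trials <- trials$trials
  stopifnot(inherits(variant, "variant_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))

  split_s <- lapply(CONDITIONS, function(cc)
    sort(signed_seconds(trials[trials$condition == cc, ])))
  names(split_s) <- CONDITIONS
  n_c <- vapply(split_s, length, 0L)
  if (any(n_c < options$trial_floor))
    stop(sprintf("fit_variant: condition %s has %d trials (< floor %d)",
                 CONDITIONS[which.min(n_c)], min(n_c), options$trial_floor),
         call. = FALSE)
  N <- sum(n_c)
  pts <- lapply(split_s, ks_points, max_points = options$max_points)

  wts <- n_c / N
  objective <- function(theta) {
    par <- decode_theta(theta, variant)
    if (any(!is.finite(par))) return(10)
    obj <- 0
    for (i in 1:4) obj <- obj + wts[i] * condition_ks(pts[[i]], par[i, ],
                                                      options)
    obj
  }

  # data-driven deterministic start
  p_face <- vapply(CONDITIONS, function(cc) {
    s <- split_s[[cc]]; mean(s > 0)
  }, 0.0)
  p_face <- pmin(pmax(p_face, 0.05), 0.95)
  min_rt <- vapply(split_s, function(s) min(abs(s)), 0.0)
  start0 <- encode_start(variant, a = 1.0, zr = 0.5, v = qlogis(p_face),
                         t0 = pmax(0.85 * min_rt, 0.05), sv = 0.2,
                         sz_f = 0.15, st0_f = 0.3)
  if (!is.null(start)) start0 <- start[theta_template(variant)]

  npar <- length(start0)
  maxit <- if (is.null(options$maxit)) 200L * npar else options$maxit
  set.seed(options$seed)
  # chained restarts: each restart re-initializes the simplex at the best
  # point found so far (the first from the data-driven/warm start, later
  # ones with a small seeded jitter), which recovers Nelder-Mead from
  # premature simplex collapse in the higher-dimensional variants
  fits <- vector("list", options$n_restarts)
  best <- NULL
  for (r in seq_len(options$n_restarts)) {
    th0 <- if (r == 1) start0
           else best$par + rnorm(npar, 0, if (r == 2) 0 else 0.15)
    fits[[r]] <- optim(th0, objective, method = "Nelder-Mead",
                       control = list(maxit = maxit,
                                      reltol = options$reltol))
    if (is.null(best) || fits[[r]]$value < best$value) best <- fits[[r]]
  }
  objs <- vapply(fits, `[[`, 0.0, "value")
  parm <- decode_theta(best$par, variant)
  par <- theta_to_params(best$par, variant)

  ks <- vapply(seq_along(CONDITIONS), function(i) {
    full <- list(s = split_s[[i]],
                 lo = (seq_len(n_c[i]) - 1) / n_c[i],
                 hi = seq_len(n_c[i]) / n_c[i])
    condition_ks(full, parm[i, ], options)
  }, 0.0)
  names(ks) <- CONDITIONS

  # Marginal log-likelihood at the KS-fitted parameters, used for the BIC.
  # KS-fitted parameters are not maximum-likelihood estimates: the fitted
  # non-decision time can sit above the fastest observed trials, where the
  # pure first-passage density vanishes and the log-likelihood degenerates.
  # A fixed 2% uniform contaminant over the observed signed-RT range (the
  # standard RT contaminant model) caps those per-trial penalties and keeps
  # the BIC comparison stable; the quadrature is at least 8/3/3 nodes here
  # even when the optimizer ran with fewer.
  ll <- 0; n_zero <- 0L
  s_max <- max(abs(unlist(split_s)))
  eps_mix <- 0.02
  u_dens <- 1 / (2 * s_max)
  for (i in seq_along(CONDITIONS)) {
    p <- parm[i, ]
    g <- predicted_joint_density(p, split_s[[i]],
                                 n_sv = max(options$n_sv, 8),
                                 n_sz = max(options$n_sz, 3),
                                 n_st0 = max(options$n_st0, 3))
    n_zero <- n_zero + sum(g <= 0)
    ll <- ll + sum(log((1 - eps_mix) * pmax(g, 0) + eps_mix * u_dens))
  }
  k <- variant$k
  bic <- -2 * ll + k * log(N)

  boundary <- any(abs(best$par) > 15)
  structure(list(variant = variant,
                 params = par,
                 ks_by_condition = ks,
                 objective = best$value,
                 log_likelihood = ll,
                 n_zero_density = n_zero,
                 bic = bic,
                 k = k,
                 n_trials = N,
                 theta = best$par,
                 restarts = data.frame(restart = seq_along(objs),
                                       objective = objs,
                                       convergence = vapply(fits, `[[`, 0L,
                                                            "convergence")),
                 converged = any(vapply(fits, `[[`, 0L, "convergence") == 0),
                 boundary_warning = boundary),
            class = "variant_fit")
}

#' @export
print.variant_fit <- function(x, ...) {
  cat(sprintf("variant %s: objective %.4f, logLik %.1f, BIC %.1f (k=%d, n=%d)\n",
              x$variant$label, x$objective, x$log_likelihood, x$bic, x$k,
              x$n_trials))
  print(x$params, digits = 3)
  invisible(x)
}

#' Fit all eight model variants to one participant
#'
#' Fits the fully shared variant first and warm-starts every richer variant
#' from the best-fitting variant nested inside it (singles from the shared
#' fit, pairs from their best single, the full variant from the best pair),
#' each with additional jittered restarts.  The nesting cascade keeps the
#' monotonicity of best objectives across nested variants at modest restart
#' counts.
#'
#' @inheritParams fit_variant
#' @return A named list of eight `variant_fit` objects, in increasing-`k`
#'   order.
#' @export
fit_all_variants <- function(trials, options = fit_options()) {
  variants <- all_variants()
  fits <- vector("list", length(variants))
  names(fits) <- names(variants)
  fits[["none"]] <- fit_variant(trials, variants[["none"]], options)
  for (nm in setdiff(names(variants), "none")) {
    vs <- variants[[nm]]
    parents <- Filter(function(f)
      !is.null(f) && all(f$variant$free %in% vs$free) &&
        length(f$variant$free) == length(vs$free) - 1L,
      fits)
    parent <- parents[[which.min(vapply(parents, `[[`, 0.0, "objective"))]]
    warm <- expand_theta(parent$theta, parent$variant, vs)
    fits[[nm]] <- fit_variant(trials, vs, options, start = warm)
  }
  fits
}

# Re-encode a fitted solution into a richer variant's layout, replicating
# newly freed parameters across conditions.
expand_theta <- function(theta, from_variant, to_variant) {
  out <- numeric(0)
  for (par in c("a", "v", "t0")) {
    if (par %in% to_variant$free) {
      if (par %in% from_variant$free) {
        vals <- theta[paste0(par, ".", CONDITIONS)]
      } else {
        vals <- rep(unname(theta[par]), 4)
        names(vals) <- paste0(par, ".", CONDITIONS)
      }
    } else {
      vals <- theta[par]
    }
    out <- c(out, vals)
  }
  out <- c(out, theta[c("zr", "sv", "sz_f", "st0_f")])
  out[theta_template(to_variant)]
}

#' BIC information weights
#'
#' `w_i = exp(-(BIC_i - min BIC)/2) / sum_j exp(-(BIC_j - min BIC)/2)`.
#' Weights lie in \[0, 1\], sum to 1, and are invariant to adding a constant
#' to all BICs; higher weight indicates better support for the variant.
#'
#' @param bics Numeric vector of BIC values (finite).
#' @return Weights, named like `bics`.
#' @examples
#' information_weights(c(m1 = 0, m2 = 2))
#' @export
information_weights <- function(bics) {
  if (any(!is.finite(bics))) stop("information_weights: non-finite BIC",
                                  call. = FALSE)
  d <- bics - min(bics)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Select the winning variant across participants
#'
#' Averages the per-participant information weights and returns the variant
#' with the highest mean weight; ties at machine precision break toward the
#' smaller parameter count (noted in the result).
#'
#' @param weights Matrix or data frame of participants x variants
#'   information weights; column names must be variant labels as produced by
#'   [variant_spec()].
#' @return A list: `variant` (winning [variant_spec()]), `mean_weights`
#'   (data frame with variant, k, mean weight), `tie` (logical).
#' @export
select_model <- function(weights) {
  w <- as.matrix(weights)
  if (nrow(w) < 1) stop("select_model: no participants", call. = FALSE)
  specs <- all_variants()
  if (!all(colnames(w) %in% names(specs)))
    stop("select_model: unknown variant label(s): ",
         paste(setdiff(colnames(w), names(specs)), collapse = ", "),
         call. = FALSE)
  mw <- colMeans(w)
  k <- vapply(specs[colnames(w)], `[[`, 0L, "k")
  top <- which(mw >= max(mw) - 1e-12)
  tie <- length(top) > 1
  winner <- top[which.min(k[top])]
  tab <- data.frame(variant = colnames(w), k = unname(k),
                    mean_weight = unname(mw), stringsAsFactors = FALSE)
  tab <- tab[order(-tab$mean_weight, tab$k), ]
  rownames(tab) <- NULL
  if (tie)
    message("select_model: tie at machine precision; selected smallest-k variant '",
            colnames(w)[winner], "'")
  list(variant = specs[[colnames(w)[winner]]], mean_weights = tab, tie = tie)
}

#' Symmetric response-time outlier trimming
#'
#' Removes `floor(n * fraction / 2)` trials from each tail of the fixation
#' duration distribution within every participant x condition cell; used for
#' the 5%-outlier robustness refit.
#'
#' @param session A `ddm_session` (or a trial data frame).
#' @param fraction Total fraction to remove (0 <= fraction < 0.5), split
#'   evenly between the fast and slow tail.
#' @return An object like the input with trimmed trials; the removed rows
#'   are attached as attribute `"removed"`.
#' @export
trim_outliers <- function(session, fraction = 0.05) {
  stopifnot(fraction >= 0, fraction < 0.5)
  trials <- if (inherits(session, "ddm_session")) session$trials else session
  keep <- rep(TRUE, nrow(trials))
  for (pid in unique(trials$participant_id)) {
    for (cc in unique(trials$condition)) {
      idx <- which(trials$participant_id == pid & trials$condition == cc)
      n_tail <- floor(length(idx) * fraction / 2)
      if (n_tail == 0) next
      ord <- idx[order(trials$fixation_duration_ms[idx])]
      keep[c(head(ord, n_tail), tail(ord, n_tail))] <- FALSE
    }
  }
  removed <- trials[!keep, ]
  trimmed <- trials[keep, ]
  rownames(trimmed) <- NULL
  out <- if (inherits(session, "ddm_session")) {
    s <- new_session(trimmed, metadata = c(session$metadata,
                                           list(trimmed_fraction = fraction)))
    s
  } else trimmed
  attr(out, "removed") <- removed
  out
}

#' Negative log-likelihood fit criterion
#'
#' The alternative, outlier-sensitive criterion: minus the summed log
#' marginal first-passage density of the signed response times.  Any trial
#' with zero density (e.g. faster than the minimum non-decision time)
#' makes the value `+Inf`; the offending trials are attached as attribute
#' `"zero_trials"`.
#'
#' @param trials Data frame of one participant's trials.
#' @param params 4-row condition-wise parameter data frame (as in a
#'   `variant_fit`), or a single [ddm_params()] applied to all conditions.
#' @param n_sv,n_sz,n_st0 Quadrature node counts.
#' @return Negative log-likelihood (scalar, possibly `Inf`).
#' @export
ml_objective <- function(trials, params, n_sv = 15, n_sz = 7, n_st0 = 7) {
  if (inherits(trials, "ddm_session")) trials <- trials$trials
  if (inherits(params, "ddm_params") || is.numeric(params))
    params <- cbind(data.frame(condition = CONDITIONS),
                    as.data.frame(as.list(unlist(params)[PARAM_NAMES])))
  nll <- 0; zero_rows <- integer(0)
  for (cc in intersect(CONDITIONS, unique(trials$condition))) {
    idx <- which(trials$condition == cc)
    s <- signed_seconds(trials[idx, ])
    p <- unlist(params[params$condition == cc, PARAM_NAMES])
    g <- predicted_joint_density(p, s, n_sv = n_sv, n_sz = n_sz,
                                 n_st0 = n_st0)
    zero_rows <- c(zero_rows, idx[g <= 0])
    nll <- nll - sum(log(g[g > 0]))
  }
  if (length(zero_rows) > 0) {
    out <- Inf
    attr(out, "zero_trials") <- sort(zero_rows)
    return(out)
  }
  nll
}
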