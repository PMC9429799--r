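# Analytic first-passage quantities and trial simulation for the Wiener
# diffusion model.  The heavy series evaluations live in src/ddm.cpp; this
# file provides validated, documented wrappers and the quadrature layout for
# across-trial parameter variability.

#' Probability of absorption at the upper (face) boundary
#'
#' Closed-form choice probability of the Wiener diffusion without across-trial
#' variability: `(1 - exp(-2 v z)) / (1 - exp(-2 v a))` with `z = zr * a`, and
#' `zr` in the driftless limit.
#'
#' @param params A [ddm_params()] object with `sv = sz = 0`.
#' @return Probability in (0, 1) of reaching the upper boundary.
#' @examples
#' choice_probability(ddm_params(a = 2, zr = 0.5, v = 0.5))
#' @export
choice_probability <- function(params) {
  p <- validate_ddm_params(params)
  if (p["sv"] != 0 || p["sz"] != 0)
    stop("choice_probability: closed form requires sv = sz = 0", call. = FALSE)
  prob_upper_cpp(p[["v"]], p[["a"]], p[["zr"]])
}

#' Defective first-passage-time density
#'
#' Density of the decision time at one boundary, without across-trial
#' variability; integrates to that boundary's absorption probability.  The
#' implementation switches between the small-time image expansion and the
#' large-time sine series, choosing whichever needs fewer terms at a target
#' error of 1e-7 per evaluation.
#'
#' @param t Decision times in seconds (> 0); vectorized.
#' @param boundary `"upper"` or `"lower"`.
#' @param params A [ddm_params()] object with `sv = sz = st0 = 0` (the
#'   variability fields are ignored here; use [predicted_joint_cdf()] for the
#'   marginal distribution).
#' @return Density values (per second).
#' @export
fpt_density <- function(t, boundary = c("upper", "lower"), params) {
  boundary <- match.arg(boundary)
  p <- validate_ddm_params(params)
  if (any(!is.finite(t)) || any(t <= 0))
    stop("fpt_density: t must be finite and > 0", call. = FALSE)
  vapply(t, wfpt_pdf_cpp, 0.0, v = p[["v"]], a = p[["a"]], w = p[["zr"]],
         upper = as.integer(boundary == "upper"), eps = 1e-7)
}

#' Defective first-passage-time CDF
#'
#' @inheritParams fpt_density
#' @return `P(absorbed at boundary and decision time <= t)`.
#' @export
fpt_cdf <- function(t, boundary = c("upper", "lower"), params) {
  boundary <- match.arg(boundary)
  p <- validate_ddm_params(params)
  if (any(!is.finite(t))) stop("fpt_cdf: t must be finite", call. = FALSE)
  f <- if (boundary == "upper") wfpt_cdf_upper_cpp else wfpt_cdf_lower_cpp
  vapply(t, f, 0.0, v = p[["v"]], a = p[["a"]], w = p[["zr"]])
}

.quad_cache <- new.env(parent = emptyenv())

# Gauss--Hermite nodes/weights by Golub--Welsch (weights sum to sqrt(pi)).
gauss_hermite <- function(n) {
  key <- paste0("gh", n)
  if (!is.null(.quad_cache[[key]])) return(.quad_cache[[key]])
  if (n == 1) return(.quad_cache[[key]] <- list(nodes = 0,
                                                weights = sqrt(pi)))
  b <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(1:(n - 1), 2:n)] <- b
  J[cbind(2:n, 1:(n - 1))] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  .quad_cache[[key]] <- list(nodes = e$values[idx],
                             weights = sqrt(pi) * e$vectors[1, idx]^2)
}

# Gauss--Legendre nodes/weights on [-1, 1] (weights sum to 2).
gauss_legendre <- function(n) {
  key <- paste0("gl", n)
  if (!is.null(.quad_cache[[key]])) return(.quad_cache[[key]])
  if (n == 1) return(.quad_cache[[key]] <- list(nodes = 0, weights = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, n)
  J[cbind(1:(n - 1), 2:n)] <- b
  J[cbind(2:n, 1:(n - 1))] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  .quad_cache[[key]] <- list(nodes = e$values[idx],
                             weights = 2 * e$vectors[1, idx]^2)
}

# Quadrature layout marginalizing (v, zr, t0) variability.  Returns absolute
# node values with probability weights summing to 1 per dimension; collapses
# to single nodes when a variability is zero.
variability_nodes <- function(p, n_sv = 15, n_sz = 7, n_st0 = 7) {
  if (p[["sv"]] > 0) {
    gh <- gauss_hermite(n_sv)
    vn <- p[["v"]] + sqrt(2) * p[["sv"]] * gh$nodes
    vw <- gh$weights / sqrt(pi)
  } else { vn <- p[["v"]]; vw <- 1 }
  if (p[["sz"]] > 0) {
    gl <- gauss_legendre(n_sz)
    wn <- p[["zr"]] + p[["sz"]] / 2 * gl$nodes
    ww <- gl$weights / 2
  } else { wn <- p[["zr"]]; ww <- 1 }
  if (p[["st0"]] > 0) {
    gl <- gauss_legendre(n_st0)
    tn <- p[["t0"]] + p[["st0"]] / 2 * gl$nodes
    tw <- gl$weights / 2
  } else { tn <- p[["t0"]]; tw <- 1 }
  list(vn = vn, vw = vw, wn = wn, ww = ww, tn = tn, tw = tw)
}

#' Joint CDF of the signed response variable
#'
#' CDF of the signed response time `T = +RT` for upper-boundary (face)
#' responses and `T = -RT` for lower-boundary (noise) responses, marginalized
#' over across-trial variability in drift (Gauss--Hermite quadrature),
#' starting point and non-decision time (Gauss--Legendre quadrature).  Its
#' limit just below 0 equals the variability-averaged lower-boundary response
#' probability, and it increases to 1.
#'
#' @param params A [ddm_params()] object (variabilities allowed).
#' @param t_grid Signed times in seconds (any real values); need not be
#'   sorted.
#' @param n_sv,n_sz,n_st0 Quadrature node counts for the three variability
#'   dimensions (defaults 15, 7, 7); ignored where a variability is zero.
#' @return CDF values in \[0, 1\] at `t_grid`.
#' @examples
#' p <- ddm_params(a = 1, zr = 0.5, v = 0.6, t0 = 0.2, sv = 0.3, st0 = 0.08)
#' predicted_joint_cdf(p, c(-0.5, -0.001, 0.3, 1))
#' @export
predicted_joint_cdf <- function(params, t_grid, n_sv = 15, n_sz = 7,
                                n_st0 = 7) {
  p <- validate_ddm_params(params)
  if (any(!is.finite(t_grid)))
    stop("predicted_joint_cdf: non-finite grid values", call. = FALSE)
  nd <- variability_nodes(p, n_sv, n_sz, n_st0)
  joint_cdf_grid_cpp(as.numeric(t_grid), p[["a"]], nd$vn, nd$vw, nd$wn,
                     nd$ww, nd$tn, nd$tw)
}

#' Marginal density of the signed response variable
#'
#' Companion to [predicted_joint_cdf()]: the defective density of the signed
#' response time, marginalized over across-trial variability with the same
#' quadrature layout.  Used by the likelihood-based fit criterion.
#'
#' @inheritParams predicted_joint_cdf
#' @return Density values at `t_grid`.
#' @export
predicted_joint_density <- function(params, t_grid, n_sv = 15, n_sz = 7,
                                    n_st0 = 7) {
  p <- validate_ddm_params(params)
  nd <- variability_nodes(p, n_sv, n_sz, n_st0)
  joint_pdf_grid_cpp(as.numeric(t_grid), p[["a"]], nd$vn, nd$vw, nd$wn,
                     nd$ww, nd$tn, nd$tw)
}

#' Simulate diffusion trials
#'
#' Euler--Maruyama simulation of single trials: per trial the drift is drawn
#' from `Normal(v, sv)`, the relative start from `Uniform(zr - sz/2,
#' zr + sz/2)` and the non-decision time from `Uniform(t0 - st0/2,
#' t0 + st0/2)`; the diffusion path is then stepped at `dt` seconds until
#' absorption.  Reproducibility is controlled by R's RNG (`set.seed()`).
#'
#' @param n Number of trials.
#' @param params A [ddm_params()] object.
#' @param dt Step size in seconds (default 0.5 ms; halving it changes summary
#'   statistics well within Monte-Carlo error at the default scale).
#' @return A data frame with columns `upper` (logical, absorbed at the upper
#'   boundary) and `rt` (response time in seconds, decision + non-decision).
#' @examples
#' set.seed(1)
#' head(simulate_trials(5, ddm_params(v = 1)))
#' @export
simulate_trials <- function(n, params, dt = 5e-4) {
  p <- validate_ddm_params(params)
  m <- simulate_wiener_cpp(as.integer(n), p[["a"]], p[["zr"]], p[["v"]],
                           p[["t0"]], p[["sv"]], p[["sz"]], p[["st0"]], dt)
  data.frame(upper = m[, 1] == 1, rt = m[, 2])
}
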