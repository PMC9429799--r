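#' Diffusion-model parameters for one condition
#'
#' Container for the seven parameters of the Wiener diffusion model with
#' across-trial variability, with the diffusion constant fixed at 1 and time
#' in seconds.
#'
#' @param a Boundary separation (> 0, evidence units).
#' @param zr Relative starting point in (0, 1); the absolute start is
#'   `zr * a`.
#' @param v Mean drift rate (evidence per second); positive drift approaches
#'   the upper (face) boundary.
#' @param t0 Mean non-decision time in seconds (>= 0).
#' @param sv SD of the normal across-trial drift variability (>= 0).
#' @param sz Width of the uniform starting-point variability, in relative
#'   units (>= 0); `zr - sz/2` and `zr + sz/2` must stay inside (0, 1).
#' @param st0 Width of the uniform non-decision-time variability in seconds
#'   (>= 0); `t0 - st0/2` must be >= 0.
#'
#' @return A named numeric vector of class `ddm_params`.
#' @examples
#' ddm_params(a = 1, zr = 0.5, v = 0.6, t0 = 0.2)
#' @export
ddm_params <- function(a = 1, zr = 0.5, v = 0, t0 = 0.2,
                       sv = 0, sz = 0, st0 = 0) {
  p <- c(a = a, zr = zr, v = v, t0 = t0, sv = sv, sz = sz, st0 = st0)
  validate_ddm_params(p)
  structure(p, class = "ddm_params")
}

#' @rdname ddm_params
#' @param p A named vector or list holding the seven parameters.
#' @export
validate_ddm_params <- function(p) {
  p <- unlist(p)[c("a", "zr", "v", "t0", "sv", "sz", "st0")]
  if (anyNA(p)) stop("ddm_params: missing or unnamed parameter", call. = FALSE)
  if (!all(is.finite(p))) stop("ddm_params: non-finite parameter", call. = FALSE)
  if (p["a"] <= 0) stop("ddm_params: boundary separation a must be > 0", call. = FALSE)
  if (p["sv"] < 0 || p["sz"] < 0 || p["st0"] < 0)
    stop("ddm_params: variabilities sv, sz, st0 must be >= 0", call. = FALSE)
  if (p["zr"] - p["sz"] / 2 <= 0 || p["zr"] + p["sz"] / 2 >= 1)
    stop("ddm_params: zr +/- sz/2 must lie inside (0, 1)", call. = FALSE)
  if (p["t0"] - p["st0"] / 2 < 0)
    stop("ddm_params: t0 - st0/2 must be >= 0", call. = FALSE)
  invisible(p)
}

# Canonical condition labels: inspection identity (Face/Noise) x preview
# (Preview/Outline).
CONDITIONS <- c("FP", "FO", "NP", "NO")

PARAM_NAMES <- c("a", "zr", "v", "t0", "sv", "sz", "st0")

#' Model-variant specification
#'
#' One of the eight diffusion-model variants: the subset of \{v, a, t0\} whose
#' values may differ between the four experimental conditions.  Starting point
#' and the three variability parameters are always shared across conditions.
#' The parameter count is `k = 7 + 3 * length(free)`: seven base parameters,
#' plus three extra condition-specific values for each freed parameter.
#'
#' @param free Character vector, a subset of `c("v", "a", "t0")` (possibly
#'   empty).
#' @return A list of class `variant_spec` with elements `free`, `label`, `k`.
#' @examples
#' variant_spec(c("v", "t0"))
#' @export
variant_spec <- function(free = character()) {
  free <- sort(unique(as.character(free)))
  if (!all(free %in% c("v", "a", "t0")))
    stop("variant_spec: free parameters must be among v, a, t0", call. = FALSE)
  label <- if (length(free) == 0) "none" else paste(free, collapse = "+")
  structure(list(free = free, label = label, k = 7L + 3L * length(free)),
            class = "variant_spec")
}

#' All eight model variants
#'
#' @return A named list of eight `variant_spec` objects, ordered by number of
#'   free parameters (ties alphabetical), so the fully shared variant comes
#'   first.
#' @export
all_variants <- function() {
  subsets <- list(character(), "a", "t0", "v",
                  c("a", "t0"), c("a", "v"), c("t0", "v"), c("a", "t0", "v"))
  out <- lapply(subsets, variant_spec)
  names(out) <- vapply(out, `[[`, "", "label")
  out
}

#' @export
print.variant_spec <- function(x, ...) {
  cat("DDM variant:", x$label, "(k =", x$k, "parameters)\n")
  invisible(x)
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Wiener diffusion parameters (time in s, diffusion constant 1):\n")
  print(unclass(x), ...)
  invisible(x)
}
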