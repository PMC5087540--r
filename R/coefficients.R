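# Spatially varying weights of the GVF-family fields. g/h trade smoothing
# against data fidelity as functions of the edge-map gradient magnitude;
# gs/hs split the diffusion between the normal and tangent directions as a
# function of the edge-map *intensity* itself, which is what protects weak
# edges: tangent-only diffusion switches on as soon as the edge response
# reaches tau, however faint the edge is in absolute terms.

#' Smoothing weight g of the generalized gradient vector flow field
#'
#' `g = exp(-|grad f| / K)`: close to 1 in flat regions (strong smoothing),
#' decaying towards 0 at edges so the data term takes over.
#'
#' @param grad_mag Nonnegative matrix (or vector) of edge-map gradient
#'   magnitudes.
#' @param K Positive decay constant; larger K smooths more aggressively
#'   (appropriate for noisier images).
#' @return Values in (0, 1\], same shape as `grad_mag`.
#' @export
coeff_g <- function(grad_mag, K) {
  assert_scalar(K, "K", lower = 0, strict_lower = TRUE)
  if (any(grad_mag < 0)) stop("`grad_mag` must be nonnegative", call. = FALSE)
  exp(-grad_mag / K)
}

#' Data weight h of the generalized gradient vector flow field
#'
#' Complement of [coeff_g()]: `h = 1 - g`, so `g + h = 1` everywhere.
#'
#' @inheritParams coeff_g
#' @return Values in \[0, 1), same shape as `grad_mag`.
#' @export
coeff_h <- function(grad_mag, K) 1 - coeff_g(grad_mag, K)

#' Tangent-diffusion weight hs of the convex-coefficient field
#'
#' Piecewise weight on the *intensity* of the normalized edge map `f`:
#' 0 at `f = 0`, the cubic `-f^3/(8 tau^3) + 5 f/(8 tau) + 1/2` on
#' `0 < f < tau`, and 1 for `f >= tau`. The cubic rises steeply near 0 and
#' flattens into 1 at `tau` (continuously), so even a weak edge response
#' switches diffusion to the edge-preserving tangent direction, while far
#' from edges (`f = 0` exactly) diffusion is purely normal. Note the jump
#' at `f = 0+`: the cubic's limit is 1/2, but `hs(0) = 0` by definition.
#'
#' @param f Normalized edge-map intensities in \[0, 1\].
#' @param tau Edge-intensity threshold in (0, 1\].
#' @return Values in \[0, 1\], same shape as `f`.
#' @export
#' @examples
#' coeff_hs(0.5, tau = 1)  # 0.796875
coeff_hs <- function(f, tau) {
  assert_scalar(tau, "tau", lower = 0, upper = 1, strict_lower = TRUE)
  if (any(f < 0 | f > 1))
    stop("`f` must be a normalized edge map in [0, 1]", call. = FALSE)
  out <- -f^3 / (8 * tau^3) + 5 * f / (8 * tau) + 1 / 2
  out[f >= tau] <- 1
  out[f == 0] <- 0
  out
}

#' Normal-diffusion weight gs of the convex-coefficient field
#'
#' Complement of [coeff_hs()]: `gs = 1 - hs`.
#'
#' @inheritParams coeff_hs
#' @return Values in \[0, 1\], same shape as `f`.
#' @export
coeff_gs <- function(f, tau) 1 - coeff_hs(f, tau)

#' Normal-diffusion bias of the normally biased field
#'
#' `beta = exp(-|grad f|^2 / K^2)`: full normal diffusion in flat regions,
#' suppressed near edges while the tangent component is always kept.
#'
#' @inheritParams coeff_g
#' @return Values in (0, 1\], same shape as `grad_mag`.
#' @export
nbgvf_beta <- function(grad_mag, K) {
  assert_scalar(K, "K", lower = 0, strict_lower = TRUE)
  exp(-grad_mag^2 / K^2)
}
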