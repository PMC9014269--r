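#' Exponential shade-response factor
#'
#' Multiplicative plasticity factor applied to a morphology parameter X under
#' shading intensity `s` (s = 1 - PAR shaded / PAR unshaded):
#' `X = X_unshaded * exp(sign * mu * s)`. With the default positive sign
#' convention, `mu > 0` means the trait increases under shading (e.g. shade
#' avoidance by height growth).
#'
#' @param mu signed dimensionless shade-response coefficient.
#' @param s shading intensity in `[0, 1)`.
#' @param sign `+1` (default) or `-1`; see option `cropideo.shade_sign`.
#' @return multiplicative factor, 1 when `s = 0` or `mu = 0`.
#' @export
shade_factor <- function(mu, s, sign = getOption("cropideo.shade_sign", 1)) {
  stopifnot(all(s >= 0), all(s < 1), sign %in% c(-1, 1))
  exp(sign * mu * s)
}

#' Cumulative leaf-area profile along relative plant height
#'
#' Fraction of total plant leaf area below relative height `h`, modelled as
#' `F(h) = 1 / (1 + ((RLH (1-h)) / ((1-RLH) h))^b_RLH)`. `RLH` is the
#' relative height below which half the leaf area lies (`F(RLH) = 0.5` by
#' construction); larger `b_RLH` concentrates area near `RLH`, and
#' `RLH = 0.5, b_RLH = 1` gives the uniform profile `F(h) = h`. On the
#' logit scale the model is linear: `logit F = b_RLH (logit h - logit RLH)`.
#'
#' @param h relative height(s) in `[0, 1]`.
#' @param RLH median relative leaf height in (0, 1).
#' @param b_RLH shape parameter `>= 1` (larger = more concentrated).
#' @return cumulative fraction(s) in `[0, 1]`.
#' @export
leaf_profile_cdf <- function(h, RLH, b_RLH) {
  stopifnot(RLH > 0, RLH < 1, b_RLH > 0)
  out <- numeric(length(h))
  inside <- h > 0 & h < 1
  hi <- h[inside]
  out[inside] <- 1 / (1 + ((RLH * (1 - hi)) / ((1 - RLH) * hi))^b_RLH)
  out[h >= 1] <- 1
  out[h <= 0] <- 0
  out
}

#' Inverse of the cumulative leaf-area profile
#'
#' @param p cumulative fraction(s) in (0, 1).
#' @inheritParams leaf_profile_cdf
#' @return relative height(s) in (0, 1).
#' @export
leaf_profile_quantile <- function(p, RLH, b_RLH) {
  stopifnot(all(p > 0), all(p < 1))
  # invert logit F = b (logit h - logit RLH)
  u <- log(p / (1 - p)) / b_RLH + log(RLH / (1 - RLH))
  1 / (1 + exp(-u))
}
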