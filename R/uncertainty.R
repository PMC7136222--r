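# Closed-form uncertainty algebra. Every standard error produced by this
# package flows through these functions: summation in quadrature of
# partial-derivative-scaled contributions, the Bernoulli standard deviation
# of a classification probability, and probability-weighted mixing of two
# class-specific estimates. Independence of the inputs is assumed
# throughout; no covariance terms are carried.

#' Summation in quadrature
#'
#' Combines independent uncertainty contributions as
#' `sqrt(sum(terms^2))`. Each term is expected to already be the
#' partial-derivative-scaled contribution `|df/dx| * sigma_x` of one input.
#'
#' @param terms Numeric vector of non-negative contributions.
#' @return The combined standard error (scalar).
#' @examples
#' quadrature(c(3, 4))  # 5
#' @export
quadrature <- function(terms) {
  if (any(terms < 0, na.rm = TRUE))
    stop("quadrature terms must be >= 0")
  sqrt(sum(terms^2))
}

#' Product of two uncertain values
#'
#' Mean is the product of the means; the standard error uses the absolute
#' (expanded) form of the product rule,
#' `sqrt((mb * sa)^2 + (ma * sb)^2)`, which is algebraically identical to the
#' relative form for nonzero means but remains defined when a mean is zero.
#'
#' @param a,b [uval()] objects (vectorized).
#' @return A [uval()].
#' @examples
#' se_of_product(uval(100, 10), uval(0.47, 0))
#' @export
se_of_product <- function(a, b) {
  stopifnot(inherits(a, "uval"), inherits(b, "uval"))
  uval(a$mean * b$mean,
       sqrt((b$mean * a$se)^2 + (a$mean * b$se)^2))
}

#' Bernoulli standard deviation of a classification probability
#'
#' `sqrt(p * (1 - p))` — the standard deviation of a Bernoulli trial with
#' success probability `p`, used as the uncertainty of a binary thematic
#' classification with user's accuracy `p`.
#'
#' @param p Probability (vectorized), in `[0, 1]`.
#' @return Numeric vector of standard deviations.
#' @export
bernoulli_sd <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p must be in [0, 1]")
  sqrt(p * (1 - p))
}

#' Probability-weighted carbon fraction
#'
#' Weights the carbon concentration of the most probable phylogeny by the
#' probability of its correct classification (the class user's accuracy),
#' with the complement allocated to the average of the other two phylogenies:
#' `mu_c = mu_m * p_m + (mu_n + mu_o) / 2 * (1 - p_m)`.
#'
#' @param mu_m Mean carbon fraction of the most probable phylogeny.
#' @param p_m User's accuracy of that phylogeny's classification, in
#'   `[0, 1]`.
#' @param mu_n,mu_o Mean carbon fractions of the two remaining phylogenies.
#' @return The probability-weighted mean carbon fraction.
#' @export
weighted_c_fraction <- function(mu_m, p_m, mu_n, mu_o) {
  if (any(p_m < 0 | p_m > 1, na.rm = TRUE))
    stop("p_m must be in [0, 1]")
  mu_m * p_m + (mu_n + mu_o) / 2 * (1 - p_m)
}

#' Standard error of the probability-weighted carbon fraction
#'
#' Companion quadrature weighting for [weighted_c_fraction()], applied
#' exactly in its published form:
#' `sigma_c = sqrt(2 * sigma_m^2 + ((1 - p_m) / 2 * sigma_n)^2 +
#'  ((1 - p_m) / 2 * sigma_o)^2 + (p_m * sigma_m)^2)`.
#'
#' Note the leading `2 * sigma_m^2` term in addition to the
#' `(p_m * sigma_m)^2` term: the published weighting counts the most probable
#' phylogeny's error twice relative to a textbook linear propagation of the
#' mean formula. It is reproduced literally here, not "repaired", so that
#' derived fractions match the published probability-weighted tables.
#'
#' @param sigma_m SE of the most probable phylogeny's carbon fraction.
#' @param p_m User's accuracy of that classification.
#' @param sigma_n,sigma_o SEs of the remaining phylogenies' fractions.
#' @return The probability-weighted standard error.
#' @export
weighted_c_fraction_se <- function(sigma_m, p_m, sigma_n, sigma_o) {
  if (any(c(sigma_m, sigma_n, sigma_o) < 0, na.rm = TRUE))
    stop("standard errors must be >= 0")
  sqrt(2 * sigma_m^2 +
         ((1 - p_m) / 2 * sigma_n)^2 +
         ((1 - p_m) / 2 * sigma_o)^2 +
         (p_m * sigma_m)^2)
}

#' Probability-weighted mix of two class-specific estimates
#'
#' Mean: `mu = mu_i * p_i + mu_j * (1 - p_i)`, the allocation between the
#' most probable class `i` (with classification probability `p_i`) and the
#' alternative class `j`. The standard error propagates the class estimates'
#' errors together with the Bernoulli uncertainty `delta_i` of the
#' classification itself, evaluated in the expanded absolute form
#' `sqrt((p_i*s_i)^2 + (mu_i*d_i)^2 + ((1-p_i)*s_j)^2 +
#'  (mu_j*(1-p_i)*d_i/p_i)^2)`
#' which is algebraically identical to the published relative form for
#' nonzero means and probabilities but remains defined when a mean is zero.
#' At `p_i = 0` the `d_i/p_i` term is taken as 0 by continuity.
#'
#' @param mu_i [uval()] of the most probable class (vectorized).
#' @param mu_j [uval()] of the less probable class.
#' @param p_i Probability of correct classification of class `i`.
#' @return A [uval()].
#' @export
mix_two_classes <- function(mu_i, mu_j, p_i) {
  stopifnot(inherits(mu_i, "uval"), inherits(mu_j, "uval"))
  if (any(p_i < 0 | p_i > 1, na.rm = TRUE))
    stop("p_i must be in [0, 1]")
  d <- bernoulli_sd(p_i)
  d_over_p <- ifelse(p_i > 0, d / p_i, 0)
  m <- mu_i$mean * p_i + mu_j$mean * (1 - p_i)
  s <- sqrt((p_i * mu_i$se)^2 +
              (mu_i$mean * d)^2 +
              ((1 - p_i) * mu_j$se)^2 +
              (mu_j$mean * (1 - p_i) * d_over_p)^2)
  uval(m, s)
}
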