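# Independent oracles: every formula here is written out longhand, straight
# from its definition, and never calls the package's own implementation.

# Eq. oracle: product-rule SE, absolute form
oracle_product_se <- function(ma, sa, mb, sb) {
  sqrt((mb * sa)^2 + (ma * sb)^2)
}

# Monte-Carlo oracle for the product of two independent Gaussians
oracle_product_se_mc <- function(ma, sa, mb, sb, n = 1e5, seed = 99) {
  set.seed(seed)
  stats::sd(stats::rnorm(n, ma, sa) * stats::rnorm(n, mb, sb))
}

# probability-weighted carbon fraction and its printed quadrature weighting
oracle_weighted_cf <- function(mu_m, p_m, mu_n, mu_o) {
  mu_m * p_m + ((mu_n + mu_o) / 2) * (1 - p_m)
}
oracle_weighted_cf_se <- function(s_m, p_m, s_n, s_o) {
  sqrt(2 * s_m^2 + ((1 - p_m) / 2 * s_n)^2 + ((1 - p_m) / 2 * s_o)^2 +
         (p_m * s_m)^2)
}

# two-class mix: mean and the relative-form SE evaluated literally
# (guarded against zero means/probabilities by construction of the inputs)
oracle_mix_mean <- function(mi, mj, p) mi * p + mj * (1 - p)
oracle_mix_se <- function(mi, si, mj, sj, p) {
  d <- sqrt(p * (1 - p))
  t1 <- mi * p * sqrt((si / mi)^2 + (d / p)^2)
  t2 <- mj * (1 - p) * sqrt((sj / mj)^2 + (d / p)^2)
  sqrt(t1^2 + t2^2)
}

# total allocation: mean and the printed relative-form SE
oracle_alloc_mean <- function(mw, mh, q) mw + mh * (1 - q)
oracle_alloc_se <- function(sw, mh, sh, q, sq) {
  inner <- mh * q * sqrt((sh / mh)^2 + (sq / q)^2)
  sqrt(sw^2 + inner^2)
}

# regional-map SE polynomial
oracle_bouvet <- function(agb) {
  1.0551 * agb - 0.007 * agb^2 - 0.0000273 * agb^3
}

# crop conversions
oracle_crop_agbc <- function(y, omega, h, c) {
  y * omega * (0.451 * h^-1 + 1.025 * c - 0.451)
}
oracle_crop_bgbc <- function(y, r, h) 0.451 * y * r * h^-1

# Theil-Sen by brute force: enumerate every pair explicitly
oracle_theil_sen <- function(years, values) {
  slopes <- c()
  n <- length(years)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (years[j] != years[i])
        slopes <- c(slopes, (values[j] - values[i]) / (years[j] - years[i]))
    }
  }
  sort(slopes)
  ns <- length(slopes)
  srt <- sort(slopes)
  if (ns %% 2 == 1) srt[(ns + 1) / 2]
  else (srt[ns / 2] + srt[ns / 2 + 1]) / 2
}

# bootstrap SE of the Theil-Sen slope, independent implementation
oracle_bootstrap_se <- function(years, values, n_reps, drop_fraction, seed) {
  set.seed(seed)
  out <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    repeat {
      keep <- stats::runif(length(years)) >= drop_fraction
      if (sum(keep) >= 3) break
    }
    out[r] <- oracle_theil_sen(years[keep], values[keep])
  }
  stats::sd(out)
}

# integer-percent rounding used for comparisons with printed percentages
pct <- function(x) floor(x * 100 + 0.5)
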