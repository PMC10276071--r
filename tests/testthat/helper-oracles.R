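# Independent oracles used to freeze expected values. These deliberately use
# different algorithms from the package code paths they check.

# Benjamini-Hochberg step-up by its textbook definition:
# q_(i) = min_{j >= i} p_(j) * m / j, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(pmin(p[ord][i:m] * m / (i:m), 1))
  }, numeric(1))
  q_sorted[match(seq_len(m), ord)]
}

# weighted 0.5-quantile via the piecewise-linear CDF and stats::approx
weighted_median_oracle <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  stats::approx(s, theta, xout = 0.5)$y
}

# weighted normal-kernel density argmax evaluated point by point
kde_mode_oracle <- function(theta, w, phi = 1) {
  w <- w / sum(w)
  h <- phi * 0.9 * min(sd(theta), mad(theta)) * length(theta)^(-1 / 5)
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = 512)
  dens <- sapply(grid, function(g) sum(w / h * dnorm((g - theta) / h)))
  grid[which.max(dens)]
}

# colocalization posteriors by exhaustive enumeration of the
# 1 + M + M + M(M-1) + M causal configurations
coloc_enum_oracle <- function(labf_x, labf_y, p1, p2, p12) {
  M <- length(labf_x)
  abf_x <- exp(labf_x)
  abf_y <- exp(labf_y)
  s <- c(H0 = 1, H1 = 0, H2 = 0, H3 = 0, H4 = 0)
  for (j in seq_len(M)) {
    s["H1"] <- s["H1"] + p1 * abf_x[j]
    s["H2"] <- s["H2"] + p2 * abf_y[j]
    s["H4"] <- s["H4"] + p12 * abf_x[j] * abf_y[j]
    for (k in seq_len(M)) if (k != j)
      s["H3"] <- s["H3"] + p1 * p2 * abf_x[j] * abf_y[k]
  }
  s / sum(s)
}

# fixed-effect inverse-variance meta-analysis of the per-instrument ratios,
# assembled from Wald ratios rather than the closed-form weighted mean
ivw_meta_oracle <- function(hs) {
  theta_j <- hs$beta_y / hs$beta_x
  se_j <- hs$se_y / abs(hs$beta_x)
  w <- 1 / se_j^2
  list(theta = sum(w * theta_j) / sum(w), se = sqrt(1 / sum(w)))
}

# PPARG region rows of the built-in target table
pparg_target <- function() drug_target(load_drug_targets(),
                                       "thiazolidinediones")

# small deterministic harmonized-instrument fixture
toy_hs <- function(k = 5, seed = 42) {
  set.seed(seed)
  data.frame(rsid = paste0("rs", seq_len(k)),
             beta_x = runif(k, 0.05, 0.2) * sample(c(-1, 1), k, TRUE),
             se_x = runif(k, 0.005, 0.02),
             beta_y = rnorm(k, 0.02, 0.02),
             se_y = runif(k, 0.005, 0.02))
}

# run selection + harmonization on a simulated PPARG-region scenario
scenario_mr_data <- function(name, seed, overrides = list(), ...) {
  sim <- simulate_two_sample(preset(name, seed = seed,
                                    overrides = overrides))
  sel <- select_instruments(sim$exposure, sim$outcome, pparg_target(),
                            sim$ld, ...)
  align_datasets(sel, sim$outcome, sim$ld)
}

# vectorized palindromic-pair predicate (A/T or C/G)
is_pal_vec <- function(ea, oa) {
  a <- pmin(ea, oa); b <- pmax(ea, oa)
  (a == "A" & b == "T") | (a == "C" & b == "G")
}
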