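#' Wald ratio estimate for one instrument
#'
#' theta = beta_y / beta_x with first-order delta-method standard error
#' se = se_y / |beta_x| (the two-sample MR convention, which ignores the
#' exposure-side sampling error; the second-order correction adding
#' beta_y^2 se_x^2 / beta_x^4 is available via `second_order = TRUE`).
#'
#' @param h one-row harmonized instrument (needs `beta_x, beta_y, se_y`, and
#'   `se_x` for the second-order form).
#' @param second_order include the exposure-error term in the se.
#' @return list(rsid, theta, se, weight) with weight = se^-2.
#' @export
wald_ratio <- function(h, second_order = FALSE) {
  if (h$beta_x == 0) stop("undefined ratio: beta_x = 0 for ", h$rsid)
  theta <- h$beta_y / h$beta_x
  v <- h$se_y^2 / h$beta_x^2
  if (second_order) v <- v + h$beta_y^2 * h$se_x^2 / h$beta_x^4
  se <- sqrt(v)
  list(rsid = h$rsid, theta = theta, se = se, weight = 1 / v)
}

#' Fixed-effect inverse-variance-weighted estimate
#'
#' Combines per-instrument Wald ratios in a fixed-effect meta-analysis:
#' theta_hat = sum(w_j theta_j) / sum(w_j) with w_j = beta_x_j^2 / se_y_j^2,
#' se = sum(w_j)^(-1/2). With a single instrument this reduces exactly to the
#' Wald ratio.
#'
#' @param hs harmonized instruments (`mr_data` or data.frame with
#'   `beta_x, beta_y, se_y`).
#' @return list(theta, se, k).
#' @export
ivw_fixed <- function(hs) {
  if (!nrow(hs)) stop("no instruments")
  w <- hs$beta_x^2 / hs$se_y^2
  theta_j <- hs$beta_y / hs$beta_x
  list(theta = sum(w * theta_j) / sum(w), se = 1 / sqrt(sum(w)),
       k = nrow(hs))
}

#' MR-Egger regression
#'
#' Weighted least squares of beta_y on beta_x with intercept, weights
#' 1/se_y^2, after orienting every instrument so that beta_x >= 0 (the
#' estimator is not invariant to allele orientation otherwise). The slope is
#' the causal estimate; the intercept estimates the average directional
#' pleiotropy. Standard errors use a multiplicative dispersion floored at 1
#' (fixed-effect ses are never deflated below the weighted-regression ones).
#' Requires at least 3 instruments.
#'
#' @inheritParams ivw_fixed
#' @return list(theta, se, intercept, intercept_se, k), or NULL when k < 3.
#' @export
mr_egger <- function(hs) {
  k <- nrow(hs)
  if (k < 3) return(NULL)
  sgn <- ifelse(hs$beta_x < 0, -1, 1)
  bx <- hs$beta_x * sgn
  by <- hs$beta_y * sgn
  w <- 1 / hs$se_y^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  V <- solve(XtWX)
  coefs <- unname(drop(V %*% crossprod(X, w * by)))
  resid <- by - drop(X %*% coefs)
  sigma2 <- sum(w * resid^2) / (k - 2)
  ses <- unname(sqrt(diag(V) * max(sigma2, 1)))
  list(theta = coefs[2], se = ses[2],
       intercept = coefs[1], intercept_se = ses[1], k = k)
}

weighted_quantile_interp <- function(theta, w, q = 0.5) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (q <= s[1]) return(theta[1])
  if (q >= s[length(s)]) return(theta[length(theta)])
  below <- max(which(s < q))
  theta[below] + (theta[below + 1] - theta[below]) *
    (q - s[below]) / (s[below + 1] - s[below])
}

#' Weighted median estimate
#'
#' Orders the per-instrument ratio estimates and takes the weighted empirical
#' median (cumulative weight s_j = cumsum(w)_j - w_j/2, linear interpolation
#' at 0.5), with inverse-variance weights beta_x^2/se_y^2. Consistent when
#' instruments contributing at least half the weight are valid. The standard
#' error comes from a parametric bootstrap resampling beta_x and beta_y from
#' their estimated sampling distributions.
#'
#' @inheritParams ivw_fixed
#' @param bootstrap_reps bootstrap replicates for the se (default 10000).
#' @param seed RNG seed for the bootstrap (mandatory for reproducibility).
#' @return list(theta, se, k), or NULL when k < 3.
#' @export
weighted_median_mr <- function(hs, bootstrap_reps = 10000, seed) {
  k <- nrow(hs)
  if (k < 3) return(NULL)
  est <- function(bx, by) {
    weighted_quantile_interp(by / bx, bx^2 / hs$se_y^2)
  }
  theta <- est(hs$beta_x, hs$beta_y)
  se <- mr_bootstrap_se(hs, est, bootstrap_reps, seed)
  list(theta = theta, se = se, k = k)
}

#' Weighted mode estimate
#'
#' Kernel-density (normal kernel) mode of the per-instrument ratio estimates
#' with normalized inverse-variance weights; bandwidth
#' h = phi * 0.9 * min(sd(theta), mad(theta)) * k^(-1/5), evaluated on a
#' 512-point grid spanning the ratio range plus/minus 3h. Consistent when the
#' largest group of instruments sharing a ratio value is valid (plurality
#' validity). Standard error by parametric bootstrap. When all ratios
#' coincide (zero bandwidth) the common value is returned.
#'
#' @inheritParams weighted_median_mr
#' @param phi bandwidth multiplier (default 1).
#' @return list(theta, se, k), or NULL when k < 3.
#' @export
weighted_mode_mr <- function(hs, phi = 1, bootstrap_reps = 10000, seed) {
  k <- nrow(hs)
  if (k < 3) return(NULL)
  est <- function(bx, by) {
    theta_j <- by / bx
    w <- bx^2 / hs$se_y^2
    kde_mode(theta_j, w / sum(w), phi)
  }
  theta <- est(hs$beta_x, hs$beta_y)
  se <- mr_bootstrap_se(hs, est, bootstrap_reps, seed)
  list(theta = theta, se = se, k = k)
}

kde_mode <- function(theta, w, phi = 1, grid_n = 512L) {
  k <- length(theta)
  spread <- c(stats::sd(theta), stats::mad(theta))
  spread <- spread[spread > 0]
  if (!length(spread)) return(theta[1])
  h <- phi * 0.9 * min(spread) * k^(-1 / 5)
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = grid_n)
  dens <- vapply(grid, function(g)
    sum(w * stats::dnorm((g - theta) / h)), numeric(1))
  grid[which.max(dens)]
}

mr_bootstrap_se <- function(hs, est, reps, seed) {
  if (missing(seed) || is.null(seed))
    stop("a bootstrap seed is required for reproducible standard errors")
  k <- nrow(hs)
  out <- withr_seed(seed, {
    vapply(seq_len(reps), function(r) {
      bx <- stats::rnorm(k, hs$beta_x, hs$se_x)
      by <- stats::rnorm(k, hs$beta_y, hs$se_y)
      bx[bx == 0] <- .Machine$double.eps
      est(bx, by)
    }, numeric(1))
  })
  stats::sd(out)
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Scale a log-odds causal estimate to an odds ratio per re-scaled exposure
#'
#' The raw estimate is the log-odds of the outcome per 1 unit higher
#' exposure; `factor = -0.1` re-expresses it as the odds ratio per 0.1 unit
#' *lower* exposure (the glucose-lowering convention). The p-value is
#' scale-invariant and computed on the unscaled estimate.
#'
#' @param theta_hat,se causal estimate and standard error (per 1 exposure
#'   unit, log-odds scale).
#' @param factor scaling factor (default -0.1).
#' @param conf_level confidence level (default 0.95).
#' @return list(or, ci_low, ci_high, log_or, log_se).
#' @export
scale_estimate <- function(theta_hat, se, factor = -0.1, conf_level = 0.95) {
  if (se <= 0) stop("se must be > 0")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- factor * theta_hat
  lse <- abs(factor) * se
  ci <- sort(exp(c(lo - z * lse, lo + z * lse)))
  list(or = exp(lo), ci_low = ci[1], ci_high = ci[2],
       log_or = lo, log_se = lse)
}

#' Normal-theory summary of a log odds ratio
#'
#' @param log_or log odds ratio.
#' @param se its standard error.
#' @param conf_level confidence level (default 0.95).
#' @return list(or, ci_low, ci_high, pval) with
#'   p = 2 Phi(-|log_or / se|).
#' @export
wald_summary <- function(log_or, se, conf_level = 0.95) {
  if (se <= 0) stop("se must be > 0")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(log_or), ci_low = exp(log_or - z * se),
       ci_high = exp(log_or + z * se),
       # floored at the smallest subnormal so p stays inside (0, 1]
       pval = max(2 * stats::pnorm(-abs(log_or / se)),
                  .Machine$double.xmin))
}

#' Bonferroni significance gate
#'
#' Strict inequality against alpha / n_tests. With the default 6 drug
#' classes the threshold is 0.05/6 = 0.00833..., reported rounded to 0.008.
#'
#' @param pval p-value in (0, 1].
#' @param alpha family-wise level (default 0.05).
#' @param n_tests number of tests (default 6).
#' @return logical: pval < alpha / n_tests.
#' @export
bonferroni_gate <- function(pval, alpha = 0.05, n_tests = 6) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  if (any(pval <= 0 | pval > 1)) stop("pval must lie in (0, 1]")
  pval < alpha / n_tests
}

#' Fit two-sample MR causal-effect estimators to harmonized instruments
#'
#' The central fitting function. Dispatches on the number of instruments k:
#' the Wald ratio for k = 1, fixed-effect IVW for k >= 2, and additionally
#' MR-Egger, the weighted median and the weighted mode for k >= 3 (the
#' pleiotropy-robust estimators are not identified below three instruments).
#' Every estimate is reported on the per-1-unit log-odds scale and as an
#' odds ratio scaled by `factor` (default: per 0.1 unit lower exposure),
#' with normal-theory 95% CI and p-value and a Bonferroni significance flag.
#'
#' @param hs harmonized instruments ([align_datasets] output, or any
#'   data.frame with `beta_x, se_x, beta_y, se_y`).
#' @param factor exposure re-scaling factor (default -0.1).
#' @param alpha,n_tests Bonferroni gate parameters (defaults 0.05, 6).
#' @param bootstrap_reps bootstrap replicates for median/mode ses.
#' @param seed bootstrap seed (required when k >= 3).
#' @param phi weighted-mode bandwidth multiplier.
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `mr_fit`: list with `results` (one row per
#'   method: theta, se, or, ci_low, ci_high, pval, bonferroni_significant,
#'   egger intercept columns), `data`, `drug_class`, `mean_f`, `k`, and the
#'   call parameters. `NULL` results rows for inapplicable methods are
#'   omitted. With k = 0 the object has zero result rows and
#'   `status = "no-instruments"`.
#' @examples
#' hs <- data.frame(beta_x = c(0.1, 0.2, 0.15), se_x = 0.01,
#'                  beta_y = c(0.02, 0.041, 0.03), se_y = 0.005)
#' fit <- mr_fit(hs, seed = 1, bootstrap_reps = 200)
#' coef(fit)
#' @export
mr_fit <- function(hs, factor = -0.1, alpha = 0.05, n_tests = 6,
                   bootstrap_reps = 10000, seed = NULL, phi = 1,
                   conf_level = 0.95) {
  k <- nrow(hs)
  drug_class <- attr(hs, "drug_class")
  mean_f <- attr(hs, "mean_f")
  if (is.null(mean_f) && "f_stat" %in% names(hs) && k)
    mean_f <- mean(hs$f_stat)
  cores <- list()
  if (k == 1) {
    cores$wald <- wald_ratio(hs[1, ])
  } else if (k >= 2) {
    cores$ivw <- ivw_fixed(hs)
    if (k >= 3) {
      cores$egger <- mr_egger(hs)
      cores$weighted_median <- weighted_median_mr(hs, bootstrap_reps, seed)
      cores$weighted_mode <- weighted_mode_mr(hs, phi, bootstrap_reps, seed)
    }
  }
  rows <- lapply(names(cores), function(m) {
    co <- cores[[m]]
    if (is.null(co)) return(NULL)
    sc <- scale_estimate(co$theta, co$se, factor, conf_level)
    ws <- wald_summary(sc$log_or, sc$log_se, conf_level)
    data.frame(method = m, n_instruments = k,
               mean_f = if (is.null(mean_f)) NA_real_ else mean_f,
               theta = co$theta, se = co$se,
               or = sc$or, ci_low = sc$ci_low, ci_high = sc$ci_high,
               pval = ws$pval,
               bonferroni_significant = bonferroni_gate(ws$pval, alpha,
                                                        n_tests),
               egger_intercept = if (m == "egger") co$intercept else NA_real_,
               egger_intercept_se = if (m == "egger") co$intercept_se
                                    else NA_real_,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(results))
    results <- data.frame(method = character(0), n_instruments = integer(0),
                          mean_f = numeric(0), theta = numeric(0),
                          se = numeric(0), or = numeric(0),
                          ci_low = numeric(0), ci_high = numeric(0),
                          pval = numeric(0),
                          bonferroni_significant = logical(0),
                          egger_intercept = numeric(0),
                          egger_intercept_se = numeric(0))
  rownames(results) <- NULL
  structure(list(results = results, data = hs, drug_class = drug_class,
                 mean_f = mean_f, k = k,
                 status = if (k == 0) "no-instruments" else "analyzed",
                 factor = factor, alpha = alpha, n_tests = n_tests,
                 conf_level = conf_level, call = match.call()),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat("Two-sample Mendelian randomization fit")
  if (!is.null(x$drug_class)) cat(" —", x$drug_class)
  cat("\n")
  if (x$k == 0) {
    cat("no valid instruments\n")
    return(invisible(x))
  }
  cat(sprintf("%d instrument(s), mean F = %s; OR per %g exposure units\n",
              x$k,
              if (is.null(x$mean_f) || is.na(x$mean_f)) "NA"
              else formatC(x$mean_f, digits = 3, format = "g"),
              x$factor))
  tab <- x$results[, c("method", "or", "ci_low", "ci_high", "pval",
                       "bonferroni_significant")]
  tab$or <- round(tab$or, digits)
  tab$ci_low <- round(tab$ci_low, digits)
  tab$ci_high <- round(tab$ci_high, digits)
  tab$pval <- signif(tab$pval, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  if (f$k) {
    cat(sprintf("\nBonferroni threshold: %.3f (alpha %g / %d tests)\n",
                f$alpha / f$n_tests, f$alpha, f$n_tests))
    eg <- f$results[f$results$method == "egger", ]
    if (nrow(eg))
      cat(sprintf("Egger intercept: %.4g (se %.4g) — average pleiotropy\n",
                  eg$egger_intercept, eg$egger_intercept_se))
    if (!is.null(f$mean_f) && !is.na(f$mean_f) && f$mean_f <= 10)
      cat("warning: mean F <= 10, weak-instrument bias likely\n")
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$results$theta, object$results$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  res <- object$results
  out <- t(vapply(seq_len(nrow(res)), function(i) {
    sc <- scale_estimate(res$theta[i], res$se[i], object$factor, level)
    c(sc$ci_low, sc$ci_high)
  }, numeric(2)))
  dimnames(out) <- list(res$method,
                        paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               " %"))
  out
}

#' Scatter of instrument effects with fitted causal slopes
#'
#' Plots the outcome effect against the exposure effect per instrument
#' (oriented so beta_x >= 0) with one line per fitted method (through the
#' origin except MR-Egger, whose intercept is drawn).
#'
#' @param x an `mr_fit`.
#' @param ... passed to [graphics::plot].
#' @export
plot.mr_fit <- function(x, ...) {
  hs <- x$data
  if (!nrow(hs)) {
    warning("nothing to plot: no instruments")
    return(invisible(x))
  }
  sgn <- ifelse(hs$beta_x < 0, -1, 1)
  bx <- hs$beta_x * sgn
  by <- hs$beta_y * sgn
  graphics::plot(bx, by, xlab = "exposure effect (per allele)",
                 ylab = "outcome effect (log-odds per allele)",
                 pch = 19, ...)
  graphics::segments(bx, by - 1.96 * hs$se_y, bx, by + 1.96 * hs$se_y,
                     col = "grey60")
  res <- x$results
  cols <- stats::setNames(seq_len(nrow(res)) + 1, res$method)
  for (m in res$method) {
    r <- res[res$method == m, ]
    intercept <- if (m == "egger") r$egger_intercept else 0
    graphics::abline(intercept, r$theta, col = cols[[m]], lty = 2)
  }
  graphics::legend("topleft", legend = res$method, col = cols, lty = 2,
                   bty = "n")
  invisible(x)
}
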