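#' Configuration for the two-sample summary-statistics generator
#'
#' Describes one cis region: M variants at positions inside a drug-target
#' window, an LD model, sparse per-allele causal effects on the exposure
#' (`beta`, exposure units per allele), a causal effect of the exposure on
#' the outcome (`theta`, log-odds per exposure unit), per-allele direct
#' (pleiotropic) effects on the outcome (`alpha`, log-odds), and the two
#' sample sizes. The outcome is a case-control trait with case fraction
#' `case_frac`.
#'
#' @param M number of variants (>= 1).
#' @param beta length-M per-allele exposure effects (recycled scalar 0).
#' @param theta causal effect of exposure on outcome (log-odds per unit).
#' @param alpha length-M per-allele direct outcome effects (recycled
#'   scalar 0).
#' @param n_x,n_y exposure / outcome GWAS sample sizes (defaults: a
#'   biobank-scale glucose GWAS, N = 309895, and an RA case-control GWAS,
#'   22350 cases / 74823 controls).
#' @param case_frac outcome case fraction.
#' @param ld list: `list(type = "ar1", rho = ...)` (rho in (-1, 1)) or
#'   `list(type = "identity")`.
#' @param maf_bounds length-2 MAF sampling bounds, subset of (0, 0.5].
#' @param maf optional length-M vector pinning MAFs (NA entries are drawn);
#'   lets presets fix causal-variant frequencies so instrument strength is
#'   deterministic in expectation.
#' @param chrom,region_start,region_end genomic frame for the emitted
#'   positions (defaults: the PPARG region).
#' @param sigma_x exposure residual sd (trait units; default 1).
#' @param palindromic_frac fraction of (non-causal) variants assigned a
#'   palindromic allele pair.
#' @param outcome_flip_frac fraction of outcome records emitted under the
#'   opposite effect-allele orientation (exercises harmonization; the
#'   association content is unchanged).
#' @param seed mandatory RNG seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(M, beta = 0, theta = 0, alpha = 0,
                              n_x = 309895, n_y = 97173,
                              case_frac = 22350 / 97173,
                              ld = list(type = "ar1", rho = 0.5),
                              maf_bounds = c(0.05, 0.45), maf = NULL,
                              chrom = "3", region_start = 12328867,
                              region_end = 12475855, sigma_x = 1,
                              palindromic_frac = 0.1,
                              outcome_flip_frac = 0.3, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (M < 1) stop("M must be >= 1")
  if (n_x < 2 || n_y < 2) stop("sample sizes must be >= 2")
  if (case_frac <= 0 || case_frac >= 1) stop("case_frac must lie in (0,1)")
  if (identical(ld$type, "ar1") && abs(ld$rho) >= 1)
    stop("AR(1) rho must lie in (-1, 1)")
  if (maf_bounds[1] <= 0 || maf_bounds[2] > 0.5)
    stop("maf_bounds must be a subset of (0, 0.5]")
  beta <- rep_len(beta, M)
  alpha <- rep_len(alpha, M)
  if (!is.null(maf)) maf <- rep_len(maf, M)
  structure(list(M = M, beta = beta, theta = theta, alpha = alpha,
                 n_x = n_x, n_y = n_y, case_frac = case_frac, ld = ld,
                 maf_bounds = maf_bounds, maf = maf, chrom = chrom,
                 region_start = region_start, region_end = region_end,
                 sigma_x = sigma_x, palindromic_frac = palindromic_frac,
                 outcome_flip_frac = outcome_flip_frac, seed = seed),
            class = "simulation_config")
}

#' Named scenario presets for the generator
#'
#' Deterministic, fully populated configurations emulating the situations
#' the analysis must handle. All presets place the region in the PPARG
#' window and pin causal-variant MAFs at 0.25 so per-variant instrument
#' strength is controlled:
#' \describe{
#'   \item{null-region}{no effects anywhere (beta = theta = alpha = 0).}
#'   \item{one-causal}{a single strong exposure variant (expected F about
#'     750 at n_x = 3e5), theta = 0.2.}
#'   \item{multi-causal}{three well-separated strong exposure variants,
#'     theta = 0.2, independent LD.}
#'   \item{directional-pleiotropy}{20 independent instruments with varying
#'     exposure effects and a constant per-allele direct outcome effect
#'     alpha = 0.05, theta = 0.1.}
#'   \item{balanced-pleiotropy}{10 instruments of which 4 (40% of weight)
#'     carry a large directional direct effect; the valid majority keeps
#'     the weighted median consistent while IVW is biased.}
#'   \item{weak-instrument}{one causal variant tuned so the expected
#'     per-variant F is about 8 (below the strength bar).}
#'   \item{shared-causal}{one variant drives both traits (strong exposure
#'     effect plus a direct outcome effect at the same variant).}
#'   \item{distinct-causal}{the exposure and outcome signals sit on
#'     different, weakly correlated variants.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed for the resolved config.
#' @param overrides named list applied over the preset fields last.
#' @return a [simulation_config].
#' @export
preset <- function(name, seed, overrides = list()) {
  presets <- c("null-region", "one-causal", "multi-causal",
               "directional-pleiotropy", "balanced-pleiotropy",
               "weak-instrument", "shared-causal", "distinct-causal")
  if (!name %in% presets)
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  # per-allele effect giving standardized effect b_std = b * sqrt(2 maf(1-maf));
  # at maf 0.25 the scale is sqrt(0.375) ~ 0.612
  scale25 <- sqrt(2 * 0.25 * 0.75)
  # top-tier cis signal (~0.08 exposure units per allele, like the strongest
  # glucose cis loci): expected F ~ n_x * 0.05^2 = 750 at n_x = 3e5, so that
  # a 200-replicate bias measurement is not dominated by Monte-Carlo noise
  strong <- 0.05 / scale25
  args <- switch(name,
    "null-region" = list(M = 50, beta = 0, theta = 0, alpha = 0),
    "one-causal" = {
      b <- rep(0, 30); m <- rep(NA_real_, 30)
      b[15] <- strong; m[15] <- 0.25
      list(M = 30, beta = b, theta = 0.2, alpha = 0, maf = m,
           n_x = 3e5, n_y = 1e5)
    },
    "multi-causal" = {
      b <- rep(0, 30); m <- rep(NA_real_, 30)
      b[c(5, 15, 25)] <- strong; m[c(5, 15, 25)] <- 0.25
      list(M = 30, beta = b, theta = 0.2, alpha = 0, maf = m,
           n_x = 3e5, n_y = 1e5, ld = list(type = "ar1", rho = 0.2))
    },
    "directional-pleiotropy" = list(
      M = 20, beta = seq(0.015, 0.03, length.out = 20),
      theta = 0.1, alpha = 0.05, maf = rep(0.25, 20),
      n_x = 3e5, n_y = 1e5, ld = list(type = "identity"),
      palindromic_frac = 0),
    "balanced-pleiotropy" = list(
      M = 10, beta = strong, theta = 0.1,
      alpha = c(rep(0.06, 4), rep(0, 6)), maf = rep(0.25, 10),
      n_x = 3e5, n_y = 1e5, ld = list(type = "identity"),
      palindromic_frac = 0),
    "weak-instrument" = {
      b <- rep(0, 20); m <- rep(NA_real_, 20)
      b[10] <- sqrt(7 / 309895) / scale25; m[10] <- 0.25
      list(M = 20, beta = b, theta = 0.2, alpha = 0, maf = m)
    },
    "shared-causal" = {
      b <- rep(0, 50); a <- rep(0, 50); m <- rep(NA_real_, 50)
      b[25] <- 0.015 / scale25; a[25] <- 0.06 / scale25; m[25] <- 0.25
      list(M = 50, beta = b, theta = 0, alpha = a, maf = m)
    },
    "distinct-causal" = {
      b <- rep(0, 50); a <- rep(0, 50); m <- rep(NA_real_, 50)
      b[15] <- 0.015 / scale25; m[15] <- 0.25
      a[40] <- 0.06 / scale25; m[40] <- 0.25
      list(M = 50, beta = b, theta = 0, alpha = a, maf = m)
    })
  args[names(overrides)] <- overrides
  args$seed <- if (!is.null(overrides$seed)) overrides$seed else seed
  do.call(simulation_config, args)
}

ld_matrix_for <- function(config) {
  if (identical(config$ld$type, "identity"))
    diag(config$M)
  else if (identical(config$ld$type, "ar1"))
    config$ld$rho^abs(outer(seq_len(config$M), seq_len(config$M), "-"))
  else if (identical(config$ld$type, "matrix"))
    as.matrix(config$ld$r)
  else stop("unknown LD model type: ", config$ld$type)
}

#' Simulate two-sample GWAS summary statistics for one cis region
#'
#' Draws marginal association estimates directly from their asymptotic
#' sampling distribution on the standardized-genotype scale: with LD matrix
#' R and standardized causal effects b (converted from the per-allele
#' `beta` via sqrt(2 maf (1 - maf))),
#' `b_x ~ MVN(R b, R sigma_x^2 / n_x)` for the continuous exposure and
#' `b_y ~ MVN(R (theta b + a), R c / n_y)` with `c = 1/(phi (1 - phi))` for
#' the case-control outcome (logistic-score variance approximation at case
#' fraction phi). Standard errors are the theoretical values, effects are
#' converted back to the per-allele scale, and p-values follow two-sided
#' normal theory. The exposure and outcome draws are independent
#' (non-overlapping samples).
#'
#' @param config a [simulation_config] (or a preset name plus seed via
#'   [preset]).
#' @return list with `exposure` and `outcome` ([sumstats]), `ld`
#'   ([ld_reference] with allele orientations and positions), and `truth`
#'   (the generative parameters: beta, theta, alpha, maf, positions, seed).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  M <- config$M
  withr_seed(config$seed, {
    maf <- stats::runif(M, config$maf_bounds[1], config$maf_bounds[2])
    if (!is.null(config$maf)) {
      pin <- !is.na(config$maf)
      maf[pin] <- config$maf[pin]
    }
    pos <- sort(sample(seq(config$region_start, config$region_end), M))
    rsid <- sprintf("rs%07d", sample(1e6, M))

    nonpal <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("C", "A"), c("G", "T"))
    pal <- list(c("A", "T"), c("C", "G"))
    causal <- config$beta != 0 | config$alpha != 0
    pal_pick <- stats::runif(M) < config$palindromic_frac & !causal
    alleles <- t(vapply(seq_len(M), function(i) {
      pool <- if (pal_pick[i]) pal else nonpal
      pool[[sample(length(pool), 1)]]
    }, character(2)))

    g_sd <- sqrt(2 * maf * (1 - maf))       # per-allele -> standardized
    b_std <- config$beta * g_sd
    a_std <- config$alpha * g_sd
    identity_ld <- identical(config$ld$type, "identity")
    R <- ld_matrix_for(config)
    corr_noise <- if (identity_ld) {
      function(z) z  # skip the O(M^3) factorization for independent panels
    } else {
      L <- tryCatch(chol(R), error = function(e)
        stop("LD matrix is not positive definite: ", conditionMessage(e)))
      function(z) drop(crossprod(L, z))
    }
    mu_x <- if (identity_ld) b_std else drop(R %*% b_std)
    mu_y <- config$theta * b_std + a_std
    if (!identity_ld) mu_y <- drop(R %*% mu_y)
    se_x_std <- config$sigma_x / sqrt(config$n_x)
    cc <- 1 / (config$case_frac * (1 - config$case_frac))
    se_y_std <- sqrt(cc / config$n_y)
    bx_std <- mu_x + corr_noise(stats::rnorm(M)) * se_x_std
    by_std <- mu_y + corr_noise(stats::rnorm(M)) * se_y_std

    mk <- function(b_std_hat, se_std) {
      beta <- b_std_hat / g_sd
      se <- se_std / g_sd
      data.frame(chrom = config$chrom, pos = pos, rsid = rsid,
                 effect_allele = alleles[, 1], other_allele = alleles[, 2],
                 eaf = maf, beta = beta, se = se,
                 pval = pmax(2 * stats::pnorm(-abs(beta / se)),
                             .Machine$double.xmin),
                 n = NA_real_, stringsAsFactors = FALSE)
    }
    ex <- mk(bx_std, se_x_std)
    ex$n <- config$n_x
    ou <- mk(by_std, se_y_std)
    ou$n <- config$n_y

    # emit a fraction of outcome records on the opposite orientation so the
    # two datasets genuinely need harmonizing; palindromic variants keep the
    # panel orientation (their strand is resolved by frequency downstream)
    flip <- stats::runif(M) < config$outcome_flip_frac &
      !is_palindromic(alleles[, 1], alleles[, 2])
    exposure <- sumstats(ex, "exposure", "continuous", unit = "mmol/L")
    n_cases <- round(config$case_frac * config$n_y)
    outcome <- sumstats(ou, "outcome", "binary", unit = "log-odds",
                        n_cases = n_cases,
                        n_controls = config$n_y - n_cases)
    if (any(flip)) outcome <- flip_alleles(outcome, rsid[flip])

    dimnames(R) <- list(rsid, rsid)
    panel <- ld_reference(R, alleles = data.frame(
      rsid = rsid, effect_allele = alleles[, 1], other_allele = alleles[, 2],
      pos = pos, stringsAsFactors = FALSE))
    list(exposure = exposure, outcome = outcome, ld = panel,
         truth = list(beta = config$beta, theta = config$theta,
                      alpha = config$alpha, maf = maf, pos = pos,
                      rsid = rsid, flipped_in_outcome = rsid[flip],
                      seed = config$seed))
  })
}

#' Write a simulated two-sample dataset to disk
#'
#' Emits the exposure and outcome summary-statistic TSVs, the LD matrix TSV
#' (plus allele sidecar) and a truth JSON into `dir`.
#'
#' @param sim output of [simulate_two_sample].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             ld = file.path(dir, "ld.tsv"),
             truth = file.path(dir, "truth.json"))
  write_sumstats(sim$exposure, paths[["exposure"]])
  write_sumstats(sim$outcome, paths[["outcome"]])
  write_ld(sim$ld, paths[["ld"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
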