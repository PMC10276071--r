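make_records <- function(pos, chrom = "3", pval = 0.5,
                         rsid = paste0("rs", seq_along(pos))) {
  data.frame(chrom = chrom, pos = pos, rsid = rsid,
             effect_allele = "A", other_allele = "G", eaf = 0.3,
             beta = 0.01, se = 0.002, pval = pval, n = 1e5)
}

test_that("cis extraction uses the closed window around every target gene", {
  tzd <- pparg_target()
  lo <- 12328867 - 2500
  hi <- 12475855 + 2500
  pos <- c(lo - 1, lo, lo + 1, 12400000, hi - 1, hi, hi + 1)
  ds <- sumstats(make_records(pos), "glucose", "continuous")
  got <- extract_cis(ds, tzd, 2500)
  expect_equal(got$pos, c(lo, lo + 1, 12400000, hi - 1, hi))
  # brute-force interval check on a fixture with a known in/out split
  pos2 <- c(12300000, 12310000, 12320000, lo - 1, lo, 12400000, 12450000,
            hi, hi + 1, 12500000)
  inside <- pos2 >= lo & pos2 <= hi
  ds2 <- sumstats(make_records(pos2), "glucose", "continuous")
  expect_equal(extract_cis(ds2, tzd, 2500)$pos, pos2[inside])
  expect_equal(sum(inside), 4)
  # off-chromosome variants never match; empty datasets yield empty results
  ds3 <- sumstats(make_records(12400000, chrom = "7"), "g", "continuous")
  expect_equal(nrow(extract_cis(ds3, tzd, 2500)), 0)
  expect_equal(nrow(extract_cis(ds2[0, ], tzd, 2500)), 0)
  expect_error(extract_cis(ds2, tzd, -1), "window_bp")
})

test_that("multi-gene targets union their windows without duplicates", {
  su <- drug_target(load_drug_targets(), "sulfonylureas")
  # one variant in the inter-gene gap covered by both flanks (gap is 3167 bp)
  pos <- c(17386719 - 3000, 17412000, 17498441 + 3000)
  ds <- sumstats(make_records(pos, chrom = "11"), "g", "continuous")
  got <- extract_cis(ds, su, 5000)
  expect_equal(got$pos, pos)
  expect_equal(anyDuplicated(got$rsid), 0)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))^2
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("BH adjustment is monotone in each input p-value", {
  set.seed(11)
  p <- runif(15)
  q <- bh_fdr(p)
  for (i in 1:30) {
    j <- sample(15, 1)
    p2 <- p
    p2[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
    expect_true(all(bh_fdr(p2) >= q - 1e-12))
  }
})

test_that("clumping follows the greedy minimum-p rule", {
  panel3 <- ld_reference(local({
    r <- diag(3)
    r[1, 2] <- r[2, 1] <- sqrt(0.5)
    r[1, 3] <- r[3, 1] <- sqrt(0.0005)
    r[2, 3] <- r[3, 2] <- sqrt(0.0002)
    dimnames(r) <- list(paste0("rs", 1:3), paste0("rs", 1:3))
    r
  }))
  recs <- make_records(c(100, 200, 300), pval = c(1e-8, 1e-6, 1e-4))
  kept <- clump(recs, panel3, 0.001)
  expect_setequal(kept$rsid, c("rs1", "rs3"))
  expect_equal(kept$rsid[1], "rs1")  # global minimum p always retained
  # single record is returned unchanged
  expect_equal(clump(recs[2, ], panel3, 0.001)$rsid, "rs2")
  # r2 = 0.002 at threshold 0.001: only the lower-p variant survives
  p2 <- ld_reference(matrix(c(1, sqrt(0.002), sqrt(0.002), 1), 2,
                            dimnames = list(c("rs1", "rs2"),
                                            c("rs1", "rs2"))))
  expect_equal(clump(make_records(c(1, 2), pval = c(1e-4, 1e-6),
                                  rsid = c("rs1", "rs2")), p2, 0.001)$rsid,
               "rs2")
  expect_error(clump(make_records(1, rsid = "zz"), panel3, 0.001),
               "not in LD panel")
})

test_that("clump output is invariant to input ordering", {
  set.seed(3)
  panel <- make_ld_ar1(12, 0.6, rsid = paste0("rs", 1:12))
  recs <- make_records(seq(100, 1200, by = 100), pval = runif(12))
  ref <- clump(recs, panel, 0.05)
  for (i in 1:10) {
    perm <- recs[sample(12), ]
    expect_equal(clump(perm, panel, 0.05)$rsid, ref$rsid)
  }
  r2 <- panel$r[ref$rsid, ref$rsid]^2
  expect_true(all(r2[upper.tri(r2)] < 0.05))
})

test_that("palindromic variants are admitted only below the MAF cutoff", {
  rec <- function(ea, oa, eaf) list(effect_allele = ea, other_allele = oa,
                                    eaf = eaf)
  expect_true(palindrome_admissible(rec("A", "G", 0.5)))
  expect_true(palindrome_admissible(rec("A", "T", 0.25)))
  expect_false(palindrome_admissible(rec("C", "G", 0.65)))  # MAF 0.35
  expect_false(palindrome_admissible(rec("T", "A", 0.5)))
  expect_true(palindrome_admissible(rec("G", "C", 0.71)))   # MAF 0.29
})

test_that("proxy lookup returns the best qualifying candidate with its sign", {
  # one-factor correlation structure keeps the matrix positive semidefinite
  lam <- c(1, -sqrt(0.95), sqrt(0.85), sqrt(0.5))
  r <- tcrossprod(lam)
  diag(r) <- 1
  dimnames(r) <- list(paste0("v", 1:4), paste0("v", 1:4))
  panel <- ld_reference(r)
  outcome <- sumstats(make_records(1:3 * 100, rsid = c("v2", "v3", "v4")),
                      "o", "continuous")
  pr <- find_proxy("v1", outcome, panel, r2_min = 0.8)
  expect_equal(pr$rsid, "v2")
  expect_equal(pr$r, -sqrt(0.95))
  expect_equal(pr$r2, 0.95)
  # an instrument already present in the outcome is a caller error
  out2 <- sumstats(make_records(1:2 * 100, rsid = c("v1", "v2")), "o",
                   "continuous")
  expect_error(find_proxy("v1", out2, panel), "no proxy is needed")
  # nothing above the threshold: no proxy
  out3 <- sumstats(make_records(100, rsid = "v4"), "o", "continuous")
  expect_null(find_proxy("v1", out3, panel, r2_min = 0.8))
  expect_error(find_proxy("zz", outcome, panel), "not in LD panel")
})

test_that("F statistics follow (beta/se)^2 and flag weak sets", {
  expect_equal(f_statistic(0.02, 0.005), 16)
  expect_equal(f_statistic(0, 0.01), 0)
  expect_error(f_statistic(0.1, 0), "se")
  hs <- make_records(1:2 * 100)
  hs$beta <- c(0.03, 0.01)
  expect_equal(mean(f_statistic(hs$beta, hs$se)), mean(c(225, 25)))
})

test_that("a null region yields no instruments, with an FDR reason", {
  sim <- simulate_two_sample(preset("null-region", seed = 7))
  sel <- select_instruments(sim$exposure, sim$outcome, pparg_target(),
                            sim$ld)
  expect_equal(nrow(sel$instruments), 0)
  expect_true(is.na(sel$mean_f))
  expect_true(all(sel$exclusions$stage == "fdr"))
  expect_equal(nrow(sel$exclusions), 50)
})

test_that("a single strong causal variant is selected with F above 10", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_two_sample(preset("one-causal", seed = s))
    causal <- sim$truth$rsid[sim$truth$beta != 0]
    sel <- select_instruments(sim$exposure, sim$outcome, pparg_target(),
                              sim$ld)
    expect_true(causal %in% sel$instruments$rsid)
    expect_gt(sel$instruments$f_stat[sel$instruments$rsid == causal], 10)
    expect_false(sel$weak)
    nrow(sel$instruments)
  }, numeric(1))
  # the causal variant dominates; spurious extra instruments are the
  # exception, not the rule
  expect_gt(mean(hits == 1), 0.5)
})

test_that("the weak-instrument preset is flagged (expected F near 8)", {
  fs <- vapply(1:30, function(s) {
    sim <- simulate_two_sample(preset("weak-instrument", seed = s))
    causal <- sim$truth$rsid[sim$truth$beta != 0]
    i <- match(causal, sim$exposure$rsid)
    f_statistic(sim$exposure$beta[i], sim$exposure$se[i])
  }, numeric(1))
  expect_equal(mean(fs), 8, tolerance = 0.25)
  # an instrument set whose mean F is below ten carries the weak flag
  sim <- simulate_two_sample(simulation_config(
    M = 5, seed = 2, beta = 0.010, maf = 0.25, n_x = 1e5,
    ld = list(type = "identity"), palindromic_frac = 0))
  sel <- select_instruments(sim$exposure, sim$outcome, pparg_target(),
                            sim$ld, fdr_threshold = 1, clump_r2 = 1)
  expect_lte(sel$mean_f, 10)
  expect_true(sel$weak)
})

test_that("degenerate thresholds return every admissible cis variant", {
  sim <- simulate_two_sample(simulation_config(M = 25, seed = 9,
                                               palindromic_frac = 0.3))
  sel <- select_instruments(sim$exposure, NULL, pparg_target(), sim$ld,
                            fdr_threshold = 1, clump_r2 = 1)
  win <- extract_cis(sim$exposure, pparg_target(), 2500)
  admissible <- vapply(seq_len(nrow(win)), function(i)
    palindrome_admissible(win[i, ]), logical(1))
  expect_setequal(sel$instruments$rsid, win$rsid[admissible])
})

test_that("every excluded variant is logged exactly once with one reason", {
  sim <- simulate_two_sample(simulation_config(M = 40, seed = 5,
                                               beta = c(rep(0.08, 2),
                                                        rep(0, 38)),
                                               palindromic_frac = 0.4,
                                               maf = c(0.25, 0.25,
                                                       rep(NA, 38))))
  sel <- select_instruments(sim$exposure, sim$outcome, pparg_target(),
                            sim$ld)
  win <- extract_cis(sim$exposure, pparg_target(), 2500)
  logged <- sel$exclusions$rsid
  expect_equal(anyDuplicated(logged), 0)
  expect_setequal(c(logged, sel$instruments$rsid), win$rsid)
})

test_that("a functional-variant override yields exactly that instrument", {
  sim <- simulate_two_sample(preset("multi-causal", seed = 2))
  target_rsid <- sim$truth$rsid[sim$truth$beta != 0][2]
  sel <- select_instruments(sim$exposure, sim$outcome, pparg_target(),
                            sim$ld, functional_rsid = target_rsid)
  expect_equal(sel$instruments$rsid, target_rsid)
  expect_error(
    select_instruments(sim$exposure, sim$outcome, pparg_target(), sim$ld,
                       functional_rsid = "rs0000000"),
    "not found in the cis window")
})
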