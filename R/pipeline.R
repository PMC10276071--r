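#' Pipeline configuration
#'
#' Collects every analysis threshold with the study defaults: a 2.5 kb cis
#' window, FDR 0.05 within the window, clumping r^2 < 0.001 (relaxed 0.1 for
#' the sensitivity run), proxy r^2 > 0.8, palindromic MAF < 0.3, Bonferroni
#' alpha 0.05 over 6 drug classes, and odds scaling per 0.1 exposure unit
#' lower. Dataset slots accept in-memory objects ([sumstats],
#' [ld_reference], `drug_targets`) or file paths.
#'
#' @param exposure,outcome exposure / outcome datasets or paths.
#' @param controls named list of control-outcome datasets (names are control
#'   outcome labels matching [default_expectations]); optional.
#' @param ld LD panel or path.
#' @param targets drug-target table or path; NULL for the built-in fixture.
#' @param drug_classes classes to analyze (default: all in `targets`).
#' @param window_bp,fdr_threshold,clump_r2,relaxed_clump_r2,proxy_r2,palindrome_maf
#'   selection thresholds.
#' @param functional_variants named list mapping a drug class to a
#'   functional-variant rsid analyzed as an independent instrument set.
#' @param alpha,n_tests Bonferroni parameters.
#' @param scale_factor odds-ratio scaling factor (default -0.1).
#' @param coloc_flank_bp,coloc_p1,coloc_p2,coloc_p12 colocalization region
#'   flank and priors.
#' @param bootstrap_reps bootstrap replicates for median/mode ses.
#' @param strict_gate require nominal significance in the control gate.
#' @param seed RNG seed for the bootstrap stages.
#' @param out_dir optional output directory for [write_report].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(exposure, outcome, controls = list(), ld,
                            targets = NULL, drug_classes = NULL,
                            window_bp = 2500L, fdr_threshold = 0.05,
                            clump_r2 = 0.001, relaxed_clump_r2 = 0.1,
                            proxy_r2 = 0.8, palindrome_maf = 0.3,
                            functional_variants = list(),
                            alpha = 0.05, n_tests = 6, scale_factor = -0.1,
                            coloc_flank_bp = 2e5, coloc_p1 = 1e-4,
                            coloc_p2 = 1e-4, coloc_p12 = 1e-5,
                            bootstrap_reps = 10000, strict_gate = FALSE,
                            seed = 1L, out_dir = NULL) {
  stopifnot(window_bp >= 0, fdr_threshold > 0, fdr_threshold <= 1,
            clump_r2 > 0, clump_r2 <= 1, relaxed_clump_r2 > 0,
            relaxed_clump_r2 <= 1, proxy_r2 > 0, proxy_r2 <= 1,
            palindrome_maf > 0, palindrome_maf <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config]; dataset slots are file
#' paths. `controls` is a mapping from control outcome label to path.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

resolve_sumstats <- function(x, trait_name, trait_type = "continuous",
                             n_cases = NA_real_, n_controls = NA_real_) {
  if (inherits(x, "sumstats")) return(x)
  if (is.character(x))
    return(read_sumstats(x, trait_name, trait_type,
                         n_cases = n_cases, n_controls = n_controls))
  stop("cannot resolve dataset for ", trait_name)
}

#' Run the full drug-target MR pipeline
#'
#' Per drug class: cis-instrument selection (primary clumping and a relaxed
#' sensitivity run), harmonization against the outcome, the positive-control
#' direction gate (when control datasets are supplied), MR estimation with
#' method dispatch and Bonferroni gating, and colocalization of the regional
#' signals for classes whose primary result passes the Bonferroni gate.
#' Functional-variant instruments are analyzed as separate entries. Failures
#' are contained per class: a class with no surviving instruments is
#' reported with status `"no-instruments"`, a class failing the control gate
#' with `"gate-failed"` (its primary MR is suppressed).
#'
#' @param config a `pipeline_config` (or path to a YAML file).
#' @return An object of class `pipeline_report`: list with `classes` (one
#'   entry per analysis: status, instrument summary, gate, MR result tables,
#'   coloc posteriors, exclusion log) and `provenance` (parameter echo,
#'   seed, package version).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  exposure <- resolve_sumstats(config$exposure, "exposure", "continuous")
  outcome <- resolve_sumstats(config$outcome, "outcome", "binary",
                              n_cases = 0, n_controls = 0)
  controls <- lapply(config$controls, resolve_sumstats,
                     trait_name = "control")
  panel <- if (inherits(config$ld, "ld_reference")) config$ld
           else read_ld(config$ld)
  targets <- if (is.null(config$targets)) load_drug_targets()
             else if (is.character(config$targets))
               load_drug_targets(config$targets)
             else config$targets
  classes <- config$drug_classes
  if (is.null(classes)) classes <- unique(targets$drug_class)
  expectations <- default_expectations()

  analyze <- function(drug_class, functional_rsid = NULL) {
    target <- drug_target(targets, drug_class)
    sel <- function(out_ds, r2) select_instruments(
      exposure, out_ds, target, panel, window_bp = config$window_bp,
      fdr_threshold = config$fdr_threshold, clump_r2 = r2,
      palindrome_maf = config$palindrome_maf, proxy_r2 = config$proxy_r2,
      functional_rsid = functional_rsid)
    primary_sel <- sel(outcome, config$clump_r2)
    sensitivity_sel <- sel(outcome, config$relaxed_clump_r2)
    entry <- list(drug_class = drug_class,
                  functional_rsid = functional_rsid,
                  n_instruments = nrow(primary_sel$instruments),
                  mean_f = primary_sel$mean_f,
                  weak = primary_sel$weak,
                  instruments = primary_sel$instruments$rsid,
                  sensitivity_instruments = sensitivity_sel$instruments$rsid,
                  exclusions = primary_sel$exclusions)
    if (!nrow(primary_sel$instruments)) {
      entry$status <- "no-instruments"
      entry$reason <- if (nrow(primary_sel$exclusions))
        utils::tail(primary_sel$exclusions$reason, 1) else "empty cis window"
      return(entry)
    }
    hs <- align_datasets(primary_sel, outcome, panel)
    hs_sens <- align_datasets(sensitivity_sel, outcome, panel)
    entry$exclusions <- attr(hs, "exclusions")

    if (length(controls)) {
      control_fits <- lapply(names(controls), function(label) {
        cs <- sel(controls[[label]], config$clump_r2)
        ch <- align_datasets(cs, controls[[label]], panel)
        mr_fit(ch, factor = config$scale_factor, alpha = config$alpha,
               n_tests = config$n_tests,
               bootstrap_reps = config$bootstrap_reps, seed = config$seed)
      })
      names(control_fits) <- names(controls)
      gate <- evaluate_gate(drug_class, control_fits,
                            expectations = expectations,
                            strict = config$strict_gate)
      entry$gate <- list(passed = gate$passed, reasons = gate$reasons,
                         table = gate$table)
      entry$control_results <- lapply(control_fits, function(f) f$results)
      if (!gate$passed) {
        entry$status <- "gate-failed"
        return(entry)
      }
    }

    fit <- mr_fit(hs, factor = config$scale_factor, alpha = config$alpha,
                  n_tests = config$n_tests,
                  bootstrap_reps = config$bootstrap_reps, seed = config$seed)
    fit_sens <- mr_fit(hs_sens, factor = config$scale_factor,
                       alpha = config$alpha, n_tests = config$n_tests,
                       bootstrap_reps = config$bootstrap_reps,
                       seed = config$seed)
    entry$status <- if (fit$k == 0) "no-instruments" else "analyzed"
    entry$mr <- fit$results
    entry$mr_sensitivity <- fit_sens$results
    if (fit$k > 0 && fit$results$bonferroni_significant[1]) {
      entry$coloc <- tryCatch({
        cr <- coloc_region(exposure, outcome, target,
                           flank_bp = config$coloc_flank_bp,
                           p1 = config$coloc_p1, p2 = config$coloc_p2,
                           p12 = config$coloc_p12)
        c(as.list(cr$pp), n_variants = cr$n_variants, region = cr$region)
      }, error = function(e) list(error = conditionMessage(e)))
    }
    entry
  }

  entries <- list()
  for (cl in classes) {
    entries[[cl]] <- analyze(cl)
    frsid <- config$functional_variants[[cl]]
    if (!is.null(frsid))
      entries[[paste0(cl, " (functional)")]] <-
        tryCatch(analyze(cl, functional_rsid = frsid),
                 error = function(e)
                   list(drug_class = cl, functional_rsid = frsid,
                        status = "no-instruments",
                        reason = conditionMessage(e)))
  }

  report <- structure(list(
    classes = entries,
    provenance = list(
      params = config[c("window_bp", "fdr_threshold", "clump_r2",
                        "relaxed_clump_r2", "proxy_r2", "palindrome_maf",
                        "alpha", "n_tests", "scale_factor", "coloc_flank_bp",
                        "coloc_p1", "coloc_p2", "coloc_p12",
                        "bootstrap_reps", "strict_gate")],
      seed = config$seed,
      package = "targetmr",
      version = as.character(utils::packageVersion("targetmr")))),
    class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Drug-target MR pipeline report\n")
  for (nm in names(x$classes)) {
    e <- x$classes[[nm]]
    cat(sprintf("- %s: %s", nm, e$status))
    if (identical(e$status, "analyzed")) {
      r <- e$mr[1, ]
      cat(sprintf(" — %s OR %.2f (%.2f-%.2f), p = %.3g%s", r$method, r$or,
                  r$ci_low, r$ci_high, r$pval,
                  if (r$bonferroni_significant) " *" else ""))
    }
    cat("\n")
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (the full report), `results.tsv` (one row per drug
#' class x analysis x method) and `exclusions.tsv` (rsid, stage, reason per
#' excluded variant) into `dir`.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @return named vector of paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(json = file.path(dir, "report.json"),
             results = file.path(dir, "results.tsv"),
             exclusions = file.path(dir, "exclusions.tsv"))
  jsonlite::write_json(unclass(report), paths[["json"]], auto_unbox = TRUE,
                       digits = NA, null = "null", na = "string")
  rows <- list()
  excl <- list()
  for (nm in names(report$classes)) {
    e <- report$classes[[nm]]
    for (analysis in c("mr", "mr_sensitivity")) {
      tab <- e[[analysis]]
      if (is.null(tab) || !nrow(tab)) next
      tab <- cbind(drug_class = nm,
                   analysis = if (analysis == "mr") "primary"
                              else "sensitivity",
                   tab)
      rows[[length(rows) + 1L]] <- tab
    }
    if (!is.null(e$exclusions) && nrow(e$exclusions))
      excl[[length(excl) + 1L]] <- cbind(drug_class = nm, e$exclusions)
  }
  res <- if (length(rows)) do.call(rbind, rows)
    else data.frame(drug_class = character(0))
  utils::write.table(res, paths[["results"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ex <- if (length(excl)) do.call(rbind, excl)
    else data.frame(drug_class = character(0), rsid = character(0),
                    stage = character(0), reason = character(0))
  utils::write.table(ex, paths[["exclusions"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
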