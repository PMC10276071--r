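#' Expected positive-control effect directions per drug class
#'
#' Encodes the pharmacologically established effects used to validate the
#' genetic instruments before the primary analysis. All drug classes lower
#' glucose, so every class is expected to reduce T2DM risk. Weight effects
#' differ: GLP-1 receptor agonists and SGLT2 inhibitors cause weight loss,
#' DPP-4 inhibitors are weight-neutral, while insulin, thiazolidinediones
#' and sulfonylureas promote weight gain. Thiazolidinediones improve insulin
#' sensitivity (insulin resistance expected to decrease); GLP-1 receptor
#' agonists and sulfonylureas stimulate insulin secretion (fasting
#' proinsulin expected to increase).
#'
#' Directions are expressed on the glucose-lowering scale used throughout
#' (odds/level per 0.1 mmol/L lower glucose): `"decrease"` means the scaled
#' estimate is expected below the null, `"increase"` above, `"neutral"`
#' imposes no constraint.
#'
#' @return data.frame with columns `drug_class`, `outcome`, `expected`.
#' @export
default_expectations <- function() {
  weight_outcomes <- c("BMI", "hip circumference", "waist circumference")
  classes <- c("GLP-1 receptor agonists", "SGLT2 inhibitors",
               "DPP-4 inhibitors", "insulin and its analogues",
               "thiazolidinediones", "sulfonylureas")
  weight_dir <- c("GLP-1 receptor agonists" = "decrease",
                  "SGLT2 inhibitors" = "decrease",
                  "DPP-4 inhibitors" = "neutral",
                  "insulin and its analogues" = "increase",
                  "thiazolidinediones" = "increase",
                  "sulfonylureas" = "increase")
  rows <- list(data.frame(drug_class = classes, outcome = "T2DM",
                          expected = "decrease"))
  for (wo in weight_outcomes)
    rows[[length(rows) + 1L]] <- data.frame(drug_class = classes,
                                            outcome = wo,
                                            expected = unname(weight_dir[classes]))
  rows[[length(rows) + 1L]] <- data.frame(
    drug_class = "thiazolidinediones", outcome = "insulin resistance",
    expected = "decrease")
  rows[[length(rows) + 1L]] <- data.frame(
    drug_class = c("GLP-1 receptor agonists", "sulfonylureas"),
    outcome = "fasting proinsulin", expected = "increase")
  out <- do.call(rbind, rows)
  out <- out[order(match(out$drug_class, classes), out$outcome), ]
  rownames(out) <- NULL
  out
}

#' Evaluate the positive-control direction gate for one drug class
#'
#' Compares the sign of each control-outcome MR point estimate with the
#' expected direction. Concordance is judged on the point estimate only
#' (`strict = FALSE`, the default); `strict = TRUE` additionally requires
#' nominal significance (p < 0.05) of concordant estimates. Neutral
#' expectations never fail the gate, and expected outcomes with no supplied
#' estimate are recorded as untested rather than as failures. The gate
#' passes iff no tested non-neutral expectation is discordant.
#'
#' @param drug_class drug class name.
#' @param control_fits named list of `mr_fit` objects (or one-row data.frames
#'   with `theta`, `pval`), one per control outcome; names are outcome
#'   labels. The primary (first-listed) method's estimate is used.
#' @param expectations expectation table ([default_expectations]).
#' @param strict require nominal significance for concordance.
#' @return An object of class `gate_result`: list with `drug_class`,
#'   `table` (outcome, expected, theta_scaled, observed, concordant, tested),
#'   `passed`, `reasons`.
#' @export
evaluate_gate <- function(drug_class, control_fits,
                          expectations = default_expectations(),
                          strict = FALSE) {
  exp_rows <- expectations[expectations$drug_class == drug_class, ,
                           drop = FALSE]
  if (!nrow(exp_rows))
    stop("no control expectations for drug class '", drug_class, "'")
  rows <- lapply(seq_len(nrow(exp_rows)), function(i) {
    outc <- exp_rows$outcome[i]
    expd <- exp_rows$expected[i]
    fit <- control_fits[[outc]]
    if (is.null(fit) || (inherits(fit, "mr_fit") && fit$k == 0))
      return(data.frame(outcome = outc, expected = expd,
                        theta_scaled = NA_real_, observed = NA_character_,
                        concordant = NA, tested = FALSE))
    if (inherits(fit, "mr_fit")) {
      theta <- fit$results$theta[1]
      pval <- fit$results$pval[1]
      factor <- fit$factor
    } else {
      theta <- fit$theta[1]
      pval <- if ("pval" %in% names(fit)) fit$pval[1] else NA_real_
      factor <- if (!is.null(fit$factor)) fit$factor[1] else -0.1
    }
    theta_scaled <- factor * theta  # log scale per glucose-lowering unit
    observed <- if (theta_scaled < 0) "decrease"
                else if (theta_scaled > 0) "increase" else "neutral"
    concordant <- if (expd == "neutral") TRUE else observed == expd
    if (strict && isTRUE(concordant) && !is.na(pval))
      concordant <- pval < 0.05
    data.frame(outcome = outc, expected = expd, theta_scaled = theta_scaled,
               observed = observed, concordant = concordant, tested = TRUE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  discord <- tab$tested & tab$expected != "neutral" & !tab$concordant
  reasons <- if (any(discord))
    sprintf("%s: expected %s, observed %s", tab$outcome[discord],
            tab$expected[discord], tab$observed[discord])
  else character(0)
  structure(list(drug_class = drug_class, table = tab,
                 passed = !any(discord), reasons = reasons),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("Positive-control gate for %s: %s\n", x$drug_class,
              if (x$passed) "PASSED" else "FAILED"))
  print(x$table, row.names = FALSE)
  if (length(x$reasons)) cat("discordant:", paste(x$reasons, collapse = "; "),
                             "\n")
  invisible(x)
}
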