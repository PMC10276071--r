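#' GWAS summary-statistics dataset
#'
#' Container for per-variant association summaries of one trait. The table
#' holds one row per variant with the 10 canonical columns; trait-level
#' metadata (trait name, type, unit, case/control counts for binary traits)
#' travel as attributes.
#'
#' @param data data.frame with columns `chrom`, `pos`, `rsid`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   `beta` is the per-allele effect on the trait (e.g. mmol/L per allele for
#'   a continuous exposure, log-odds per allele for a binary outcome).
#' @param trait_name character trait label.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param unit unit label for `beta` (e.g. `"mmol/L"`, `"log-odds"`).
#' @param n_cases,n_controls case/control counts; required when
#'   `trait_type = "binary"`.
#' @return An object of class `sumstats`: the validated data.frame with
#'   metadata attributes.
#' @examples
#' d <- data.frame(chrom = "3", pos = 1:3 * 1000L, rsid = paste0("rs", 1:3),
#'                 effect_allele = "A", other_allele = "G", eaf = 0.3,
#'                 beta = 0.01, se = 0.002, pval = 1e-6, n = 1e5)
#' ss <- sumstats(d, "glucose", "continuous", unit = "mmol/L")
#' @export
sumstats <- function(data, trait_name, trait_type = c("continuous", "binary"),
                     unit = "", n_cases = NA_real_, n_controls = NA_real_) {
  trait_type <- match.arg(trait_type)
  data <- validate_gwas_records(data)
  if (anyDuplicated(data$rsid))
    stop("duplicated rsid in dataset: ",
         paste(unique(data$rsid[duplicated(data$rsid)]), collapse = ", "))
  if (trait_type == "binary" && (is.na(n_cases) || is.na(n_controls)))
    stop("binary trait requires n_cases and n_controls")
  structure(data,
            class = c("sumstats", "data.frame"),
            trait_name = trait_name, trait_type = trait_type, unit = unit,
            n_cases = n_cases, n_controls = n_controls)
}

SUMSTATS_COLS <- c("chrom", "pos", "rsid", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")

#' Validate a table of per-variant GWAS records
#'
#' Checks the record invariants row by row: alleles are single nucleotides in
#' \{A,C,G,T\} and differ, eaf in (0,1) (missing allowed), se > 0,
#' pval in (0,1], pos >= 1.
#'
#' @param data data.frame with the canonical 10 columns.
#' @return The data.frame with columns coerced to canonical types,
#'   row names dropped.
#' @export
validate_gwas_records <- function(data) {
  missing_cols <- setdiff(SUMSTATS_COLS, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data)[SUMSTATS_COLS]
  data$chrom <- as.character(data$chrom)
  data$pos <- as.integer(data$pos)
  data$rsid <- as.character(data$rsid)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n"))
    data[[col]] <- as.numeric(data[[col]])
  bad <- function(cond, what) {
    cond[is.na(cond)] <- TRUE
    if (any(cond))
      stop("invalid record (", what, ") for rsid: ",
           paste(data$rsid[cond], collapse = ", "))
  }
  nt <- c("A", "C", "G", "T")
  bad(!(data$effect_allele %in% nt) | !(data$other_allele %in% nt),
      "allele not in A/C/G/T")
  bad(data$effect_allele == data$other_allele, "identical alleles")
  eaf_known <- !is.na(data$eaf)
  if (any(eaf_known & (data$eaf <= 0 | data$eaf >= 1)))
    stop("invalid record (eaf outside (0,1)) for rsid: ",
         paste(data$rsid[eaf_known & (data$eaf <= 0 | data$eaf >= 1)],
               collapse = ", "))
  bad(data$se <= 0, "se must be > 0")
  bad(data$pval <= 0 | data$pval > 1, "pval outside (0,1]")
  bad(data$pos < 1, "pos must be >= 1")
  rownames(data) <- NULL
  data
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' The file must be tab-delimited with a header carrying the 10 canonical
#' columns (`chrom, pos, rsid, effect_allele, other_allele, eaf, beta, se,
#' pval, n`). `"."` denotes a missing `eaf`; all other fields are mandatory.
#' Row order is preserved.
#'
#' @inheritParams sumstats
#' @param path file path.
#' @return A [sumstats] object.
#' @export
read_sumstats <- function(path, trait_name, trait_type = "continuous",
                          unit = "", n_cases = NA_real_, n_controls = NA_real_) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = TRUE,
                           comment.char = "", quote = "")
  missing_cols <- setdiff(SUMSTATS_COLS, names(tab))
  if (length(missing_cols))
    stop("file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$eaf[tab$eaf == "."] <- NA
  sumstats(tab, trait_name = trait_name, trait_type = trait_type, unit = unit,
           n_cases = n_cases, n_controls = n_controls)
}

#' Write GWAS summary statistics to a tab-delimited file
#'
#' Inverse of [read_sumstats]: numeric fields are serialized with up to 12
#' significant digits so a write-then-read round trip preserves them.
#'
#' @param x a [sumstats] object (or plain data.frame with the 10 columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- as.data.frame(x)[SUMSTATS_COLS]
  for (col in c("eaf", "beta", "se", "pval", "n"))
    out[[col]] <- formatC(out[[col]], digits = 12, format = "g")
  out$eaf[is.na(x$eaf)] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s%s), %d variants\n",
              attr(x, "trait_name"), attr(x, "trait_type"),
              if (!is.na(attr(x, "n_cases")))
                sprintf(", %g cases / %g controls",
                        attr(x, "n_cases"), attr(x, "n_controls")) else "",
              nrow(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

trait_type <- function(x) attr(x, "trait_type")
trait_name <- function(x) attr(x, "trait_name")
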