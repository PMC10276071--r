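#' Drug-target gene regions for the major antidiabetic drug classes
#'
#' Built-in GRCh37 coordinates (1-based, inclusive) of the genes encoding the
#' target proteins of six antidiabetic drug classes, as curated from DrugBank
#' and ChEMBL. Sulfonylureas carry two adjacent genes (KCNJ11 and ABCC8);
#' every other class maps to a single gene. Metformin is excluded: its target
#' annotation is inconsistent between databases and its mechanism is not
#' settled, so no cis region can be assigned.
#'
#' @param path optional path to a user table (tab-delimited, header with
#'   columns `chrom, start, end, gene, drug_class`) replacing the built-in
#'   fixture.
#' @return A data.frame of class `drug_targets` with columns
#'   `drug_class, gene, chrom, start, end`.
#' @examples
#' targets <- load_drug_targets()
#' subset(targets, drug_class == "thiazolidinediones")
#' @export
load_drug_targets <- function(path = NULL) {
  if (is.null(path)) {
    tab <- data.frame(
      drug_class = c("GLP-1 receptor agonists", "SGLT2 inhibitors",
                     "DPP-4 inhibitors", "insulin and its analogues",
                     "thiazolidinediones", "sulfonylureas", "sulfonylureas"),
      gene  = c("GLP1R", "SLC5A2", "DPP4", "INSR", "PPARG", "KCNJ11", "ABCC8"),
      chrom = c("6", "16", "2", "19", "3", "11", "11"),
      start = c(39016557L, 31494323L, 162848755L, 7112266L, 12328867L,
                17386719L, 17414045L),
      end   = c(39059079L, 31502181L, 162930904L, 7294425L, 12475855L,
                17410878L, 17498441L),
      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "gene", "drug_class")
    missing_cols <- setdiff(need, names(tab))
    if (length(missing_cols))
      stop("target table missing column(s): ",
           paste(missing_cols, collapse = ", "))
    tab <- tab[, c("drug_class", "gene", "chrom", "start", "end")]
    tab$chrom <- as.character(tab$chrom)
    tab$start <- as.integer(tab$start)
    tab$end <- as.integer(tab$end)
  }
  if (any(tab$start > tab$end))
    stop("target region with start > end: ",
         paste(tab$gene[tab$start > tab$end], collapse = ", "))
  class(tab) <- c("drug_targets", "data.frame")
  tab
}

#' Look up the gene region(s) of one drug class
#'
#' @param targets a `drug_targets` table from [load_drug_targets].
#' @param drug_class drug class name (exact match).
#' @return The rows for that class (one per gene).
#' @export
drug_target <- function(targets, drug_class) {
  hit <- targets[targets$drug_class == drug_class, , drop = FALSE]
  if (!nrow(hit))
    stop("no target region for drug class '", drug_class,
         "' (metformin is excluded; known classes: ",
         paste(unique(targets$drug_class), collapse = ", "), ")")
  hit
}
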