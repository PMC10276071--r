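#' Linkage-disequilibrium reference panel
#'
#' A signed correlation matrix r between variant allele dosages, with the
#' effect-allele orientation of each variant recorded so that the sign of r
#' is interpretable (needed for proxy allele mapping). Validated for symmetry,
#' unit diagonal, |r| <= 1 and positive semidefiniteness (tolerance 1e-8).
#'
#' @param r square numeric matrix of signed correlations, dimnames = rsids.
#' @param alleles optional data.frame (`rsid, effect_allele, other_allele`,
#'   optionally `pos`) recording the dosage orientation per variant.
#' @param tol validation tolerance.
#' @return An object of class `ld_reference`: list with elements `rsid`,
#'   `r`, `alleles`.
#' @export
ld_reference <- function(r, alleles = NULL, tol = 1e-8) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  rsid <- rownames(r)
  if (is.null(rsid)) stop("LD matrix must carry rsid dimnames")
  if (!identical(rsid, colnames(r))) stop("LD row/column rsids disagree")
  if (max(abs(r - t(r))) > tol) stop("LD matrix not symmetric")
  if (max(abs(diag(r) - 1)) > tol) stop("LD matrix diagonal must be 1")
  if (max(abs(r)) > 1 + tol) stop("LD correlations must satisfy |r| <= 1")
  if (any(r[upper.tri(r)] != 0)) {  # diagonal matrices are trivially PSD
    ev <- eigen((r + t(r)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -tol) stop("LD matrix not positive semidefinite")
  }
  if (!is.null(alleles)) {
    alleles <- as.data.frame(alleles)
    if (!all(c("rsid", "effect_allele", "other_allele") %in% names(alleles)))
      stop("alleles table needs rsid, effect_allele, other_allele")
    alleles <- alleles[match(rsid, alleles$rsid), , drop = FALSE]
    if (anyNA(alleles$rsid)) stop("alleles table missing some panel variants")
    rownames(alleles) <- NULL
  }
  structure(list(rsid = rsid, r = r, alleles = alleles),
            class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("LD reference panel: %d variants (signed r)\n", length(x$rsid)))
  invisible(x)
}

#' Squared LD correlation between two panel variants
#'
#' @param panel an [ld_reference] object.
#' @param rsid_a,rsid_b variant identifiers.
#' @return r^2 (square of the signed correlation); symmetric in its arguments.
#' @export
ld_r2 <- function(panel, rsid_a, rsid_b) {
  ld_r(panel, rsid_a, rsid_b)^2
}

#' Signed LD correlation between two panel variants
#'
#' @inheritParams ld_r2
#' @return signed r on the panel's recorded allele orientation.
#' @export
ld_r <- function(panel, rsid_a, rsid_b) {
  ia <- match(rsid_a, panel$rsid)
  ib <- match(rsid_b, panel$rsid)
  if (is.na(ia)) stop("variant not in LD panel: ", rsid_a)
  if (is.na(ib)) stop("variant not in LD panel: ", rsid_b)
  unname(panel$r[ia, ib])
}

#' Read / write an LD panel as a tab-delimited square matrix
#'
#' The on-disk layout is a square matrix with an rsid header row and an rsid
#' first column. Allele orientations, when present, are stored alongside in
#' `<path>.alleles` (tab-delimited rsid/effect_allele/other_allele).
#'
#' @param path matrix path.
#' @return [read_ld] returns an [ld_reference]; [write_ld] returns `path`
#'   invisibly.
#' @export
read_ld <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                         check.names = FALSE)
  alleles_path <- paste0(path, ".alleles")
  alleles <- if (file.exists(alleles_path))
    utils::read.table(alleles_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  ld_reference(as.matrix(m), alleles = alleles)
}

#' @rdname read_ld
#' @param panel an [ld_reference] object.
#' @export
write_ld <- function(panel, path) {
  m <- format(panel$r, digits = 12, trim = TRUE, scientific = FALSE)
  out <- cbind(rsid = panel$rsid, as.data.frame(m, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(panel$alleles))
    utils::write.table(panel$alleles, paste0(path, ".alleles"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' AR(1) LD panel
#'
#' Autoregressive correlation structure r\[i,j\] = rho^|i-j| over `M`
#' variants; positive definite for rho in (-1, 1). Used as a stand-in for a
#' population reference panel in simulations.
#'
#' @param M number of variants.
#' @param rho lag-1 correlation, in (-1, 1).
#' @param rsid optional rsid vector (defaults to sim_1..sim_M).
#' @param alleles optional allele orientation table (see [ld_reference]).
#' @return An [ld_reference].
#' @export
make_ld_ar1 <- function(M, rho, rsid = paste0("sim_", seq_len(M)),
                        alleles = NULL) {
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  r <- rho^abs(outer(seq_len(M), seq_len(M), "-"))
  dimnames(r) <- list(rsid, rsid)
  ld_reference(r, alleles = alleles)
}
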