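#' Extract cis variants around a drug-target gene region
#'
#' Returns the exposure records lying inside the closed interval
#' \[start - window_bp, end + window_bp\] of any gene of the target (GRCh37,
#' 1-based inclusive). For multi-gene targets the windows are unioned and
#' overlapping windows return each variant once.
#'
#' @param dataset a [sumstats] object.
#' @param target one or more rows of a `drug_targets` table ([drug_target]).
#' @param window_bp flank added on each side of the gene span (default 2500).
#' @return data.frame of the records in the window, in dataset order.
#' @export
extract_cis <- function(dataset, target, window_bp = 2500L) {
  if (window_bp < 0) stop("window_bp must be >= 0")
  keep <- rep(FALSE, nrow(dataset))
  for (i in seq_len(nrow(target))) {
    keep <- keep | (dataset$chrom == target$chrom[i] &
                    dataset$pos >= target$start[i] - window_bp &
                    dataset$pos <= target$end[i] + window_bp)
  }
  out <- as.data.frame(dataset)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order. Thin
#' wrapper over [stats::p.adjust] with `method = "BH"`.
#'
#' @param pvals p-values in (0, 1].
#' @return adjusted values, each in \[p, 1\].
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Greedy LD clumping
#'
#' Iterates records by ascending p-value (ties broken by ascending position,
#' then lexicographic rsid, so the output is invariant to input ordering),
#' retaining the current best and discarding every remaining record with
#' r^2 >= `r2_threshold` against any retained one. The global minimum-p record
#' is always retained and the retained set has pairwise r^2 below threshold.
#'
#' @param records data.frame of variant records (needs `rsid, pos, pval`).
#' @param panel an [ld_reference] containing every record.
#' @param r2_threshold retain threshold on r^2 (default 0.001).
#' @return the retained records, ordered by ascending p-value.
#' @export
clump <- function(records, panel, r2_threshold = 0.001) {
  if (!nrow(records)) return(records)
  idx <- match(records$rsid, panel$rsid)
  if (anyNA(idx))
    stop("variant(s) not in LD panel: ",
         paste(records$rsid[is.na(idx)], collapse = ", "))
  ord <- order(records$pval, records$pos, records$rsid)
  records <- records[ord, , drop = FALSE]
  idx <- idx[ord]
  r2 <- panel$r[idx, idx, drop = FALSE]^2
  keep <- logical(nrow(records))
  alive <- rep(TRUE, nrow(records))
  for (i in seq_len(nrow(records))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive <- alive & (r2[i, ] < r2_threshold)
    alive[i] <- FALSE
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Palindrome admissibility of a variant
#'
#' Palindromic variants (A/T or C/G) are strand-ambiguous; they are admitted
#' as instruments only when the minor allele frequency is below `maf_cutoff`,
#' so that allele frequencies can resolve the strand downstream.
#' Non-palindromic variants are always admissible.
#'
#' @param record one-row data.frame or list with `effect_allele`,
#'   `other_allele`, `eaf`.
#' @param maf_cutoff MAF admission threshold (default 0.3).
#' @return logical.
#' @export
palindrome_admissible <- function(record, maf_cutoff = 0.3) {
  pair <- sort(c(record$effect_allele, record$other_allele))
  palindromic <- identical(pair, c("A", "T")) || identical(pair, c("C", "G"))
  if (!palindromic) return(TRUE)
  if (is.na(record$eaf)) return(FALSE)
  min(record$eaf, 1 - record$eaf) < maf_cutoff
}

is_palindromic <- function(effect_allele, other_allele) {
  a <- pmin(effect_allele, other_allele)
  b <- pmax(effect_allele, other_allele)
  (a == "A" & b == "T") | (a == "C" & b == "G")
}

#' Find an LD proxy for an instrument missing from the outcome dataset
#'
#' Scans panel variants present in the outcome dataset (optionally restricted
#' to a candidate set, e.g. the cis window plus flanks) and returns the one
#' with maximal r^2 against the instrument, provided r^2 > `r2_min`. The
#' signed correlation is returned for proxy allele mapping. Ties break by
#' distance to the instrument (when positions are available in the panel
#' allele table), then by rsid.
#'
#' @param rsid instrument identifier (must be absent from `outcome`).
#' @param outcome a [sumstats] object (the outcome dataset).
#' @param panel an [ld_reference] containing the instrument.
#' @param r2_min minimum r^2 for an acceptable proxy (default 0.8, strict).
#' @param candidates optional rsid vector restricting the search.
#' @return list(rsid, r, r2) for the best proxy, or NULL when none qualifies.
#' @export
find_proxy <- function(rsid, outcome, panel, r2_min = 0.8, candidates = NULL) {
  i <- match(rsid, panel$rsid)
  if (is.na(i)) stop("instrument not in LD panel: ", rsid)
  if (rsid %in% outcome$rsid)
    stop("instrument ", rsid, " is present in the outcome dataset; ",
         "no proxy is needed")
  cand <- intersect(panel$rsid, outcome$rsid)
  if (!is.null(candidates)) cand <- intersect(cand, candidates)
  cand <- setdiff(cand, rsid)
  if (!length(cand)) return(NULL)
  r <- panel$r[i, match(cand, panel$rsid)]
  r2 <- r^2
  ok <- r2 > r2_min
  if (!any(ok)) return(NULL)
  cand <- cand[ok]; r <- r[ok]; r2 <- r2[ok]
  dist <- rep(Inf, length(cand))
  if (!is.null(panel$alleles) && "pos" %in% names(panel$alleles)) {
    pos <- panel$alleles$pos[match(cand, panel$alleles$rsid)]
    pos0 <- panel$alleles$pos[match(rsid, panel$alleles$rsid)]
    if (!is.na(pos0)) dist <- abs(pos - pos0)
  }
  best <- order(-r2, dist, cand)[1L]
  list(rsid = cand[best], r = unname(r[best]), r2 = unname(r2[best]))
}

#' Per-variant F statistic and mean instrument strength
#'
#' F = (beta/se)^2 per variant; the mean over an instrument set gauges
#' instrument strength (mean F above 10 is the conventional bar for a strong
#' instrument).
#'
#' @param beta,se effect and standard error (vectors allowed).
#' @return F statistic(s).
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop("se must be > 0")
  (beta / se)^2
}

#' Select cis genetic instruments for one drug class
#'
#' Composition of the selection pipeline on the exposure dataset:
#' cis-window extraction around the target gene(s), Benjamini-Hochberg FDR
#' filter (computed within the extracted window), palindrome admissibility
#' filter, greedy LD clumping, and, for retained instruments absent from the
#' outcome dataset, proxy substitution (or drop when no proxy qualifies).
#' Per-variant F statistics and the mean F are attached; a weak-instrument
#' flag is raised when mean F <= 10. Every excluded variant is recorded once
#' in the exclusion log with a stage and reason code.
#'
#' When `functional_rsid` is given, the FDR/clump stages are bypassed and the
#' named variant alone is evaluated (palindrome and proxy checks still apply):
#' instruments of established biological relevance are analyzed as their own
#' instrument set.
#'
#' @param exposure exposure [sumstats].
#' @param outcome outcome [sumstats] (used for proxy lookup); may be NULL to
#'   skip the proxy stage.
#' @param target rows of a `drug_targets` table for one drug class.
#' @param panel an [ld_reference] covering the region.
#' @param window_bp,fdr_threshold,clump_r2,palindrome_maf,proxy_r2 selection
#'   parameters (defaults 2500, 0.05, 0.001, 0.3, 0.8).
#' @param proxy_flank_bp flank around the cis window searched for proxies
#'   (default 5e5).
#' @param functional_rsid optional rsid forcing a functional-variant
#'   instrument set.
#' @return An object of class `instrument_set`: list with `drug_class`,
#'   `instruments` (data.frame with `qval`, `f_stat`, `proxy_of`, `proxy_r`,
#'   `proxy_r2` columns appended), `mean_f`, `weak`, `params`, `exclusions`
#'   (data.frame rsid/stage/reason).
#' @export
select_instruments <- function(exposure, outcome, target, panel,
                               window_bp = 2500L, fdr_threshold = 0.05,
                               clump_r2 = 0.001, palindrome_maf = 0.3,
                               proxy_r2 = 0.8, proxy_flank_bp = 5e5,
                               functional_rsid = NULL) {
  drug_class <- unique(target$drug_class)[1L]
  excl <- list()
  note <- function(rsid, stage, reason) {
    excl[[length(excl) + 1L]] <<- data.frame(rsid = rsid, stage = stage,
                                             reason = reason)
  }
  win <- extract_cis(exposure, target, window_bp)

  if (is.null(functional_rsid)) {
    if (nrow(win)) {
      win$qval <- bh_fdr(win$pval)
      fail <- win$qval >= fdr_threshold
      if (any(fail)) note(win$rsid[fail], "fdr",
                          sprintf("q >= %g", fdr_threshold))
      win <- win[!fail, , drop = FALSE]
    } else win$qval <- numeric(0)
    if (nrow(win)) {
      pal_ok <- vapply(seq_len(nrow(win)), function(i)
        palindrome_admissible(win[i, ], palindrome_maf), logical(1))
      if (any(!pal_ok)) note(win$rsid[!pal_ok], "palindrome",
                             sprintf("palindromic with MAF >= %g",
                                     palindrome_maf))
      win <- win[pal_ok, , drop = FALSE]
    }
    if (nrow(win)) {
      kept <- clump(win, panel, clump_r2)
      dropped <- setdiff(win$rsid, kept$rsid)
      if (length(dropped))
        note(dropped, "clump", sprintf("r2 >= %g with a retained variant",
                                       clump_r2))
      win <- kept
    }
  } else {
    win <- win[win$rsid == functional_rsid, , drop = FALSE]
    if (!nrow(win))
      stop("functional variant ", functional_rsid,
           " not found in the cis window of ", drug_class)
    win$qval <- win$pval  # not FDR-ranked; carried for reporting
    if (!palindrome_admissible(win[1L, ], palindrome_maf)) {
      note(win$rsid, "palindrome",
           sprintf("palindromic with MAF >= %g", palindrome_maf))
      win <- win[0L, , drop = FALSE]
    }
  }

  win$proxy_of <- rep(NA_character_, nrow(win))
  win$proxy_r <- rep(NA_real_, nrow(win))
  win$proxy_r2 <- rep(NA_real_, nrow(win))
  if (!is.null(outcome) && nrow(win)) {
    flank_lo <- min(target$start) - window_bp - proxy_flank_bp
    flank_hi <- max(target$end) + window_bp + proxy_flank_bp
    cand <- panel$rsid
    if (!is.null(panel$alleles) && "pos" %in% names(panel$alleles)) {
      pos <- panel$alleles$pos
      cand <- panel$rsid[!is.na(pos) & pos >= flank_lo & pos <= flank_hi]
    }
    keep <- rep(TRUE, nrow(win))
    for (i in seq_len(nrow(win))) {
      if (win$rsid[i] %in% outcome$rsid) next
      pr <- find_proxy(win$rsid[i], outcome, panel, r2_min = proxy_r2,
                       candidates = cand)
      if (is.null(pr)) {
        note(win$rsid[i], "proxy",
             sprintf("absent from outcome and no proxy with r2 > %g",
                     proxy_r2))
        keep[i] <- FALSE
      } else {
        win$proxy_of[i] <- win$rsid[i]
        win$proxy_r[i] <- pr$r
        win$proxy_r2[i] <- pr$r2
        win$rsid[i] <- pr$rsid  # substitute; exposure stats stay the index's
      }
    }
    win <- win[keep, , drop = FALSE]
  }

  win$f_stat <- if (nrow(win)) f_statistic(win$beta, win$se) else numeric(0)
  rownames(win) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl)
    else data.frame(rsid = character(0), stage = character(0),
                    reason = character(0))
  mean_f <- if (nrow(win)) mean(win$f_stat) else NA_real_
  structure(list(
    drug_class = drug_class,
    instruments = win,
    mean_f = mean_f,
    weak = isTRUE(mean_f <= 10),
    params = list(window_bp = window_bp, fdr_threshold = fdr_threshold,
                  clump_r2 = clump_r2, palindrome_maf = palindrome_maf,
                  proxy_r2 = proxy_r2, functional_rsid = functional_rsid),
    exclusions = exclusions), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for %s: %d instrument(s)", x$drug_class,
              nrow(x$instruments)))
  if (nrow(x$instruments))
    cat(sprintf(", mean F = %.1f%s", x$mean_f,
                if (x$weak) " [weak]" else ""))
  cat("\n")
  if (nrow(x$instruments))
    print(x$instruments[, c("rsid", "pos", "beta", "se", "pval", "qval",
                            "f_stat", "proxy_of")])
  if (nrow(x$exclusions))
    cat(nrow(x$exclusions), "variant(s) excluded; see $exclusions\n")
  invisible(x)
}
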