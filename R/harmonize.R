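#' Harmonize one exposure/outcome variant pair to a shared effect allele
#'
#' Aligns the outcome record to the exposure record's effect allele. If the
#' outcome's effect/other alleles are swapped relative to the exposure, the
#' outcome beta is negated and its frequency complemented; strand-complement
#' matches (e.g. A/G vs T/C) are resolved before declaring incompatibility.
#' Palindromic pairs (A/T, C/G), for which swap and strand-complement are
#' indistinguishable, are aligned by effect-allele frequency concordance:
#' the orientation minimizing |eaf_x - eaf_y| wins, and the pair is dropped
#' as ambiguous when both frequencies lie in (0.42, 0.58).
#'
#' For proxy pairs (outcome record is a different, high-LD variant) the
#' outcome record is first aligned to the proxy's orientation in the LD panel,
#' then mapped to the index variant through the sign of the panel correlation:
#' negative r swaps the proxy's alleles (negates beta, complements eaf) before
#' adoption.
#'
#' @param exposure one-row exposure record (list/data.frame with the
#'   canonical fields).
#' @param outcome one-row outcome record for the same variant, or for the
#'   proxy variant.
#' @param signed_proxy_r signed LD correlation between index and proxy on the
#'   panel orientation; NULL for a same-variant pair.
#' @param proxy_alleles the proxy variant's panel orientation
#'   (list with `effect_allele`, `other_allele`); required with
#'   `signed_proxy_r`.
#' @param ambiguity_band numeric length-2; palindromic pairs with both
#'   frequencies inside this open band are dropped (default c(0.42, 0.58)).
#' @return one-row data.frame with fields `rsid, effect_allele, other_allele,
#'   beta_x, se_x, eaf_x, beta_y, se_y, eaf_y, flipped, strand_complemented`,
#'   or a `harmonize_drop` object carrying `$reason` when the pair cannot be
#'   harmonized.
#' @export
harmonize_pair <- function(exposure, outcome, signed_proxy_r = NULL,
                           proxy_alleles = NULL,
                           ambiguity_band = c(0.42, 0.58)) {
  drop_with <- function(reason)
    structure(list(reason = reason), class = "harmonize_drop")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ea_x <- exposure$effect_allele; oa_x <- exposure$other_allele
  b_y <- outcome$beta; eaf_y <- outcome$eaf
  ea_y <- outcome$effect_allele; oa_y <- outcome$other_allele
  flipped <- FALSE
  strand_complemented <- FALSE

  # reference orientation the outcome must be aligned to: for a same-variant
  # pair the exposure's alleles; for a proxy pair the proxy's panel alleles
  if (!is.null(signed_proxy_r)) {
    if (is.null(proxy_alleles))
      stop("proxy harmonization needs the proxy's panel allele orientation")
    ref_ea <- proxy_alleles$effect_allele
    ref_oa <- proxy_alleles$other_allele
  } else {
    ref_ea <- ea_x
    ref_oa <- oa_x
  }

  pal <- is_palindromic(ref_ea, ref_oa)
  if (pal && is.null(signed_proxy_r)) {
    # swap and strand flip are indistinguishable: use frequency concordance
    if (is.na(exposure$eaf) || is.na(eaf_y))
      return(drop_with("palindromic pair without frequencies"))
    in_band <- function(f) f > ambiguity_band[1] && f < ambiguity_band[2]
    if (in_band(exposure$eaf) && in_band(eaf_y))
      return(drop_with("palindromic and frequency-ambiguous"))
    if (abs(exposure$eaf - eaf_y) > abs(exposure$eaf - (1 - eaf_y))) {
      b_y <- -b_y; eaf_y <- 1 - eaf_y; flipped <- TRUE
    }
  } else {
    if (ea_y == ref_ea && oa_y == ref_oa) {
      # already aligned
    } else if (ea_y == ref_oa && oa_y == ref_ea) {
      b_y <- -b_y; eaf_y <- 1 - eaf_y; flipped <- TRUE
    } else if (comp[ea_y] == ref_ea && comp[oa_y] == ref_oa) {
      strand_complemented <- TRUE
    } else if (comp[ea_y] == ref_oa && comp[oa_y] == ref_ea) {
      strand_complemented <- TRUE
      b_y <- -b_y; eaf_y <- 1 - eaf_y; flipped <- TRUE
    } else {
      return(drop_with(sprintf("incompatible alleles (%s/%s vs %s/%s)",
                               ref_ea, ref_oa, ea_y, oa_y)))
    }
  }

  if (!is.null(signed_proxy_r)) {
    # proxy now on panel orientation; map to the index's effect allele
    if (signed_proxy_r < 0) {
      b_y <- -b_y
      eaf_y <- if (is.na(eaf_y)) NA_real_ else 1 - eaf_y
      flipped <- !flipped
    }
  }

  data.frame(rsid = exposure$rsid,
             effect_allele = ea_x, other_allele = oa_x,
             beta_x = exposure$beta, se_x = exposure$se, eaf_x = exposure$eaf,
             beta_y = b_y, se_y = outcome$se, eaf_y = eaf_y,
             flipped = flipped, strand_complemented = strand_complemented,
             stringsAsFactors = FALSE)
}

#' Align a selected instrument set against an outcome dataset
#'
#' Applies [harmonize_pair] to every instrument, resolving proxies through
#' the LD panel's recorded allele orientations. Harmonization failures are
#' dropped and logged.
#'
#' @param instruments an `instrument_set` from [select_instruments].
#' @param outcome outcome [sumstats].
#' @param panel [ld_reference] with an allele table (required when proxies
#'   are present).
#' @return An object of class `mr_data`: data.frame of harmonized
#'   instruments (one row each) with `f_stat`, `qval`, `proxy_of`, `proxy_r2`
#'   carried through; attributes `drug_class`, `mean_f`, `exclusions`.
#' @export
align_datasets <- function(instruments, outcome, panel = NULL) {
  ins <- instruments$instruments
  rows <- list()
  excl <- instruments$exclusions
  for (i in seq_len(nrow(ins))) {
    rec <- ins[i, ]
    j <- match(rec$rsid, outcome$rsid)
    if (is.na(j)) {
      excl <- rbind(excl, data.frame(rsid = rec$rsid, stage = "harmonize",
                                     reason = "absent from outcome dataset"))
      next
    }
    proxy_r <- NULL; proxy_alleles <- NULL
    if (!is.na(rec$proxy_of)) {
      if (is.null(panel) || is.null(panel$alleles))
        stop("proxy instruments need an LD panel with allele orientations")
      proxy_r <- rec$proxy_r
      k <- match(rec$rsid, panel$alleles$rsid)
      proxy_alleles <- panel$alleles[k, ]
    }
    h <- harmonize_pair(rec, outcome[j, ], signed_proxy_r = proxy_r,
                        proxy_alleles = proxy_alleles)
    if (inherits(h, "harmonize_drop")) {
      excl <- rbind(excl, data.frame(rsid = rec$rsid, stage = "harmonize",
                                     reason = h$reason))
      next
    }
    h$qval <- rec$qval
    h$f_stat <- rec$f_stat
    h$proxy_of <- rec$proxy_of
    h$proxy_r2 <- rec$proxy_r2
    rows[[length(rows) + 1L]] <- h
  }
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(rsid = character(0), effect_allele = character(0),
                    other_allele = character(0), beta_x = numeric(0),
                    se_x = numeric(0), eaf_x = numeric(0),
                    beta_y = numeric(0), se_y = numeric(0),
                    eaf_y = numeric(0), flipped = logical(0),
                    strand_complemented = logical(0), qval = numeric(0),
                    f_stat = numeric(0), proxy_of = character(0),
                    proxy_r2 = numeric(0))
  rownames(out) <- NULL
  structure(out, class = c("mr_data", "data.frame"),
            drug_class = instruments$drug_class,
            mean_f = if (nrow(out)) mean(out$f_stat) else NA_real_,
            exclusions = excl)
}

#' Swap the allele representation of selected variants in a dataset
#'
#' Rewrites the named variants with effect and other allele exchanged, beta
#' negated and eaf complemented — the same association under the opposite
#' effect-allele orientation. Useful for constructing harmonization test
#' cases and for checking flip-invariance of downstream estimates.
#'
#' @param dataset a [sumstats] object.
#' @param rsids variants to rewrite (default: all).
#' @param strand if TRUE, additionally complement both alleles (A<->T,
#'   C<->G), i.e. report the variant on the opposite strand.
#' @return the modified [sumstats] object.
#' @export
flip_alleles <- function(dataset, rsids = dataset$rsid, strand = FALSE) {
  i <- match(rsids, dataset$rsid)
  if (anyNA(i)) stop("unknown rsid: ", paste(rsids[is.na(i)], collapse = ", "))
  ea <- dataset$effect_allele[i]
  dataset$effect_allele[i] <- dataset$other_allele[i]
  dataset$other_allele[i] <- ea
  dataset$beta[i] <- -dataset$beta[i]
  dataset$eaf[i] <- 1 - dataset$eaf[i]
  if (strand) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    dataset$effect_allele[i] <- comp[dataset$effect_allele[i]]
    dataset$other_allele[i] <- comp[dataset$other_allele[i]]
  }
  dataset
}
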