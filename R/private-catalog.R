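#' Is a single-base substitution a transition?
#'
#' Transitions exchange purines (A<->G) or pyrimidines (C<->T); everything
#' else is a transversion.
#'
#' @param ref,alt single-base character vectors (vectorized), `ref != alt`.
#' @return logical vector, TRUE for transitions.
#' @export
is_transition <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("is_transition is defined for single-base alleles only")
  if (any(ref == alt))
    stop("ref and alt must differ")
  (ref %in% c("A", "G") & alt %in% c("A", "G")) |
    (ref %in% c("C", "T") & alt %in% c("C", "T"))
}

privacy_categories <- c("private_A", "private_B", "shared_exclusive",
                        "known", "unclassifiable")

#' Classify a variant as private, shared or known
#'
#' A variant is *known* when its alternate allele is carried (het or hom) by
#' any strain of the known panel; otherwise it is *private* to the single
#' focal strain homozygous for the alternate allele, *shared exclusively*
#' when both focal strains are, and *unclassifiable* when a genotype needed
#' to decide is missing (or when neither focal strain is homozygous for the
#' allele, which pass-filter input normally precludes).  Multiallelic sites
#' are classified per alternate allele; privacy is a property of the
#' allele, not the site.
#'
#' @param vs a [variant_set] (typically the pass partition of
#'   [filter_all()]).
#' @param panel a [sample_panel]; classification uses its focal strains and
#'   known panel.
#' @return data.frame of class `privacy_calls` with one row per (site, alt
#'   allele): `site` (row index into `vs$sites`), `allele` (1-based alt
#'   index), `alt`, `variant_class`, `category`.
#' @export
classify_variants <- function(vs, panel) {
  stopifnot(inherits(vs, "variant_set"), inherits(panel, "sample_panel"))
  missing_samples <- setdiff(c(panel$focal, panel$known_panel), vs$samples)
  if (length(missing_samples))
    stop("panel sample(s) missing from variant set: ",
         paste(missing_samples, collapse = ", "))
  s <- vs$sites
  alts <- strsplit(s$alt, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  if (nrow(s) && any(n_alt == 0L))
    stop("site without an alternate allele at row ", which(n_alt == 0L)[1L])
  site_idx <- rep(seq_len(nrow(s)), n_alt)
  allele_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  alt_vec <- unlist(alts, use.names = FALSE)
  if (!length(site_idx)) {
    out <- data.frame(site = integer(), allele = integer(),
                      alt = character(), variant_class = character(),
                      category = character())
    return(structure(out, class = c("privacy_calls", "data.frame")))
  }
  focal_gt <- vs$gt[, panel$focal, drop = FALSE]
  panel_gt <- vs$gt[, panel$known_panel, drop = FALSE]
  category <- rep(NA_character_, length(site_idx))
  for (k in unique(allele_idx)) {
    rows <- which(allele_idx == k)
    i <- site_idx[rows]
    ## panel: any carrier -> known; else any missing -> unclassifiable
    if (length(panel$known_panel)) {
      pc <- vapply(panel$known_panel,
                   function(smp) gt_carries(panel_gt[i, smp], k),
                   logical(length(i)))
      pc <- matrix(pc, nrow = length(i))
      panel_hit <- rowSums(pc, na.rm = TRUE) > 0
      panel_miss <- rowSums(is.na(pc)) > 0
    } else {
      panel_hit <- panel_miss <- rep(FALSE, length(i))
    }
    homA <- gt_is_hom_alt(focal_gt[i, 1L], k)
    missA <- gt_is_missing(focal_gt[i, 1L])
    if (length(panel$focal) == 2L) {
      homB <- gt_is_hom_alt(focal_gt[i, 2L], k)
      missB <- gt_is_missing(focal_gt[i, 2L])
    } else {
      homB <- rep(FALSE, length(i)); missB <- rep(FALSE, length(i))
    }
    cat_k <- rep("unclassifiable", length(i))
    cat_k[homA & !homB & !missB] <- "private_A"
    cat_k[!homA & homB & !missA] <- "private_B"
    cat_k[homA & homB] <- if (length(panel$focal) == 2L)
      "shared_exclusive" else "private_A"
    if (length(panel$focal) == 1L) cat_k[homA] <- "private_A"
    cat_k[!panel_hit & panel_miss] <- "unclassifiable"
    cat_k[panel_hit] <- "known"
    category[rows] <- cat_k
  }
  vclass <- ifelse(nchar(s$ref[site_idx]) == 1L & nchar(alt_vec) == 1L,
                   "SNV", "indel")
  out <- data.frame(site = site_idx, allele = allele_idx, alt = alt_vec,
                    variant_class = vclass, category = category,
                    stringsAsFactors = FALSE)
  structure(out, class = c("privacy_calls", "data.frame"))
}

#' Classify one site (single alternate allele)
#'
#' @inheritParams classify_variants
#' @param i site index into `vs`.
#' @param allele 1-based alternate-allele index.
#' @return a single category string (see [classify_variants()]).
#' @export
classify_site <- function(vs, panel, i = 1L, allele = 1L) {
  calls <- classify_variants(vs[i], panel)
  calls$category[calls$allele == allele][1L]
}

#' Summarize a privacy catalog
#'
#' Tabulates calls by category and variant class and computes the
#' transition:transversion ratio over the novel (non-known, classified)
#' biallelic SNVs.
#'
#' @param vs the [variant_set] the calls refer to.
#' @param calls `privacy_calls` from [classify_variants()].
#' @return list of class `catalog_summary`: `counts` (category x
#'   variant-class integer table), `ts_count`, `tv_count`, `ts_tv_ratio`
#'   (`NaN` when no transversions were observed).
#' @export
summarize_catalog <- function(vs, calls) {
  stopifnot(inherits(calls, "privacy_calls"))
  counts <- table(factor(calls$category, levels = privacy_categories),
                  factor(calls$variant_class, levels = c("SNV", "indel")))
  novel <- calls$variant_class == "SNV" &
    !calls$category %in% c("known", "unclassifiable") &
    !vs$sites$multiallelic[calls$site]
  ts <- tv <- 0L
  if (any(novel)) {
    is_ts <- is_transition(vs$sites$ref[calls$site[novel]],
                           calls$alt[novel])
    ts <- sum(is_ts); tv <- sum(!is_ts)
  }
  structure(list(counts = unclass(counts), ts_count = ts, tv_count = tv,
                 ts_tv_ratio = if (tv > 0) ts / tv else NaN),
            class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("catalog_summary\n")
  print(x$counts)
  cat(sprintf("Ts:Tv over novel biallelic SNVs: %d:%d = %s\n",
              x$ts_count, x$tv_count,
              if (is.nan(x$ts_tv_ratio)) "undefined" else
                format(x$ts_tv_ratio, digits = 4)))
  invisible(x)
}
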