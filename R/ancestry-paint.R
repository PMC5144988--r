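#' Polarize sites against the outgroup
#'
#' Classifies each allele as ancestral or derived using the outgroup: the
#' ancestral allele is the outgroup's homozygous allele, the derived allele
#' is the other one (so the reference allele can be the derived one).
#' Sites where the outgroup is heterozygous or missing, and multiallelic or
#' non-SNV sites, are excluded with a reason.  For each retained site the
#' result records whether the focal strain is homozygous for the derived
#' allele and which subspecies representatives carry it.
#'
#' @param vs a [variant_set] of pass-filter candidate sites.
#' @param panel a [sample_panel] naming the representatives and outgroup.
#' @param focal focal sample name (default: first focal strain of the
#'   panel).
#' @return data.frame of class `polarized_sites`, one row per site:
#'   `chrom`, `pos`, `status` (`"ok"` or an exclusion reason among
#'   `non_snv`, `multiallelic`, `outgroup_unresolved`), `derived`
#'   (`"ref"`/`"alt"`), `focal_has_derived` (focal homozygous derived),
#'   `reps_resolved` (all three representative genotypes non-missing) and
#'   logical sharing flags `share_dom`, `share_mus`, `share_cas`.
#' @export
polarize <- function(vs, panel, focal = panel$focal[1L]) {
  stopifnot(inherits(vs, "variant_set"), inherits(panel, "sample_panel"))
  need <- c(focal, unname(panel$representatives), panel$outgroup)
  missing_samples <- setdiff(need, vs$samples)
  if (length(missing_samples))
    stop("sample(s) missing from variant set: ",
         paste(missing_samples, collapse = ", "))
  s <- vs$sites
  n <- nrow(s)
  status <- rep("ok", n)
  status[s$variant_class != "SNV"] <- "non_snv"
  status[s$multiallelic] <- "multiallelic"
  og <- gt_code(vs$gt[, panel$outgroup])
  unresolved <- status == "ok" & og %in% c("het", "missing")
  status[unresolved] <- "outgroup_unresolved"
  derived <- ifelse(og == "hom_ref", "alt",
                    ifelse(og == "hom_alt", "ref", NA))
  derived[status != "ok"] <- NA

  carries_allele <- function(gts, which_allele) {
    m <- gt_allele_matrix(gts)
    k <- ifelse(which_allele == "alt", 1L, 0L)
    out <- m[, 1] == k | m[, 2] == k
    out[is.na(m[, 1]) | is.na(m[, 2])] <- NA
    out
  }
  hom_for_allele <- function(gts, which_allele) {
    m <- gt_allele_matrix(gts)
    k <- ifelse(which_allele == "alt", 1L, 0L)
    !is.na(m[, 1]) & !is.na(m[, 2]) & m[, 1] == k & m[, 2] == k
  }
  focal_has_derived <- hom_for_allele(vs$gt[, focal], derived)
  focal_has_derived[status != "ok"] <- NA
  shares <- sapply(c(dom = "dom", mus = "mus", cas = "cas"), function(ss)
    carries_allele(vs$gt[, panel$representatives[[ss]]], derived),
    simplify = FALSE)
  if (n == 0L)
    shares <- list(dom = logical(), mus = logical(), cas = logical())
  reps_resolved <- !(is.na(shares$dom) | is.na(shares$mus) |
                       is.na(shares$cas))
  reps_resolved[status != "ok"] <- NA
  out <- data.frame(chrom = s$chrom, pos = s$pos, status = status,
                    derived = derived,
                    focal_has_derived = focal_has_derived,
                    reps_resolved = reps_resolved,
                    share_dom = shares$dom, share_mus = shares$mus,
                    share_cas = shares$cas, stringsAsFactors = FALSE)
  structure(out, class = c("polarized_sites", "data.frame"))
}

#' Exclusive derived-allele sharing
#'
#' For sites where the focal strain is homozygous derived and all three
#' representative genotypes are resolved, returns the subspecies whose
#' representative is the *only* one carrying the derived allele, or
#' `"none"` when zero, two or three representatives carry it.  Sites that
#' do not qualify (excluded, focal not homozygous derived, or a
#' representative genotype missing) return `NA`.
#'
#' @param pol `polarized_sites` from [polarize()].
#' @return character vector per site: `"dom"`, `"mus"`, `"cas"`, `"none"`
#'   or `NA`.
#' @export
exclusive_sharing <- function(pol) {
  stopifnot(inherits(pol, "polarized_sites"))
  eligible <- pol$status == "ok" & pol$focal_has_derived %in% TRUE &
    pol$reps_resolved %in% TRUE
  nshare <- pol$share_dom + pol$share_mus + pol$share_cas
  out <- rep(NA_character_, nrow(pol))
  out[eligible & nshare != 1] <- "none"
  one <- eligible & nshare == 1
  out[one & pol$share_dom] <- "dom"
  out[one & pol$share_mus] <- "mus"
  out[one & pol$share_cas] <- "cas"
  out
}

ancestry_labels <- c("dom", "mus", "cas", "uninformative", "masked",
                     "ambiguous")

#' Paint genome windows with subspecies ancestry
#'
#' Tallies exclusive derived-allele sharing per fixed-width window and
#' assigns each window an ancestry label: `masked` when the masked fraction
#' of the window exceeds `mask_threshold`; `uninformative` when fewer than
#' `min_sites` sites show exclusive sharing; otherwise the subspecies with
#' the largest count, with ties labelled `ambiguous`.  Only sites where the
#' focal strain is homozygous for the derived allele contribute to counts;
#' sites with an unresolved outgroup or missing representative genotypes
#' are excluded (never imputed) and tracked in the bookkeeping columns.
#'
#' @param vs a [variant_set] of pass-filter sites on windowed chromosomes,
#'   sorted by (chromosome, position).
#' @param windows `GRanges` of windows from [make_windows()].
#' @param mask normalized `GRanges` mask track (possibly empty).
#' @param panel a [sample_panel].
#' @param focal focal sample name (default: first focal strain).
#' @param min_sites minimum exclusive-sharing sites for an informative
#'   window (default 10).
#' @param mask_threshold masked-fraction above which a window is dropped as
#'   masked (default 0.5, strict).
#' @return data.frame of class `ancestry_windows`, one row per window:
#'   coordinates (`chrom`, `start`, `end`; 0-based half-open), counts
#'   `n_dom`, `n_mus`, `n_cas`, bookkeeping columns `n_sites`,
#'   `n_excluded`, `n_nonderived`, `n_rep_missing`, `n_nonexclusive`,
#'   `n_informative`, `mask_frac` and the window `label`.
#' @export
paint_windows <- function(vs, windows, mask = GenomicRanges::GRanges(),
                          panel, focal = panel$focal[1L],
                          min_sites = 10, mask_threshold = 0.5) {
  stopifnot(inherits(vs, "variant_set"))
  windows <- methods::as(windows, "GRanges")
  pol <- polarize(vs, panel, focal)
  n_win <- length(windows)
  if (nrow(pol)) {
    site_gr <- GenomicRanges::GRanges(pol$chrom,
                                      IRanges::IRanges(pol$pos, pol$pos))
    hits <- GenomicRanges::findOverlaps(site_gr, windows,
                                        ignore.strand = TRUE)
    win_of <- rep(NA_integer_, nrow(pol))
    win_of[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
    if (anyNA(win_of)) {
      j <- which(is.na(win_of))[1L]
      stop(sprintf("site outside all windows: %s:%d (coordinate mismatch?)",
                   pol$chrom[j], pol$pos[j]))
    }
  } else win_of <- integer()

  tab <- function(cond) tabulate(win_of[cond], nbins = n_win)
  excl <- pol$status != "ok"
  nonderived <- pol$status == "ok" & !pol$focal_has_derived
  rep_missing <- pol$status == "ok" & pol$focal_has_derived &
    !pol$reps_resolved
  sharing <- exclusive_sharing(pol)
  out <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(windows)),
    start = GenomicRanges::start(windows) - 1L,
    end = GenomicRanges::end(windows),
    n_sites = tabulate(win_of, nbins = n_win),
    n_excluded = tab(excl),
    n_nonderived = tab(nonderived),
    n_rep_missing = tab(rep_missing),
    n_nonexclusive = tab(!is.na(sharing) & sharing == "none"),
    n_dom = tab(!is.na(sharing) & sharing == "dom"),
    n_mus = tab(!is.na(sharing) & sharing == "mus"),
    n_cas = tab(!is.na(sharing) & sharing == "cas"),
    stringsAsFactors = FALSE)
  out$n_informative <- out$n_dom + out$n_mus + out$n_cas
  out$mask_frac <- mask_overlap_fraction(windows, mask)

  counts <- as.matrix(out[, c("n_dom", "n_mus", "n_cas")])
  top <- apply(counts, 1, max)
  n_top <- rowSums(counts == top)
  label <- c("dom", "mus", "cas")[max.col(counts, ties.method = "first")]
  label[n_top > 1] <- "ambiguous"
  label[out$n_informative < min_sites] <- "uninformative"
  masked <- out$mask_frac > mask_threshold
  label[masked] <- "masked"
  ## masked windows carry no counts
  zero_cols <- c("n_dom", "n_mus", "n_cas", "n_informative")
  out[masked, zero_cols] <- 0L
  out$label <- label
  structure(out, class = c("ancestry_windows", "data.frame"),
            min_sites = min_sites, mask_threshold = mask_threshold,
            focal = focal)
}

#' Summarize painted windows into genome fractions
#'
#' Fractions per ancestry label over the analyzed (non-masked) windows.
#' Because the last window of a chromosome is truncated, a base-pair
#' (length-weighted) fraction is reported alongside the plain window
#' fraction.  As the genome-composition estimate, the per-ancestry
#' fraction among the ancestry-labelled windows only (`dom`/`mus`/`cas`,
#' excluding windows that carry no signal) is reported as
#' `fraction_informative`.
#'
#' @param aw `ancestry_windows` from [paint_windows()].
#' @return list of class `ancestry_summary`: `fraction` and
#'   `fraction_weighted` (named vectors over labels except `masked`,
#'   summing to 1), `fraction_informative` (over `dom`/`mus`/`cas` only),
#'   `n_windows` per label, `masked_fraction`, `n_analyzed`.
#' @export
summarize_ancestry <- function(aw) {
  stopifnot(inherits(aw, "ancestry_windows"))
  analyzed <- aw$label != "masked"
  if (!any(analyzed))
    stop("no analyzed windows: every window is masked")
  labs <- setdiff(ancestry_labels, "masked")
  lab <- factor(aw$label[analyzed], levels = labs)
  n <- table(lab)
  w <- tapply((aw$end - aw$start)[analyzed], lab, sum, default = 0)
  anc <- c("dom", "mus", "cas")
  n_anc <- as.numeric(n[anc])
  structure(list(fraction = stats::setNames(as.numeric(n) / sum(n), labs),
                 fraction_weighted = stats::setNames(
                   as.numeric(w) / sum(w), labs),
                 fraction_informative = stats::setNames(
                   if (sum(n_anc) > 0) n_anc / sum(n_anc) else
                     rep(NaN, 3), anc),
                 n_windows = stats::setNames(as.integer(n), labs),
                 masked_fraction = mean(!analyzed),
                 n_analyzed = sum(analyzed)),
            class = "ancestry_summary")
}

#' @export
print.ancestry_summary <- function(x, ...) {
  cat(sprintf("ancestry_summary: %d analyzed window(s), %.1f%% masked\n",
              x$n_analyzed, 100 * x$masked_fraction))
  for (l in names(x$fraction))
    if (x$n_windows[[l]] > 0)
      cat(sprintf("  %-14s %6d windows  %6.2f%% (bp-weighted %6.2f%%)\n",
                  l, x$n_windows[[l]], 100 * x$fraction[[l]],
                  100 * x$fraction_weighted[[l]]))
  invisible(x)
}

#' Write painted windows as BED4
#' @param aw `ancestry_windows`.
#' @param path output BED path (label in the name column).
#' @return `path`, invisibly.
#' @export
write_ancestry_bed <- function(aw, path) {
  stopifnot(inherits(aw, "ancestry_windows"))
  utils::write.table(aw[, c("chrom", "start", "end", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
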