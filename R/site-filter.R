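#' Hard-filter configuration
#'
#' Thresholds for the candidate-variant hard filters.  All comparisons are
#' strict, mirroring the conventional "> / <" notation: a nuclear site
#' passes the depth rule only when `depth_min < DP < depth_max`, a
#' mitochondrial site only when `DP > mito_depth_min` (high-copy mtDNA has
#' no upper bound), mapping quality must exceed `mq_min`, alternate-allele
#' read support must exceed `alt_support_min`, and an SNV must lie more than
#' `indel_distance_min` bp from the nearest indel.  With
#' `require_homozygous` the focal genotype must be homozygous (heterozygous
#' or missing genotypes fail).
#'
#' @param nuclear_depth_min,nuclear_depth_max exclusive read-depth bounds
#'   for nuclear sites (defaults 5 and 100).
#' @param mito_depth_min exclusive minimum depth for mitochondrial sites
#'   (default 350).
#' @param mq_min exclusive minimum site mapping quality (default 20).
#' @param alt_support_min exclusive minimum alternate-supporting read count
#'   (default 5).
#' @param indel_distance_min exclusive minimum distance of an SNV to the
#'   nearest indel, in bp (default 2; indels are exempt).
#' @param require_homozygous require the focal genotype to be homozygous
#'   (default TRUE).
#' @return a `filter_config` list.
#' @export
filter_config <- function(nuclear_depth_min = 5, nuclear_depth_max = 100,
                          mito_depth_min = 350, mq_min = 20,
                          alt_support_min = 5, indel_distance_min = 2,
                          require_homozygous = TRUE) {
  cfg <- list(nuclear_depth_min = nuclear_depth_min,
              nuclear_depth_max = nuclear_depth_max,
              mito_depth_min = mito_depth_min,
              mq_min = mq_min,
              alt_support_min = alt_support_min,
              indel_distance_min = indel_distance_min,
              require_homozygous = isTRUE(require_homozygous))
  num <- unlist(cfg[1:6])
  if (any(!is.finite(num)) || any(num < 0))
    stop("filter thresholds must be finite and >= 0")
  if (nuclear_depth_min >= nuclear_depth_max)
    stop("nuclear_depth_min must be below nuclear_depth_max")
  structure(cfg, class = "filter_config")
}

#' Annotate SNVs with the distance to the nearest indel
#'
#' For each SNV, the distance in bp to the nearest indel anchor position on
#' the same chromosome (absolute difference of VCF POS values).  SNVs on
#' chromosomes without any indel get `Inf`, so the proximity filter can
#' never fire for them.  Sites must be sorted by (chromosome, position).
#'
#' @param vs a [variant_set] sorted by chromosome then position.
#' @return `vs` with an `indel_dist` column added to its site table
#'   (`NA` for indel sites themselves).
#' @export
annotate_indel_distance <- function(vs) {
  stopifnot(inherits(vs, "variant_set"))
  s <- vs$sites
  if (nrow(s) > 1) {
    ## chromosomes must form contiguous blocks, positions sorted within each
    runs <- rle(s$chrom)
    if (anyDuplicated(runs$values) ||
        any(tapply(s$pos, factor(s$chrom, levels = runs$values), is.unsorted)))
      stop("sites must be sorted by (chromosome, position)")
  }
  dist <- rep(NA_real_, nrow(s))
  for (chrom in unique(s$chrom)) {
    idx <- which(s$chrom == chrom)
    is_snv <- s$variant_class[idx] == "SNV"
    ipos <- s$pos[idx][!is_snv]
    spos <- s$pos[idx][is_snv]
    if (!length(spos)) next
    if (!length(ipos)) {
      dist[idx[is_snv]] <- Inf
      next
    }
    ipos <- sort(ipos)
    j <- findInterval(spos, ipos)
    left <- ifelse(j >= 1, spos - ipos[pmax(j, 1L)], Inf)
    right <- ifelse(j < length(ipos), ipos[pmin(j + 1L, length(ipos))] - spos,
                    Inf)
    dist[idx[is_snv]] <- pmin(left, right)
  }
  vs$sites$indel_dist <- dist
  vs
}

filter_reasons <- c("LOW_DP", "HIGH_DP", "LOW_MQ", "LOW_ALT_SUPPORT",
                    "NEAR_INDEL", "NOT_HOMOZYGOUS", "MISSING_STAT")

## Vectorized verdicts: logical matrix sites x reasons
filter_verdict_matrix <- function(vs, config, layout, focal) {
  s <- vs$sites
  n <- nrow(s)
  m <- matrix(FALSE, n, length(filter_reasons),
              dimnames = list(NULL, filter_reasons))
  if (n == 0L) return(m)
  kind <- chromosome_kind(layout, s$chrom)
  mito <- kind == "mitochondrial"

  m[, "MISSING_STAT"] <- is.na(s$dp) | is.na(s$mq) | is.na(s$alt_support)
  m[, "LOW_DP"] <- !is.na(s$dp) &
    ifelse(mito, s$dp <= config$mito_depth_min,
           s$dp <= config$nuclear_depth_min)
  m[, "HIGH_DP"] <- !is.na(s$dp) & !mito & s$dp >= config$nuclear_depth_max
  m[, "LOW_MQ"] <- !is.na(s$mq) & s$mq <= config$mq_min
  m[, "LOW_ALT_SUPPORT"] <- !is.na(s$alt_support) &
    s$alt_support <= config$alt_support_min
  is_snv <- s$variant_class == "SNV"
  dist <- if (!is.null(s$indel_dist)) s$indel_dist else rep(Inf, n)
  m[, "NEAR_INDEL"] <- is_snv & !is.na(dist) &
    dist <= config$indel_distance_min
  if (config$require_homozygous) {
    if (!focal %in% vs$samples)
      stop("focal sample not in variant set: ", focal)
    code <- gt_code(vs$gt[, focal])
    m[, "NOT_HOMOZYGOUS"] <- code %in% c("het", "missing")
  }
  m
}

#' Filter one site
#'
#' Scalar convenience around the vectorized filter: applies every hard
#' filter to a single site and returns the verdict with its reason codes.
#'
#' @param vs a [variant_set]; the first site is used if `i` is not given.
#' @param config a [filter_config].
#' @param layout a [genome_layout] (selects the nuclear or mitochondrial
#'   depth rule per chromosome).
#' @param focal focal sample name for the homozygosity rule.
#' @param i site index (default 1).
#' @return list with `passed` (logical) and `reasons` (character vector of
#'   reason codes, empty iff passed).
#' @export
filter_site <- function(vs, config, layout, focal, i = 1L) {
  m <- filter_verdict_matrix(vs[i], config, layout, focal)
  reasons <- filter_reasons[m[1L, ]]
  list(passed = length(reasons) == 0L, reasons = reasons)
}

#' Apply the hard filters to every site
#'
#' Partitions a variant set into passing and failing sites and tallies each
#' failure reason independently (one site may count toward several
#' reasons).  If the site table lacks the `indel_dist` column it is
#' computed first via [annotate_indel_distance()].
#'
#' @inheritParams filter_site
#' @param vs a [variant_set] sorted by (chromosome, position).
#' @return list of class `filter_result` with elements `pass` and `fail`
#'   (variant sets), `filter` (per-site FILTER strings, `"PASS"` or
#'   semicolon-joined reason codes), `verdicts` (logical site x reason
#'   matrix) and `summary` (named integer counts per reason plus `PASS` and
#'   `TOTAL`).
#' @export
filter_all <- function(vs, config = filter_config(), layout, focal) {
  stopifnot(inherits(vs, "variant_set"), inherits(config, "filter_config"))
  if (is.null(vs$sites$indel_dist))
    vs <- annotate_indel_distance(vs)
  m <- filter_verdict_matrix(vs, config, layout, focal)
  passed <- rowSums(m) == 0L
  filt <- vapply(seq_len(nrow(m)), function(i)
    if (passed[i]) "PASS" else
      paste(filter_reasons[m[i, ]], collapse = ";"), character(1))
  vs$sites$filter <- filt
  summary <- c(colSums(m), PASS = sum(passed), TOTAL = length(passed))
  structure(list(pass = vs[passed], fail = vs[!passed], filter = filt,
                 verdicts = m, summary = summary),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("filter_result: %d/%d site(s) pass\n",
              x$summary[["PASS"]], x$summary[["TOTAL"]]))
  fails <- x$summary[filter_reasons]
  fails <- fails[fails > 0]
  if (length(fails))
    for (r in names(fails)) cat(sprintf("  %-16s %d\n", r, fails[[r]]))
  invisible(x)
}
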