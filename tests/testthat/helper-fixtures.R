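# Shared fixtures: tiny layouts, hand-built variant sets, and randomized
# site generators used by the oracle-equivalence tests.

tiny_layout <- function() {
  genome_layout(c("chr1", "chr2", "chrX", "chrM"),
                c(1e6, 8e5, 6e5, 16299),
                c("autosome", "autosome", "X", "mitochondrial"),
                rb_chromosomes = "chr1",
                centromere_width = 2e5)
}

default_samples <- c("focal_A", "focal_B", "rep_dom", "rep_mus", "rep_cas",
                     "outgroup", "known_1", "known_2", "known_3")

default_panel <- function() {
  sample_panel(focal = c("focal_A", "focal_B"),
               representatives = c(dom = "rep_dom", mus = "rep_mus",
                                   cas = "rep_cas"),
               outgroup = "outgroup",
               known_panel = c("known_1", "known_2", "known_3"))
}

# Build a variant_set from parallel vectors; unspecified genotypes are 0/0.
make_sites <- function(chrom, pos, ref = "A", alt = "G", dp = 50, mq = 40,
                       alt_support = 20, gt = NULL,
                       samples = default_samples) {
  n <- length(pos)
  sites <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                      ref = rep_len(ref, n), alt = rep_len(alt, n),
                      dp = rep_len(dp, n), mq = rep_len(mq, n),
                      alt_support = rep_len(alt_support, n),
                      stringsAsFactors = FALSE)
  if (is.null(gt)) {
    gt <- matrix("0/0", n, length(samples),
                 dimnames = list(NULL, samples))
    gt[, "focal_A"] <- "1/1"
  }
  variant_set(sites, gt)
}

# Randomized sites spanning all filter-threshold boundaries, on the tiny
# layout's chromosomes (including chrM), with occasional missing stats.
random_filter_sites <- function(n, seed) {
  set.seed(seed)
  chrom <- sort(sample(c("chr1", "chr2", "chrM"), n, replace = TRUE,
                       prob = c(0.45, 0.45, 0.1)))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(i)
    sort(sample.int(15000, length(i)))), use.names = FALSE)
  is_indel <- runif(n) < 0.25
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- ifelse(ref == "A", "G", "A")
  alt[is_indel] <- paste0(ref[is_indel], "CT")
  # depths concentrated around every boundary (5, 100, 350)
  dp <- sample(c(0:8, 95:105, 340:360, 20, 50, 400), n, replace = TRUE)
  mq <- sample(c(0, 10, 19.5, 20, 20.5, 30, 60), n, replace = TRUE)
  alt_support <- pmin(sample(c(0:8, 20, 50), n, replace = TRUE), dp)
  dp[runif(n) < 0.05] <- NA
  mq[runif(n) < 0.05] <- NA
  alt_support[runif(n) < 0.05] <- NA
  gt <- matrix("0/0", n, length(default_samples),
               dimnames = list(NULL, default_samples))
  gt[, "focal_A"] <- sample(c("1/1", "0/0", "0/1", "./."), n,
                            replace = TRUE, prob = c(0.6, 0.1, 0.2, 0.1))
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      dp = dp, mq = mq, alt_support = alt_support,
                      stringsAsFactors = FALSE)
  variant_set(sites, gt)
}

# Straight-line per-site reference for the hard filters; written
# independently of the vectorized implementation.
oracle_filter_verdict <- function(kind, variant_class, dp, mq, alt_support,
                                  indel_dist, focal_code,
                                  cfg = filter_config()) {
  reasons <- character()
  if (is.na(dp) || is.na(mq) || is.na(alt_support))
    reasons <- c(reasons, "MISSING_STAT")
  if (!is.na(dp)) {
    if (kind == "mitochondrial") {
      if (!(dp > cfg$mito_depth_min)) reasons <- c(reasons, "LOW_DP")
    } else {
      if (!(dp > cfg$nuclear_depth_min)) reasons <- c(reasons, "LOW_DP")
      if (!(dp < cfg$nuclear_depth_max)) reasons <- c(reasons, "HIGH_DP")
    }
  }
  if (!is.na(mq) && !(mq > cfg$mq_min)) reasons <- c(reasons, "LOW_MQ")
  if (!is.na(alt_support) && !(alt_support > cfg$alt_support_min))
    reasons <- c(reasons, "LOW_ALT_SUPPORT")
  if (variant_class == "SNV" && !is.na(indel_dist) &&
      !(indel_dist > cfg$indel_distance_min))
    reasons <- c(reasons, "NEAR_INDEL")
  if (cfg$require_homozygous && focal_code %in% c("het", "missing"))
    reasons <- c(reasons, "NOT_HOMOZYGOUS")
  reasons
}

# Truth-table reference for privacy classification, quantifier-based.
oracle_classify <- function(gA, gB, panel_gts) {
  carries <- function(g) if (g == "./.") NA else g %in% c("0/1", "1/1")
  hom_alt <- function(g) g == "1/1"
  pc <- vapply(panel_gts, carries, logical(1))
  if (any(pc, na.rm = TRUE)) return("known")
  if (anyNA(pc)) return("unclassifiable")
  if (hom_alt(gA) && hom_alt(gB)) return("shared_exclusive")
  if (hom_alt(gA)) return(if (gB == "./.") "unclassifiable" else "private_A")
  if (hom_alt(gB)) return(if (gA == "./.") "unclassifiable" else "private_B")
  "unclassifiable"
}

# One-row-per-window brute-force painter used as the paint oracle.
oracle_paint <- function(vs, windows_df, mask_df, panel, focal,
                         min_sites = 10, mask_threshold = 0.5) {
  out <- windows_df
  out$n_dom <- out$n_mus <- out$n_cas <- 0L
  out$label <- "uninformative"
  for (w in seq_len(nrow(out))) {
    lo <- out$start[w]; hi <- out$end[w]  # 0-based half-open
    masked_bases <- 0
    for (m in seq_len(nrow(mask_df))) {
      if (mask_df$chrom[m] != out$chrom[w]) next
      masked_bases <- masked_bases +
        max(0, min(hi, mask_df$end[m]) - max(lo, mask_df$start[m]))
    }
    if (masked_bases / (hi - lo) > mask_threshold) {
      out$label[w] <- "masked"
      next
    }
    counts <- c(dom = 0L, mus = 0L, cas = 0L)
    for (i in seq_len(n_sites(vs))) {
      s <- vs$sites[i, ]
      if (s$chrom != out$chrom[w] || s$pos <= lo || s$pos > hi) next
      if (s$variant_class != "SNV" || s$multiallelic) next
      og <- vs$gt[i, panel$outgroup]
      if (!og %in% c("0/0", "1/1")) next
      derived <- if (og == "0/0") "1" else "0"
      hom_derived <- paste0(derived, "/", derived)
      if (vs$gt[i, focal] != hom_derived) next
      rg <- vs$gt[i, unname(panel$representatives)]
      if (any(rg == "./.")) next
      carry <- vapply(rg, function(g)
        derived %in% strsplit(sub(":.*", "", g), "[/|]")[[1]], logical(1))
      if (sum(carry) == 1)
        counts[names(panel$representatives)[which(carry)]] <-
          counts[names(panel$representatives)[which(carry)]] + 1L
    }
    out$n_dom[w] <- counts[["dom"]]
    out$n_mus[w] <- counts[["mus"]]
    out$n_cas[w] <- counts[["cas"]]
    if (sum(counts) >= min_sites) {
      top <- names(counts)[counts == max(counts)]
      out$label[w] <- if (length(top) == 1) top else "ambiguous"
    }
  }
  out
}
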