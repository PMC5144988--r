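#' Compact genome layout for simulations
#'
#' A small genome with the structural features the pipeline cares about:
#' several autosomes, an X chromosome and a mitochondrial genome, with the
#' first autosomes designated Rb-fusion chromosomes.
#'
#' @param n_autosomes number of autosomes (default 3).
#' @param autosome_length autosome length in bp (default 20 Mb).
#' @param x_length X-chromosome length (default 10 Mb; 0 to omit).
#' @param mito_length mitochondrial genome length (default 16,299 bp, the
#'   mouse mtDNA size; 0 to omit).
#' @param n_rb how many autosomes carry Rb fusions (default 2).
#' @param centromere_width centromere-proximal interval width (default
#'   5 Mb).
#' @return a [genome_layout].
#' @export
sim_layout <- function(n_autosomes = 3, autosome_length = 20e6,
                       x_length = 10e6, mito_length = 16299,
                       n_rb = min(2, n_autosomes),
                       centromere_width = 5e6) {
  stopifnot(n_autosomes >= 1, n_rb <= n_autosomes)
  nm <- paste0("chr", seq_len(n_autosomes))
  len <- rep(autosome_length, n_autosomes)
  kind <- rep("autosome", n_autosomes)
  if (x_length > 0) {
    nm <- c(nm, "chrX"); len <- c(len, x_length); kind <- c(kind, "X")
  }
  if (mito_length > 0) {
    nm <- c(nm, "chrM"); len <- c(len, mito_length)
    kind <- c(kind, "mitochondrial")
  }
  genome_layout(nm, len, kind, rb_chromosomes = utils::head(
    paste0("chr", seq_len(n_autosomes)), n_rb),
    centromere_width = centromere_width)
}

#' Simulation configuration
#'
#' Everything the generator needs to emit a variant panel with a known
#' ancestry mosaic and privacy categories plus depth tracks with known sex
#' and injected copy-number events.  Defaults reflect a wild-derived
#' *M. m. domesticus* strain sequenced to moderate coverage: one candidate
#' SNV per 500 bp, 18x mean autosomal depth, a mosaic that is
#' predominantly *domesticus* with a minor *musculus* component, and
#' mega-base-scale ancestry segments.
#'
#' @param layout a [genome_layout]; default [sim_layout()].
#' @param seed integer seed; all generator randomness derives from it
#'   (per-component streams use fixed offsets, so adding a component never
#'   perturbs earlier streams).
#' @param snv_density candidate sites per bp (default 1/500).
#' @param p_polarizable probability the outgroup resolves a site
#'   (default 0.9).
#' @param p_exclusive_correct probability a derived allele inside a segment
#'   of ancestry *s* is shared exclusively with representative *s*
#'   (default 0.8).
#' @param p_noise_share probability of exclusive sharing with a wrong
#'   representative, emulating incomplete lineage sorting and homoplasy
#'   (default 0.05).
#' @param mosaic_spec named numeric vector of target ancestry fractions
#'   over `dom`/`mus`/`cas`, summing to 1 (default
#'   `c(dom = 0.92, mus = 0.08)`).
#' @param segment_length_mean mean ancestry-segment length in bp
#'   (default 1 Mb).
#' @param depth_mean mean autosomal read depth (default 18).
#' @param depth_dispersion dispersion (gamma shape) of windowed mean depth:
#'   window means are drawn from the gamma mixing density of a negative
#'   binomial with this shape, so their coefficient of variation is
#'   `1/sqrt(depth_dispersion)` (default 200, CV about 7%, the tight
#'   spread expected of 25-kb window means).
#' @param mito_depth_mean mean mitochondrial depth (default 1000).
#' @param cnv_spec optional data.frame `chrom`, `start`, `end` (0-based
#'   half-open), `ratio` of copy-ratio perturbations for the focal depth
#'   track; intervals must not overlap.
#' @param sex `"male"` or `"female"` (default female).
#' @param privacy_spec named numeric proportions over `private_A`,
#'   `private_B`, `shared_exclusive`, `known` (default roughly the shape
#'   seen for a pair of newly sequenced strains: 0.35/0.45/0.10/0.10).
#' @param p_pass fraction of sites whose statistics satisfy the hard
#'   filters (default 0.9).
#' @param p_transition probability a simulated SNV is a transition
#'   (default 0.68, giving Ts:Tv near 2.1).
#' @param indel_fraction fraction of sites simulated as short insertions
#'   (< 10 bp; default 0.1).
#' @param window_width depth/ancestry window width in bp (default 25,000).
#' @param n_known_panel number of known-catalog strains (default 3).
#' @param n_depth_panel number of comparison depth tracks (default 2).
#' @return a `sim_config` list.
#' @export
sim_config <- function(layout = sim_layout(), seed = 1,
                       snv_density = 1 / 500, p_polarizable = 0.9,
                       p_exclusive_correct = 0.8, p_noise_share = 0.05,
                       mosaic_spec = c(dom = 0.92, mus = 0.08),
                       segment_length_mean = 1e6, depth_mean = 18,
                       depth_dispersion = 200, mito_depth_mean = 1000,
                       cnv_spec = NULL, sex = c("female", "male"),
                       privacy_spec = c(private_A = 0.35, private_B = 0.45,
                                        shared_exclusive = 0.10,
                                        known = 0.10),
                       p_pass = 0.9, p_transition = 0.68,
                       indel_fraction = 0.1, window_width = 25000,
                       n_known_panel = 3, n_depth_panel = 2) {
  stopifnot(inherits(layout, "genome_layout"))
  sex <- match.arg(sex)
  probs <- c(p_polarizable, p_exclusive_correct, p_noise_share, p_pass,
             p_transition, indel_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (p_exclusive_correct + p_noise_share > 1)
    stop("p_exclusive_correct + p_noise_share must not exceed 1")
  if (snv_density <= 0) stop("snv_density must be positive")
  full <- c(dom = 0, mus = 0, cas = 0)
  if (!all(names(mosaic_spec) %in% names(full)))
    stop("mosaic_spec names must be among dom, mus, cas")
  full[names(mosaic_spec)] <- mosaic_spec
  if (abs(sum(full) - 1) > 1e-8) stop("mosaic fractions must sum to 1")
  if (abs(sum(privacy_spec) - 1) > 1e-8)
    stop("privacy_spec proportions must sum to 1")
  if (!is.null(cnv_spec)) {
    cnv_spec <- as.data.frame(cnv_spec)
    stopifnot(all(c("chrom", "start", "end", "ratio") %in% names(cnv_spec)))
    gr <- GenomicRanges::GRanges(cnv_spec$chrom,
                                 IRanges::IRanges(cnv_spec$start + 1,
                                                  cnv_spec$end))
    if (length(gr) > 1 &&
        sum(GenomicRanges::countOverlaps(gr, gr)) > length(gr))
      stop("cnv_spec intervals must not overlap")
  }
  structure(list(layout = layout, seed = as.integer(seed),
                 snv_density = snv_density, p_polarizable = p_polarizable,
                 p_exclusive_correct = p_exclusive_correct,
                 p_noise_share = p_noise_share, mosaic_spec = full,
                 segment_length_mean = segment_length_mean,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 mito_depth_mean = mito_depth_mean, cnv_spec = cnv_spec,
                 sex = sex, privacy_spec = privacy_spec, p_pass = p_pass,
                 p_transition = p_transition,
                 indel_fraction = indel_fraction,
                 window_width = window_width,
                 n_known_panel = as.integer(n_known_panel),
                 n_depth_panel = as.integer(n_depth_panel)),
            class = "sim_config")
}

#' Sample panel used by the generator
#' @param config a [sim_config].
#' @return the [sample_panel] matching simulated sample names.
#' @export
sim_panel <- function(config) {
  sample_panel(focal = c("focal_A", "focal_B"),
               representatives = c(dom = "rep_dom", mus = "rep_mus",
                                   cas = "rep_cas"),
               outgroup = "outgroup",
               known_panel = if (config$n_known_panel > 0)
                 paste0("known_", seq_len(config$n_known_panel)) else
                   character())
}

## Seed-stream offsets: each component consumes an independent stream so
## adding one never perturbs the others.
.seed_mosaic <- 101L
.seed_variants <- 202L
.seed_depth <- 303L

#' Simulate an ancestry mosaic
#'
#' Draws alternating segments with exponentially distributed lengths (mean
#' `segment_length_mean`) along every non-mitochondrial chromosome,
#' assigning each segment an ancestry by the `mosaic_spec` weights;
#' consecutive same-ancestry segments are merged, so the result partitions
#' each chromosome into maximal uniform-ancestry segments.  Deterministic
#' given the seed.
#'
#' @param config a [sim_config].
#' @return `GRanges` with metadata column `ancestry`.
#' @export
simulate_mosaic <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .seed_mosaic)
  sl <- layout_seqlengths(config$layout, c("autosome", "X"))
  if (sum(sl) < config$segment_length_mean)
    warning("genome shorter than one expected segment; ",
            "single segments emitted")
  anc_names <- names(config$mosaic_spec)
  ## quota-depletion sampling: each ancestry owns a base quota equal to its
  ## target fraction of the genome; a segment's ancestry is drawn with
  ## probability proportional to the remaining quota, so realized fractions
  ## self-correct to the targets (deviation is at most of the order of one
  ## segment length over the genome length)
  remaining <- config$mosaic_spec * sum(sl)
  out <- list()
  for (chrom in names(sl)) {
    len <- sl[[chrom]]
    pos <- 0
    starts <- ends <- numeric(0)
    anc <- character(0)
    while (pos < len) {
      p <- pmax(remaining, 0)
      if (sum(p) == 0) p <- config$mosaic_spec
      a <- sample(anc_names, 1L, prob = p)
      w <- ceiling(stats::rexp(1, rate = 1 / config$segment_length_mean))
      if (remaining[a] > 0) w <- min(w, ceiling(remaining[a]))
      w <- max(1, min(w, len - pos))
      starts <- c(starts, pos + 1)
      ends <- c(ends, pos + w)
      anc <- c(anc, a)
      remaining[a] <- remaining[a] - w
      pos <- pos + w
    }
    ## merge consecutive same-ancestry segments
    r <- rle(anc)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    out[[chrom]] <- data.frame(chrom = chrom, start = starts[lo],
                               end = ends[hi], ancestry = r$values,
                               stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr)$ancestry <- df$ancestry
  gr
}

#' Realized base fractions of an ancestry mosaic
#' @param segments `GRanges` from [simulate_mosaic()].
#' @return named numeric vector of per-ancestry base fractions.
#' @export
ancestry_fractions <- function(segments) {
  w <- tapply(GenomicRanges::width(segments),
              S4Vectors::mcols(segments)$ancestry, sum)
  stats::setNames(as.numeric(w) / sum(w), names(w))
}

#' Simulate a variant panel over a known mosaic
#'
#' Places candidate sites by a Poisson process at `snv_density`, then draws
#' per-site genotypes and statistics so that every downstream truth is
#' known: the outgroup is homozygous ancestral (the reference allele) with
#' probability `p_polarizable` and heterozygous otherwise; inside a segment
#' of ancestry *s* the derived allele is carried exclusively by
#' representative *s* with probability `p_exclusive_correct`, exclusively
#' by a wrong representative with `p_noise_share`, and otherwise by zero or
#' two representatives; privacy categories are assigned by `privacy_spec`
#' through the focal and known-panel genotypes; and site statistics (DP,
#' MQ, alt support) are drawn so that a `p_pass` fraction satisfies the
#' hard filters, with the remainder failing one randomly chosen rule.
#'
#' @param config a [sim_config].
#' @param segments ancestry mosaic from [simulate_mosaic()].
#' @return list with `variants` (a [variant_set]), `privacy_truth`
#'   (character per site), `pass_truth` (logical per site: statistics drawn
#'   from the passing regime).
#' @export
simulate_variants <- function(config, segments) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .seed_variants)
  layout <- config$layout
  panel <- sim_panel(config)
  samples <- panel_samples(panel)
  chroms <- layout$chromosomes
  ## sites are emitted chromosome-block-wise, position-sorted within block
  per_chrom <- list()
  for (ci in seq_len(nrow(chroms))) {
    chrom <- chroms$name[ci]
    len <- chroms$length[ci]
    mito <- chroms$kind[ci] == "mitochondrial"
    n <- stats::rpois(1, config$snv_density * len)
    n <- min(n, len)
    if (n == 0) next
    pos <- sort(sample.int(len, n))
    per_chrom[[chrom]] <- data.frame(chrom = chrom, pos = pos, mito = mito,
                                     stringsAsFactors = FALSE)
  }
  if (!length(per_chrom)) stop("no sites simulated; increase density")
  sites <- do.call(rbind, per_chrom)
  rownames(sites) <- NULL
  n <- nrow(sites)

  ## alleles
  bases <- c("A", "C", "G", "T")
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  ref <- sample(bases, n, replace = TRUE)
  is_indel <- stats::runif(n) < config$indel_fraction
  is_ts <- !is_indel & stats::runif(n) < config$p_transition
  alt <- character(n)
  alt[is_ts] <- transition_of[ref[is_ts]]
  tv <- !is_indel & !is_ts
  if (any(tv)) {
    partners <- rbind(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))
    pick <- 1L + (stats::runif(sum(tv)) < 0.5)
    alt[tv] <- partners[cbind(match(ref[tv], rownames(partners)), pick)]
  }
  if (any(is_indel)) {
    ins_len <- sample(1:9, sum(is_indel), replace = TRUE)
    alt[is_indel] <- paste0(ref[is_indel], vapply(ins_len, function(k)
      paste(sample(bases, k, replace = TRUE), collapse = ""), ""))
  }

  ## ancestry of each site (from focal_A's mosaic; mito sites get none)
  anc <- rep(NA_character_, n)
  nonmito <- !sites$mito
  if (any(nonmito)) {
    site_gr <- GenomicRanges::GRanges(sites$chrom[nonmito],
                                      IRanges::IRanges(sites$pos[nonmito],
                                                       sites$pos[nonmito]))
    hits <- GenomicRanges::findOverlaps(site_gr, segments)
    anc[which(nonmito)[S4Vectors::queryHits(hits)]] <-
      S4Vectors::mcols(segments)$ancestry[S4Vectors::subjectHits(hits)]
  }

  ## genotypes
  gt <- matrix("0/0", n, length(samples), dimnames = list(NULL, samples))
  ## privacy categories -> focal + known-panel genotypes
  privacy <- sample(names(config$privacy_spec), n, replace = TRUE,
                    prob = config$privacy_spec)
  gt[, "focal_A"] <- ifelse(privacy %in% c("private_A", "shared_exclusive",
                                           "known"), "1/1", "0/0")
  gt[, "focal_B"] <- ifelse(privacy %in% c("private_B", "shared_exclusive",
                                           "known"), "1/1", "0/0")
  if (config$n_known_panel > 0) {
    carrier <- sample.int(config$n_known_panel, n, replace = TRUE)
    for (k in seq_len(config$n_known_panel))
      gt[privacy == "known" & carrier == k, paste0("known_", k)] <- "1/1"
  } else if (any(privacy == "known")) {
    stop("privacy_spec includes 'known' but n_known_panel is 0")
  }
  ## outgroup: ancestral (= ref) when polarizable, het otherwise
  polarizable <- stats::runif(n) < config$p_polarizable
  gt[, "outgroup"] <- ifelse(polarizable, "0/0", "0/1")
  ## representatives: the sharing channel is driven by segment ancestry at
  ## the sites the focal strain carries; derived alleles the focal strain
  ## does not carry (here: variants private to the other strain) are novel
  ## mutations no representative shares, so ancestry information lives in
  ## the focal-by-representative sharing pattern, not in the
  ## representatives alone
  focal_carries <- privacy %in% c("private_A", "shared_exclusive", "known")
  reps <- c(dom = "rep_dom", mus = "rep_mus", cas = "rep_cas")
  u <- stats::runif(n)
  v <- stats::runif(n)
  anc_filled <- ifelse(is.na(anc), "dom", anc)
  wrong_pick <- ifelse(stats::runif(n) < 0.5, 1L, 2L)
  for (s in names(reps)) {
    others <- setdiff(names(reps), s)
    rows <- which(anc_filled == s & !sites$mito & focal_carries)
    if (!length(rows)) next
    correct <- rows[u[rows] < config$p_exclusive_correct]
    gt[correct, reps[[s]]] <- "1/1"
    noise <- rows[u[rows] >= config$p_exclusive_correct &
                    u[rows] < config$p_exclusive_correct +
                    config$p_noise_share]
    for (w in 1:2) {
      pick <- noise[wrong_pick[noise] == w]
      gt[pick, reps[[others[w]]]] <- "1/1"
    }
    rest <- rows[u[rows] >= config$p_exclusive_correct +
                   config$p_noise_share]
    two <- rest[v[rest] >= 0.5]      # two carriers (non-exclusive)
    for (w in 1:2) {
      pick <- two[wrong_pick[two] == w]
      gt[pick, reps[[s]]] <- "1/1"
      gt[pick, reps[[others[w]]]] <- "1/1"
    }
    ## remaining "rest" rows: no representative carries the derived allele
  }

  ## site statistics: pass regime vs one failing rule
  pass <- stats::runif(n) < config$p_pass
  dp <- stats::rnbinom(n, size = config$depth_dispersion,
                       mu = config$depth_mean)
  dp <- pmin(pmax(dp, 7L), 99L)
  mito_rows <- sites$mito
  if (any(mito_rows)) {
    dpm <- stats::rnbinom(sum(mito_rows), size = config$depth_dispersion,
                          mu = config$mito_depth_mean)
    dp[mito_rows] <- pmax(dpm, 351L)
  }
  mq <- stats::runif(n, 30, 60)
  alt_support <- pmax(stats::rbinom(n, dp, 0.98), 6L)
  fail_mode <- sample(c("low_dp", "high_dp", "low_mq", "low_alt"), n,
                      replace = TRUE)
  fail_mode[mito_rows & fail_mode == "high_dp"] <- "low_dp"
  f <- !pass
  dp[f & fail_mode == "low_dp"] <- ifelse(
    mito_rows[f & fail_mode == "low_dp"],
    sample(300:350, sum(f & fail_mode == "low_dp"), replace = TRUE),
    sample(0:5, sum(f & fail_mode == "low_dp"), replace = TRUE))
  dp[f & fail_mode == "high_dp"] <- sample(100:300,
                                           sum(f & fail_mode == "high_dp"),
                                           replace = TRUE)
  mq[f & fail_mode == "low_mq"] <- stats::runif(sum(f & fail_mode ==
                                                      "low_mq"), 0, 20)
  alt_support[f & fail_mode == "low_alt"] <-
    sample(0:5, sum(f & fail_mode == "low_alt"), replace = TRUE)
  alt_support <- pmin(alt_support, dp)

  site_tab <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = ref,
                         alt = alt, dp = as.numeric(dp),
                         mq = round(mq, 2),
                         alt_support = as.numeric(alt_support),
                         stringsAsFactors = FALSE)
  list(variants = variant_set(site_tab, gt), privacy_truth = privacy,
       pass_truth = pass)
}

#' Simulate a windowed depth track
#'
#' Window means are drawn from a negative binomial with mean
#' `depth_mean x copy_ratio x sex_factor`, where the sex factor is 0.5 on
#' the X for males and the copy ratio comes from `cnv_spec` (1 elsewhere).
#' Total depth adds a small low-mapping-quality excess on top of the MQ>20
#' depth.  Deterministic given the seed.
#'
#' @param config a [sim_config].
#' @param sample track sample name (default `"focal_A"`).
#' @param with_cnvs apply `cnv_spec` perturbations (default TRUE; panel
#'   comparison tracks are drawn without them).
#' @param seed_offset extra offset so panel tracks get independent draws.
#' @return a [depth_track].
#' @export
simulate_depth <- function(config, sample = "focal_A", with_cnvs = TRUE,
                           seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .seed_depth + seed_offset)
  win <- make_windows(config$layout, config$window_width,
                      kinds = c("autosome", "X"))
  n <- length(win)
  kind <- chromosome_kind(config$layout,
                          as.character(GenomeInfoDb::seqnames(win)))
  ratio <- rep(1, n)
  if (with_cnvs && !is.null(config$cnv_spec)) {
    cnv <- GenomicRanges::GRanges(
      config$cnv_spec$chrom,
      IRanges::IRanges(config$cnv_spec$start + 1, config$cnv_spec$end))
    mid <- GenomicRanges::GRanges(
      as.character(GenomeInfoDb::seqnames(win)),
      IRanges::IRanges(floor((GenomicRanges::start(win) +
                                GenomicRanges::end(win)) / 2), width = 1))
    hits <- GenomicRanges::findOverlaps(mid, cnv)
    ratio[S4Vectors::queryHits(hits)] <-
      config$cnv_spec$ratio[S4Vectors::subjectHits(hits)]
  }
  sexf <- ifelse(kind == "X" & config$sex == "male", 0.5, 1)
  mu <- config$depth_mean * ratio * sexf
  ## window *means* are continuous: gamma with shape = dispersion (the
  ## mixing density of a negative binomial), CV = 1/sqrt(dispersion)
  depth_mq20 <- numeric(n)
  pos <- mu > 0
  depth_mq20[pos] <- stats::rgamma(sum(pos), shape = config$depth_dispersion,
                                   rate = config$depth_dispersion / mu[pos])
  depth_mq20 <- round(depth_mq20, 3)
  depth_total <- depth_mq20 +
    round(stats::rgamma(n, shape = 20,
                        rate = 20 / (0.05 * config$depth_mean)), 3)
  depth_track(data.frame(chrom = as.character(GenomeInfoDb::seqnames(win)),
                         start = GenomicRanges::start(win) - 1,
                         end = GenomicRanges::end(win),
                         depth_mq20 = depth_mq20,
                         depth_total = depth_total),
              sample = sample, layout = config$layout)
}

#' Generate a complete synthetic dataset
#'
#' Runs the mosaic, variant and depth generators and optionally writes
#' every artifact to disk (layout TSV, VCF, truth BEDs/TSVs, depth TSVs).
#' Identical configurations (including the seed) produce byte-identical
#' files.
#'
#' @param config a [sim_config].
#' @param outdir optional output directory (created if needed).
#' @return list: `config`, `layout`, `panel`, `segments`, `variants`,
#'   `privacy_truth`, `pass_truth`, `depth_focal`, `depth_panel` (list),
#'   `cnv_truth`, `sex_truth`, and `files` (named paths when `outdir` was
#'   given).
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  segments <- simulate_mosaic(config)
  sim <- simulate_variants(config, segments)
  depth_focal <- simulate_depth(config, sample = "focal_A",
                                with_cnvs = TRUE)
  depth_panel <- lapply(seq_len(config$n_depth_panel), function(k)
    simulate_depth(config, sample = paste0("panel_", k), with_cnvs = FALSE,
                   seed_offset = 1000L * k))
  out <- list(config = config, layout = config$layout,
              panel = sim_panel(config), segments = segments,
              variants = sim$variants, privacy_truth = sim$privacy_truth,
              pass_truth = sim$pass_truth, depth_focal = depth_focal,
              depth_panel = depth_panel, cnv_truth = config$cnv_spec,
              sex_truth = config$sex)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(outdir, x)
    files <- c(layout = fp("layout.tsv"), vcf = fp("variants.vcf"),
               segments = fp("truth_segments.bed"),
               privacy = fp("truth_privacy.tsv"),
               depth_focal = fp("depth_focal.tsv"))
    write_genome_layout(config$layout, files[["layout"]])
    write_vcf(sim$variants, files[["vcf"]])
    seg_df <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(segments)),
      start = GenomicRanges::start(segments) - 1,
      end = GenomicRanges::end(segments),
      ancestry = S4Vectors::mcols(segments)$ancestry)
    utils::write.table(seg_df, files[["segments"]], sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(
      data.frame(chrom = sim$variants$sites$chrom,
                 pos = sim$variants$sites$pos,
                 category = sim$privacy_truth),
      files[["privacy"]], sep = "\t", quote = FALSE, row.names = FALSE)
    write_depth_track(depth_focal, files[["depth_focal"]])
    for (k in seq_along(depth_panel)) {
      f <- fp(sprintf("depth_panel_%d.tsv", k))
      write_depth_track(depth_panel[[k]], f)
      files[[sprintf("depth_panel_%d", k)]] <- f
    }
    if (!is.null(config$cnv_spec)) {
      files[["cnv_truth"]] <- fp("truth_cnv.bed")
      utils::write.table(config$cnv_spec[, c("chrom", "start", "end",
                                             "ratio")],
                         files[["cnv_truth"]], sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    out$files <- files
  }
  out
}
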