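#' Sample panel: focal strains, subspecies representatives, outgroup, catalog
#'
#' Names the roles every downstream stage needs: one or two focal strains,
#' one representative per house-mouse subspecies (*M. m. domesticus*,
#' *musculus*, *castaneus*), an outgroup species carrying the ancestral
#' allele, and an optional panel of previously sequenced strains used to
#' decide whether a variant is already known.
#'
#' @param focal character vector of 1 or 2 focal sample names.
#' @param representatives named character vector with names `dom`, `mus`,
#'   `cas` giving the representative sample per subspecies.
#' @param outgroup single outgroup sample name.
#' @param known_panel character vector of known-strain sample names (may be
#'   empty).
#' @return an object of class `sample_panel`.
#' @export
sample_panel <- function(focal, representatives, outgroup,
                         known_panel = character()) {
  focal <- as.character(focal)
  if (!length(focal) %in% 1:2)
    stop("panel needs 1 or 2 focal samples")
  if (!all(c("dom", "mus", "cas") %in% names(representatives)))
    stop("representatives must be named dom, mus, cas")
  representatives <- representatives[c("dom", "mus", "cas")]
  all_names <- c(focal, unname(representatives), outgroup, known_panel)
  if (anyDuplicated(all_names))
    stop("sample names must be distinct across roles")
  structure(list(focal = focal,
                 representatives = representatives,
                 outgroup = as.character(outgroup),
                 known_panel = as.character(known_panel)),
            class = "sample_panel")
}

#' @export
print.sample_panel <- function(x, ...) {
  cat("sample_panel\n")
  cat("  focal:     ", paste(x$focal, collapse = ", "), "\n")
  cat("  dom/mus/cas:", paste(x$representatives, collapse = " / "), "\n")
  cat("  outgroup:  ", x$outgroup, "\n")
  cat("  known panel:", length(x$known_panel), "strain(s)\n")
  invisible(x)
}

panel_samples <- function(panel) {
  c(panel$focal, unname(panel$representatives), panel$outgroup,
    panel$known_panel)
}

#' Construct a variant set
#'
#' The in-memory container for candidate variant sites: a site table plus a
#' genotype matrix of VCF-style GT strings (`"0/0"`, `"1/1"`, `"0/1"`,
#' `"./."`, ...), one row per site and one column per sample.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based, as in VCF),
#'   `ref`, `alt` (comma-separated when multiallelic), and optionally `dp`,
#'   `mq`, `alt_support`, `filter`.  `variant_class` and `multiallelic` are
#'   derived from the alleles if absent.
#' @param gt character matrix of GT strings, `nrow(sites)` rows, with sample
#'   names as column names.
#' @return an object of class `variant_set`.
#' @export
variant_set <- function(sites, gt) {
  stopifnot(is.data.frame(sites))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites)))
    stop("sites needs columns: ", paste(need, collapse = ", "))
  gt <- as.matrix(gt)
  if (nrow(sites) > 0 && nrow(gt) != nrow(sites))
    stop("genotype matrix must have one row per site")
  if (is.null(colnames(gt)))
    stop("genotype matrix needs sample names as column names")
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- toupper(as.character(sites$ref))
  sites$alt <- toupper(as.character(sites$alt))
  for (col in c("dp", "mq", "alt_support"))
    if (is.null(sites[[col]])) sites[[col]] <- rep(NA_real_, nrow(sites))
  alts <- strsplit(sites$alt, ",", fixed = TRUE)
  sites$multiallelic <- lengths(alts) > 1L
  if (is.null(sites$variant_class)) {
    is_snv <- nchar(sites$ref) == 1L &
      vapply(alts, function(a) all(nchar(a) == 1L), logical(1))
    sites$variant_class <- ifelse(is_snv, "SNV", "indel")
  }
  ok_allele <- grepl("^[ACGT]+$", sites$ref) &
    vapply(alts, function(a) all(grepl("^[ACGT]+$", a)), logical(1))
  if (nrow(sites) && !all(ok_allele))
    stop("non-ACGT allele at site row ", which(!ok_allele)[1L])
  rownames(sites) <- NULL
  rownames(gt) <- NULL
  structure(list(sites = sites, gt = gt, samples = colnames(gt)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d site(s) x %d sample(s)\n",
              nrow(x$sites), length(x$samples)))
  if (nrow(x$sites)) {
    cat(sprintf("  SNV: %d, indel: %d, multiallelic: %d\n",
                sum(x$sites$variant_class == "SNV"),
                sum(x$sites$variant_class == "indel"),
                sum(x$sites$multiallelic)))
  }
  invisible(x)
}

#' @export
`[.variant_set` <- function(x, i) {
  variant_set(x$sites[i, , drop = FALSE], x$gt[i, , drop = FALSE])
}

#' Number of sites in a variant set
#' @param vs a [variant_set].
#' @return integer site count.
#' @export
n_sites <- function(vs) nrow(vs$sites)

## ---- genotype string helpers -------------------------------------------

## Split GT strings into a 2-column integer allele matrix (NA = missing).
## Haploid calls are duplicated; anything unparseable is missing.
gt_allele_matrix <- function(gt) {
  gt <- sub(":.*$", "", as.character(gt))
  parts <- strsplit(gt, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  a2 <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) >= 2L) p[2L] else p[1L], "")))
  cbind(a1, a2)
}

#' Classify genotype strings
#' @param gt character vector of VCF GT strings.
#' @return character vector in `hom_ref`, `hom_alt`, `het`, `missing`.
#' @export
gt_code <- function(gt) {
  m <- gt_allele_matrix(gt)
  out <- rep("missing", length(gt))
  known <- !is.na(m[, 1]) & !is.na(m[, 2])
  out[known & m[, 1] == m[, 2] & m[, 1] == 0L] <- "hom_ref"
  out[known & m[, 1] == m[, 2] & m[, 1] > 0L] <- "hom_alt"
  out[known & m[, 1] != m[, 2]] <- "het"
  out
}

## TRUE where the genotype is homozygous for alt allele k (1-based alt index)
gt_is_hom_alt <- function(gt, k = 1L) {
  m <- gt_allele_matrix(gt)
  !is.na(m[, 1]) & !is.na(m[, 2]) & m[, 1] == k & m[, 2] == k
}

## TRUE where the genotype carries >=1 copy of alt allele k; NA if missing
gt_carries <- function(gt, k = 1L) {
  m <- gt_allele_matrix(gt)
  miss <- is.na(m[, 1]) | is.na(m[, 2])
  out <- m[, 1] == k | m[, 2] == k
  out[miss] <- NA
  out
}

gt_is_missing <- function(gt) {
  m <- gt_allele_matrix(gt)
  is.na(m[, 1]) | is.na(m[, 2])
}

## ---- VCF reading --------------------------------------------------------

#' Read a VCF into a variant set
#'
#' Reads the VCF v4.2 subset the pipeline uses: `CHROM POS REF ALT FILTER`,
#' `INFO/DP`, `INFO/MQ`, alternate-allele read support from `INFO/DP4` (sum
#' of the two alt-strand counts) with a fallback to the focal sample's
#' `FORMAT/AD`, and per-sample `GT`.  Multiallelic records are retained with
#' all alternate alleles and flagged.  Records with unparseable coordinates
#' or non-ACGT alleles are dropped with a warning naming their record
#' numbers; the count of dropped records is available as
#' `attr(x, "n_malformed")`.
#'
#' @param path VCF file (plain or gzip).
#' @param panel optional [sample_panel]; when given, all panel samples must
#'   be present in the VCF (fatal otherwise), and the first focal sample is
#'   used for the AD fallback.
#' @return a [variant_set]; site statistics that are absent in the file are
#'   `NA` (and fail any filter that needs them).
#' @export
read_vcf <- function(path, panel = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_in <- nrow(fix)
  gt_full <- if (n_in) vcfR::extract.gt(v, element = "GT") else
    matrix(character(), 0, 0)
  if (n_in && is.null(dim(gt_full)))
    gt_full <- matrix(gt_full, nrow = 1, dimnames = list(NULL, names(gt_full)))
  samples <- colnames(v@gt)[-1]
  if (!is.null(panel)) {
    missing_samples <- setdiff(panel_samples(panel), samples)
    if (length(missing_samples))
      stop("required sample(s) missing from VCF: ",
           paste(missing_samples, collapse = ", "))
  }
  if (n_in == 0L) {
    out <- variant_set(data.frame(chrom = character(), pos = integer(),
                                  ref = character(), alt = character()),
                       matrix(character(), 0, length(samples),
                              dimnames = list(NULL, samples)))
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  ok <- !is.na(pos) & pos >= 1 & grepl("^[ACGT]+$", ref) &
    grepl("^[ACGT]+(,[ACGT]+)*$", alt)
  if (any(!ok))
    warning(sum(!ok), " malformed record(s) dropped (record number ",
            paste(utils::head(which(!ok), 10), collapse = ", "), ")")
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  dp4 <- vcfR::extract.info(v, "DP4")
  alt_support <- rep(NA_real_, n_in)
  has_dp4 <- !is.na(dp4)
  if (any(has_dp4)) {
    parts <- strsplit(dp4[has_dp4], ",", fixed = TRUE)
    alt_support[has_dp4] <- vapply(parts, function(p) {
      p <- suppressWarnings(as.numeric(p))
      if (length(p) == 4L && !anyNA(p)) p[3L] + p[4L] else NA_real_
    }, numeric(1))
  }
  if (any(!has_dp4) && !is.null(panel)) {
    ad <- try(vcfR::extract.gt(v, element = "AD")[, panel$focal[1L]],
              silent = TRUE)
    if (!inherits(ad, "try-error") && !all(is.na(ad))) {
      idx <- which(!has_dp4 & !is.na(ad))
      alt_support[idx] <- vapply(strsplit(ad[idx], ",", fixed = TRUE),
                                 function(p) {
        p <- suppressWarnings(as.numeric(p))
        if (length(p) >= 2L) sum(p[-1L], na.rm = TRUE) else NA_real_
      }, numeric(1))
    }
  }
  sites <- data.frame(chrom = fix[, "CHROM"], pos = pos, ref = ref,
                      alt = alt, dp = dp, mq = mq,
                      alt_support = alt_support,
                      filter = ifelse(is.na(fix[, "FILTER"]), ".",
                                      fix[, "FILTER"]),
                      stringsAsFactors = FALSE)
  keep <- which(ok)
  gt_keep <- gt_full[keep, , drop = FALSE]
  gt_keep[is.na(gt_keep)] <- "./."
  out <- variant_set(sites[keep, , drop = FALSE], gt_keep)
  attr(out, "n_malformed") <- sum(!ok)
  out
}

#' Write a variant set as VCF v4.2
#'
#' Emits the same subset [read_vcf()] consumes, so that
#' `read_vcf(write_vcf(x))` reproduces coordinates, alleles, site
#' statistics, genotypes and filter verdicts exactly.  Alternate-allele
#' support is encoded in `INFO/DP4` (reference and alternate read counts
#' split across strands).
#'
#' @param vs a [variant_set].
#' @param path output path (`.gz` for gzip).
#' @param filter optional character vector of FILTER strings per site
#'   (`"PASS"` or semicolon-joined reason codes); defaults to the set's
#'   `filter` column, or `"."`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, filter = NULL) {
  stopifnot(inherits(vs, "variant_set"))
  s <- vs$sites
  if (is.null(filter)) filter <- if (!is.null(s$filter)) s$filter else
    rep(".", nrow(s))
  if (nrow(s) && length(filter) != nrow(s))
    stop("one filter string per site required")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=strainpaint",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"Ref fwd, ref rev, alt fwd, alt rev read counts\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vs$samples), collapse = "\t"))
  info <- character(nrow(s))
  if (nrow(s)) {
    dp_f <- ifelse(is.na(s$dp), NA, paste0("DP=", as.integer(round(s$dp))))
    mq_f <- ifelse(is.na(s$mq), NA, paste0("MQ=", vapply(s$mq, format,
                                                         "", digits = 15)))
    dp4_f <- rep(NA_character_, nrow(s))
    ok4 <- !is.na(s$dp) & !is.na(s$alt_support)
    if (any(ok4)) {
      a <- as.integer(round(s$alt_support[ok4]))
      r <- pmax(as.integer(round(s$dp[ok4])) - a, 0L)
      dp4_f[ok4] <- sprintf("%d,%d,%d,%d", r %/% 2L, r - r %/% 2L,
                            a %/% 2L, a - a %/% 2L)
      dp4_f[ok4] <- paste0("DP4=", dp4_f[ok4])
    }
    info <- apply(cbind(dp_f, mq_f, dp4_f), 1, function(x)
      if (all(is.na(x))) "." else paste(x[!is.na(x)], collapse = ";"))
    body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", filter, info,
                  "GT", sep = "\t")
    if (length(vs$samples))
      body <- paste(body, apply(vs$gt, 1, paste, collapse = "\t"),
                    sep = "\t")
  } else body <- character()
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

## ---- depth tracks -------------------------------------------------------

#' Construct a windowed depth track
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open, the BED convention), `depth_mq20` (mean depth of reads with
#'   mapping quality > 20) and `depth_total` (mean depth of all reads).
#' @param sample sample name the track belongs to.
#' @param layout optional [genome_layout]; windows are checked against
#'   chromosome bounds when given.
#' @return data.frame of class `depth_track` with a `sample` attribute.
#' @export
depth_track <- function(df, sample = "sample", layout = NULL) {
  need <- c("chrom", "start", "end", "depth_mq20", "depth_total")
  if (!all(need %in% names(df)))
    stop("depth track needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$chrom <- as.character(df$chrom)
  for (col in c("start", "end", "depth_mq20", "depth_total"))
    df[[col]] <- as.numeric(df[[col]])
  if (nrow(df)) {
    if (any(df$start < 0 | df$end <= df$start))
      stop("invalid window at row ",
           which(df$start < 0 | df$end <= df$start)[1L])
    if (any(df$depth_mq20 < 0 | df$depth_total < 0))
      stop("negative depth at row ",
           which(df$depth_mq20 < 0 | df$depth_total < 0)[1L])
    bad <- df$depth_mq20 > df$depth_total
    if (any(bad))
      stop("depth_mq20 exceeds depth_total at row ", which(bad)[1L])
    if (!is.null(layout)) {
      i <- match(df$chrom, layout$chromosomes$name)
      if (anyNA(i))
        stop("depth window on unknown chromosome: ",
             paste(unique(df$chrom[is.na(i)]), collapse = ", "))
      out <- df$end > layout$chromosomes$length[i]
      if (any(out))
        stop("depth window outside chromosome at row ", which(out)[1L])
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("depth_track", "data.frame"), sample = sample)
}

#' Read a windowed depth track from TSV
#'
#' Expects a header line with columns `chromosome` (or `chrom`), `start`,
#' `end`, `depth_mq20`, `depth_total`; `start`/`end` are 0-based half-open.
#'
#' @param path TSV file (plain or gzip).
#' @inheritParams depth_track
#' @return a [depth_track].
#' @export
read_depth_track <- function(path, layout = NULL, sample = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "chromosome"] <- "chrom"
  if (is.null(sample))
    sample <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  depth_track(df, sample = sample, layout = layout)
}

#' Write a depth track as TSV
#' @param track a [depth_track].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(track, path) {
  df <- as.data.frame(track)
  names(df)[names(df) == "chrom"] <- "chromosome"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## GRanges view of a depth track (1-based, for overlap arithmetic)
depth_granges <- function(track) {
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(start = track$start + 1,
                                          end = track$end))
}
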