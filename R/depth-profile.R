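#' Normalize a depth track to copy-number ratios
#'
#' Divides each window's MQ>20 depth by the autosome-wide median, so a
#' diploid autosomal window sits at ratio 1, a single-copy region (one X in
#' a male, a heterozygous deletion) near 0.5, and a homozygous deletion
#' near 0.  Normalizing an already-normalized track is a no-op because the
#' autosomal median of the ratios is 1 by construction.
#'
#' @param track a [depth_track].
#' @param layout a [genome_layout] (identifies autosomal windows).
#' @return the track with a `ratio` column added (or recomputed).
#' @export
normalize_depth <- function(track, layout) {
  stopifnot(inherits(track, "depth_track"))
  if (nrow(track) == 0L) stop("empty depth track")
  kind <- chromosome_kind(layout, track$chrom)
  values <- if (!is.null(track$ratio)) track$ratio else track$depth_mq20
  auto <- values[kind == "autosome"]
  if (!length(auto) || all(auto == 0))
    stop("no autosomal windows with positive depth")
  med <- stats::median(auto)
  track$ratio <- values / med
  track
}

#' Infer genetic sex from the X:autosome depth ratio
#'
#' A male carries one X against two copies of each autosome, so the median
#' normalized X depth sits near 0.5; a female sits near 1.  The label is
#' `male` when the ratio falls below `threshold` and `female` otherwise
#' (the boundary value is assigned to female).
#'
#' @param track a [depth_track].
#' @param layout a [genome_layout] with an X chromosome.
#' @param threshold ratio below which the sample is called male
#'   (default 0.75).
#' @return list with `label` (`"male"`/`"female"`) and `x_auto_ratio`.
#' @export
infer_sex <- function(track, layout, threshold = 0.75) {
  track <- normalize_depth(track, layout)
  kind <- chromosome_kind(layout, track$chrom)
  x <- track$ratio[kind == "X"]
  if (!length(x)) stop("depth track has no X-chromosome windows")
  ratio <- stats::median(x)
  list(label = if (ratio < threshold) "male" else "female",
       x_auto_ratio = ratio)
}

#' Callable fraction of the genome
#'
#' Length-weighted fraction of bases lying in windows whose raw MQ>20 depth
#' reaches the threshold ("at least", inclusive).
#'
#' @param track a [depth_track] with raw (unnormalized) depths.
#' @param threshold minimum depth in reads (default 10).
#' @return fraction in \[0, 1\].
#' @export
callable_fraction <- function(track, threshold = 10) {
  stopifnot(inherits(track, "depth_track"))
  if (nrow(track) == 0L) return(0)
  len <- track$end - track$start
  sum(len[track$depth_mq20 >= threshold]) / sum(len)
}

#' CNV-calling configuration
#'
#' @param min_consecutive minimum run of deviant windows for a call
#'   (default 3).
#' @param del_threshold normalized ratio below which a window is
#'   deletion-deviant (default 0.25, strict).
#' @param dup_threshold ratio above which a window is duplication-deviant
#'   (default 1.5, strict).
#' @param panel_band normal range for panel tracks over a call interval;
#'   a call is private only when every panel mean falls inside it
#'   (default \[0.75, 1.25\], inclusive).
#' @return a `cnv_config` list.
#' @export
cnv_config <- function(min_consecutive = 3, del_threshold = 0.25,
                       dup_threshold = 1.5, panel_band = c(0.75, 1.25)) {
  stopifnot(min_consecutive >= 1, del_threshold < dup_threshold,
            length(panel_band) == 2L, panel_band[1] < panel_band[2])
  structure(list(min_consecutive = min_consecutive,
                 del_threshold = del_threshold,
                 dup_threshold = dup_threshold,
                 panel_band = panel_band), class = "cnv_config")
}

#' Screen a normalized depth track for copy-number variants
#'
#' Runs of at least `min_consecutive` windows with normalized ratio below
#' the deletion threshold or above the duplication threshold become calls.
#' A call is *private* when every panel track's mean ratio over the same
#' windows lies inside the normal band — i.e. the deviation is absent from
#' the comparison strains.
#'
#' @param focal a normalized [depth_track] (see [normalize_depth()]).
#' @param panel list of normalized [depth_track]s on the identical window
#'   grid (may be empty, in which case every call is private by
#'   definition).
#' @param config a [cnv_config].
#' @return data.frame of class `cnv_calls`: `chrom`, `start`, `end`
#'   (0-based half-open), `kind` (`deletion`/`duplication`), `mean_ratio`,
#'   `n_windows`, `private`.
#' @export
call_cnvs <- function(focal, panel = list(), config = cnv_config()) {
  stopifnot(inherits(focal, "depth_track"), inherits(config, "cnv_config"))
  if (is.null(focal$ratio))
    stop("focal track is not normalized; run normalize_depth() first")
  for (p in panel) {
    if (!inherits(p, "depth_track") || is.null(p$ratio))
      stop("panel tracks must be normalized depth tracks")
    if (!identical(p$chrom, focal$chrom) ||
        !identical(p$start, focal$start) || !identical(p$end, focal$end))
      stop("panel track window grid disagrees with the focal track")
  }
  state <- ifelse(focal$ratio < config$del_threshold, "deletion",
                  ifelse(focal$ratio > config$dup_threshold, "duplication",
                         "normal"))
  calls <- list()
  for (chrom in unique(focal$chrom)) {
    idx <- which(focal$chrom == chrom)
    r <- rle(state[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != "normal" & r$lengths >= config$min_consecutive
    for (j in which(keep)) {
      win <- idx[starts[j]:ends[j]]
      private <- all(vapply(panel, function(p)
        mean(p$ratio[win]) >= config$panel_band[1] &&
          mean(p$ratio[win]) <= config$panel_band[2], logical(1)))
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = chrom, start = focal$start[win[1L]],
        end = focal$end[win[length(win)]], kind = r$values[j],
        mean_ratio = mean(focal$ratio[win]), n_windows = length(win),
        private = private, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               kind = character(), mean_ratio = numeric(),
               n_windows = integer(), private = logical())
  structure(out, class = c("cnv_calls", "data.frame"))
}

#' Centromere-proximal CNV screen for Rb-fusion chromosomes
#'
#' For each chromosome involved in a Robertsonian fusion, reports the
#' private CNV calls overlapping its centromere-proximal interval.  An
#' all-zero report is the negative finding: no private copy-number change
#' near the fused centromeres.
#'
#' @param calls `cnv_calls` from [call_cnvs()].
#' @param layout a [genome_layout] with `rb_chromosomes` and
#'   `centromere_proximal` intervals.
#' @return data.frame of class `centromere_report`, one row per Rb
#'   chromosome: `chrom`, `n_private_cnvs`; the flagged calls themselves
#'   are in `attr(x, "flagged")`.
#' @export
centromere_screen <- function(calls, layout) {
  stopifnot(inherits(calls, "cnv_calls"), inherits(layout, "genome_layout"))
  rb <- layout$rb_chromosomes
  out <- data.frame(chrom = rb, n_private_cnvs = 0L,
                    stringsAsFactors = FALSE)
  flagged <- calls[0, , drop = FALSE]
  priv <- calls[calls$private, , drop = FALSE]
  if (nrow(priv) && length(rb)) {
    call_gr <- GenomicRanges::GRanges(
      priv$chrom, IRanges::IRanges(priv$start + 1, priv$end))
    cen <- layout$centromere_proximal
    cen <- cen[as.character(GenomeInfoDb::seqnames(cen)) %in% rb]
    hits <- GenomicRanges::findOverlaps(call_gr, cen, ignore.strand = TRUE)
    if (length(hits)) {
      flagged <- priv[unique(S4Vectors::queryHits(hits)), , drop = FALSE]
      tab <- table(flagged$chrom)
      i <- match(names(tab), out$chrom)
      out$n_private_cnvs[i] <- as.integer(tab)
    }
  }
  structure(out, class = c("centromere_report", "data.frame"),
            flagged = flagged)
}

#' @export
print.centromere_report <- function(x, ...) {
  n <- sum(x$n_private_cnvs)
  cat(sprintf("centromere_screen: %d Rb chromosome(s), %d private CNV(s) in centromere-proximal regions\n",
              nrow(x), n))
  if (n == 0) cat("  negative finding: no private centromere-proximal CNVs\n")
  else print.data.frame(x[x$n_private_cnvs > 0, ])
  invisible(x)
}

#' Write CNV calls as BED
#' @param calls `cnv_calls`.
#' @param path output path; columns 4+ carry kind, mean ratio and privacy.
#' @return `path`, invisibly.
#' @export
write_cnv_bed <- function(calls, path) {
  df <- as.data.frame(calls)[, c("chrom", "start", "end", "kind",
                                 "mean_ratio", "private")]
  df$mean_ratio <- sprintf("%.4f", df$mean_ratio)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
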