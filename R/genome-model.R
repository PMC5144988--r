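#' Genome layout: chromosome table, centromere-proximal intervals, Rb list
#'
#' A `genome_layout` is the shared coordinate system used by every analysis
#' stage.  It records the chromosome names, their lengths, whether each is an
#' autosome, the X chromosome or the mitochondrial genome, the
#' centromere-proximal interval of each chromosome, and which chromosomes are
#' involved in Robertsonian (Rb) fusions.  Mouse chromosomes are acrocentric,
#' so "centromere-proximal" means the low-coordinate end; the default
#' proximal interval is the first 5 Mb of each non-mitochondrial chromosome
#' (configurable via `centromere_width` or an explicit set of intervals).
#'
#' @param chromosomes character vector of unique chromosome names.
#' @param lengths integer-like vector of chromosome lengths in bp (> 0).
#' @param kind character vector, one of `"autosome"`, `"X"`,
#'   `"mitochondrial"` per chromosome.
#' @param centromere_proximal optional [GenomicRanges::GRanges] of
#'   centromere-proximal intervals (at most one per chromosome).  When
#'   `NULL`, the first `centromere_width` bp of every non-mitochondrial
#'   chromosome are used.
#' @param rb_chromosomes character vector of chromosome names carrying
#'   Robertsonian fusions; must be a subset of `chromosomes`.
#' @param centromere_width width in bp of the default centromere-proximal
#'   interval (default 5 Mb), truncated at the chromosome end.
#'
#' @return An object of class `genome_layout`: a list with elements
#'   `chromosomes` (data.frame: `name`, `length`, `kind`),
#'   `centromere_proximal` (GRanges) and `rb_chromosomes` (character).
#' @examples
#' layout <- genome_layout(c("chr1", "chrX", "chrM"),
#'                         c(50e6, 40e6, 16299),
#'                         c("autosome", "X", "mitochondrial"),
#'                         rb_chromosomes = "chr1")
#' layout
#' @export
genome_layout <- function(chromosomes, lengths, kind,
                          centromere_proximal = NULL,
                          rb_chromosomes = character(),
                          centromere_width = 5e6) {
  chromosomes <- as.character(chromosomes)
  lengths <- as.numeric(lengths)
  kind <- as.character(kind)
  if (length(chromosomes) == 0L)
    stop("layout needs at least one chromosome")
  if (anyDuplicated(chromosomes))
    stop("chromosome names must be unique")
  if (length(lengths) != length(chromosomes) ||
      length(kind) != length(chromosomes))
    stop("chromosomes, lengths and kind must have equal length")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  bad <- setdiff(unique(kind), c("autosome", "X", "mitochondrial"))
  if (length(bad))
    stop("unknown chromosome kind: ", paste(bad, collapse = ", "))
  if (length(rb_chromosomes) && !all(rb_chromosomes %in% chromosomes))
    stop("rb_chromosomes must be a subset of chromosome names: ",
         paste(setdiff(rb_chromosomes, chromosomes), collapse = ", "))

  tab <- data.frame(name = chromosomes, length = lengths, kind = kind,
                    stringsAsFactors = FALSE)
  if (is.null(centromere_proximal)) {
    nonmito <- tab[tab$kind != "mitochondrial", , drop = FALSE]
    centromere_proximal <- GenomicRanges::GRanges(
      nonmito$name,
      IRanges::IRanges(start = 1L,
                       end = pmin(nonmito$length, centromere_width)))
  } else {
    centromere_proximal <- methods::as(centromere_proximal, "GRanges")
    cn <- as.character(GenomeInfoDb::seqnames(centromere_proximal))
    if (!all(cn %in% chromosomes))
      stop("centromere-proximal interval on unknown chromosome: ",
           paste(setdiff(cn, chromosomes), collapse = ", "))
    len <- tab$length[match(cn, tab$name)]
    if (any(GenomicRanges::start(centromere_proximal) < 1) ||
        any(GenomicRanges::end(centromere_proximal) > len))
      stop("centromere-proximal interval outside its chromosome")
  }
  structure(list(chromosomes = tab,
                 centromere_proximal = centromere_proximal,
                 rb_chromosomes = as.character(rb_chromosomes)),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  tab <- x$chromosomes
  cat(sprintf("genome_layout: %d chromosome(s), %.1f Mb total\n",
              nrow(tab), sum(tab$length) / 1e6))
  cat(sprintf("  autosomes: %d, X: %d, mitochondrial: %d\n",
              sum(tab$kind == "autosome"), sum(tab$kind == "X"),
              sum(tab$kind == "mitochondrial")))
  if (length(x$rb_chromosomes))
    cat("  Rb-fusion chromosomes:",
        paste(x$rb_chromosomes, collapse = ", "), "\n")
  invisible(x)
}

#' Named vector of chromosome lengths for a layout
#' @param layout a [genome_layout].
#' @param kinds restrict to these chromosome kinds (default all).
#' @return named numeric vector of lengths in bp.
#' @export
layout_seqlengths <- function(layout,
                              kinds = c("autosome", "X", "mitochondrial")) {
  stopifnot(inherits(layout, "genome_layout"))
  tab <- layout$chromosomes[layout$chromosomes$kind %in% kinds, , drop = FALSE]
  stats::setNames(tab$length, tab$name)
}

#' Chromosome kind lookup
#' @param layout a [genome_layout].
#' @param chrom character vector of chromosome names.
#' @return character vector of kinds; errors on unknown chromosomes.
#' @export
chromosome_kind <- function(layout, chrom) {
  stopifnot(inherits(layout, "genome_layout"))
  i <- match(chrom, layout$chromosomes$name)
  if (anyNA(i))
    stop("unknown chromosome: ",
         paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout$chromosomes$kind[i]
}

#' Read a genome layout from a tab-separated file
#'
#' The file has three columns (`name`, `length`, `kind`), with or without a
#' header line.  Centromere-proximal intervals can be supplied as a BED file
#' (0-based half-open, as usual for BED).
#'
#' @param path path to the layout TSV.
#' @param centromere_bed optional BED file of centromere-proximal intervals.
#' @inheritParams genome_layout
#' @return a [genome_layout].
#' @export
read_genome_layout <- function(path, centromere_bed = NULL,
                               rb_chromosomes = character(),
                               centromere_width = 5e6) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 3)
    stop("layout file needs 3 columns: name, length, kind")
  if (identical(tolower(as.character(tab[1, 1])), "name"))
    tab <- tab[-1, , drop = FALSE]
  cen <- if (!is.null(centromere_bed)) rtracklayer::import(centromere_bed,
                                                           format = "BED")
  genome_layout(tab[[1]], as.numeric(tab[[2]]), tab[[3]],
                centromere_proximal = cen,
                rb_chromosomes = rb_chromosomes,
                centromere_width = centromere_width)
}

#' Write a genome layout to a tab-separated file
#' @param layout a [genome_layout].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_layout <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  utils::write.table(layout$chromosomes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Tile a genome into fixed-width windows
#'
#' Chromosomes are cut into consecutive non-overlapping windows of `width`
#' bp; the final window of each chromosome is truncated at the chromosome
#' end, so the windows cover every base exactly once.
#'
#' @param layout a [genome_layout].
#' @param width window width in bp (> 0); 25 kb is the conventional width
#'   for windowed ancestry statistics.
#' @param kinds which chromosome kinds to tile (default autosomes and X;
#'   the mitochondrial genome is not windowed by default).
#' @return a [GenomicRanges::GRanges] of windows, ordered by chromosome then
#'   start.
#' @examples
#' layout <- genome_layout("chr1", 60000, "autosome")
#' make_windows(layout, 25000)
#' @export
make_windows <- function(layout, width, kinds = c("autosome", "X")) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) ||
      width <= 0)
    stop("width must be a single positive number")
  sl <- layout_seqlengths(layout, kinds)
  if (length(sl) == 0L)
    stop("layout has no chromosomes of the requested kinds")
  tiles <- GenomicRanges::tileGenome(sl, tilewidth = width,
                                     cut.last.tile.in.chrom = TRUE)
  unname(tiles)
}

#' Normalize a mask to sorted, disjoint intervals
#'
#' Overlapping and book-ended intervals are merged; the result is sorted by
#' (chromosome, start).  The total number of masked bases is invariant under
#' input ordering and overlap.  Intervals extending beyond their chromosome
#' are rejected by name.
#'
#' @param intervals a [GenomicRanges::GRanges] (or anything coercible) of
#'   masked intervals.
#' @param layout optional [genome_layout]; when given, intervals are
#'   validated against chromosome bounds.
#' @return a normalized `GRanges` mask track.
#' @export
normalize_mask <- function(intervals, layout = NULL) {
  gr <- methods::as(intervals, "GRanges")
  if (!is.null(layout)) {
    stopifnot(inherits(layout, "genome_layout"))
    cn <- as.character(GenomeInfoDb::seqnames(gr))
    i <- match(cn, layout$chromosomes$name)
    if (anyNA(i))
      stop("mask interval on unknown chromosome: ",
           paste(unique(cn[is.na(i)]), collapse = ", "))
    too_long <- GenomicRanges::end(gr) > layout$chromosomes$length[i] |
      GenomicRanges::start(gr) < 1
    if (any(too_long)) {
      j <- which(too_long)[1L]
      stop(sprintf("mask interval exceeds chromosome bounds: %s:%d-%d",
                   cn[j], GenomicRanges::start(gr)[j],
                   GenomicRanges::end(gr)[j]))
    }
  }
  sorted <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  GenomicRanges::reduce(sorted, ignore.strand = TRUE)
}

#' Read a mask track from a BED file
#' @param path BED file (3+ columns) of masked intervals.
#' @param layout optional [genome_layout] for bounds checking.
#' @return a normalized `GRanges` mask track.
#' @export
read_mask_bed <- function(path, layout = NULL) {
  normalize_mask(rtracklayer::import(path, format = "BED"), layout)
}

#' Fraction of each window covered by a mask
#'
#' @param windows a `GRanges` of windows (e.g. from [make_windows()]).
#' @param mask a normalized `GRanges` mask track (see [normalize_mask()]);
#'   an empty mask yields 0 everywhere.
#' @return numeric vector in \[0, 1\], one value per window: masked bases in
#'   the window divided by window length.
#' @export
mask_overlap_fraction <- function(windows, mask) {
  windows <- methods::as(windows, "GRanges")
  mask <- methods::as(mask, "GRanges")
  masked <- numeric(length(windows))
  if (length(mask)) {
    hits <- GenomicRanges::findOverlaps(windows, mask, ignore.strand = TRUE)
    if (length(hits)) {
      ov <- GenomicRanges::pintersect(windows[S4Vectors::queryHits(hits)],
                                      mask[S4Vectors::subjectHits(hits)])
      agg <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
      masked[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  masked / GenomicRanges::width(windows)
}
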