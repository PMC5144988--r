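#' Pipeline run configuration
#'
#' Bundles every input and stage parameter for a full run.  Inputs are
#' either a [sim_config] (fully synthetic run) or file paths (VCF, layout
#' TSV, mask BED, depth TSVs) plus a [sample_panel].  Referenced files are
#' checked at construction time; stage parameters validate against their
#' modules' rules.
#'
#' @param sim optional [sim_config]; when given, all inputs are generated.
#' @param vcf,layout_tsv,mask_bed,depth_tsv paths used when `sim` is NULL
#'   (`mask_bed` and `depth_tsv` optional).
#' @param depth_panel_tsv character vector of comparison depth-track paths.
#' @param panel a [sample_panel] (required for file-based runs).
#' @param rb_chromosomes,centromere_bed layout extras for file-based runs.
#' @param mask optional in-memory `GRanges` mask (synthetic runs).
#' @param stages character subset of
#'   `c("filter", "catalog", "paint", "depth")`.
#' @param filter a [filter_config].
#' @param cnv a [cnv_config].
#' @param window_width,min_sites,mask_threshold ancestry-painting knobs.
#' @param callable_threshold depth for the callable fraction (default 10).
#' @param sex_threshold X:autosome ratio below which the sample is male.
#' @param outdir optional output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = NULL, vcf = NULL, layout_tsv = NULL,
                       mask_bed = NULL, depth_tsv = NULL,
                       depth_panel_tsv = character(), panel = NULL,
                       rb_chromosomes = character(), centromere_bed = NULL,
                       mask = NULL,
                       stages = c("filter", "catalog", "paint", "depth"),
                       filter = filter_config(), cnv = cnv_config(),
                       window_width = 25000, min_sites = 10,
                       mask_threshold = 0.5, callable_threshold = 10,
                       sex_threshold = 0.75, outdir = NULL) {
  stages <- match.arg(stages, c("filter", "catalog", "paint", "depth"),
                      several.ok = TRUE)
  if (is.null(sim)) {
    for (f in c(vcf, layout_tsv, mask_bed, depth_tsv, depth_panel_tsv,
                centromere_bed))
      if (!is.null(f) && !file.exists(f))
        stop("input file does not exist: ", f)
    if (is.null(vcf) || is.null(layout_tsv))
      stop("file-based runs need vcf and layout_tsv")
    if (is.null(panel)) stop("file-based runs need a sample_panel")
  } else {
    stopifnot(inherits(sim, "sim_config"))
  }
  stopifnot(inherits(filter, "filter_config"), inherits(cnv, "cnv_config"))
  structure(list(sim = sim, vcf = vcf, layout_tsv = layout_tsv,
                 mask_bed = mask_bed, depth_tsv = depth_tsv,
                 depth_panel_tsv = depth_panel_tsv, panel = panel,
                 rb_chromosomes = rb_chromosomes,
                 centromere_bed = centromere_bed, mask = mask,
                 stages = stages, filter = filter, cnv = cnv,
                 window_width = window_width, min_sites = min_sites,
                 mask_threshold = mask_threshold,
                 callable_threshold = callable_threshold,
                 sex_threshold = sex_threshold, outdir = outdir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Chains the stages — (optional) simulate, hard filtering per focal
#' strain, privacy cataloging of the union of passing sites, windowed
#' ancestry painting per focal strain, and the depth analyses (sex
#' inference, callable fraction, CNV screen with the centromere-proximal
#' check) — and returns a report whose every number is reproducible from
#' the configuration and seed.  A stage failure aborts with the stage name
#' and cause.
#'
#' @param config a [run_config].
#' @return list of class `pipeline_report`; see [render_report()] for
#'   serialization.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  report <- list(params = list(
    stages = config$stages, filter = unclass(config$filter),
    cnv = unclass(config$cnv), window_width = config$window_width,
    min_sites = config$min_sites, mask_threshold = config$mask_threshold,
    callable_threshold = config$callable_threshold,
    sex_threshold = config$sex_threshold,
    seed = if (!is.null(config$sim)) config$sim$seed else NA))

  ## ---- inputs -----------------------------------------------------------
  if (!is.null(config$sim)) {
    ds <- stage("simulate", simulate_dataset(config$sim))
    layout <- ds$layout; panel <- ds$panel; vs <- ds$variants
    mask <- if (!is.null(config$mask)) normalize_mask(config$mask, layout)
      else GenomicRanges::GRanges()
    depth_focal <- ds$depth_focal; depth_panel <- ds$depth_panel
  } else {
    layout <- stage("inputs", read_genome_layout(
      config$layout_tsv, centromere_bed = config$centromere_bed,
      rb_chromosomes = config$rb_chromosomes))
    panel <- config$panel
    vs <- stage("inputs", read_vcf(config$vcf, panel))
    mask <- if (!is.null(config$mask_bed))
      stage("inputs", read_mask_bed(config$mask_bed, layout)) else
        GenomicRanges::GRanges()
    depth_focal <- if (!is.null(config$depth_tsv))
      stage("inputs", read_depth_track(config$depth_tsv, layout)) else NULL
    depth_panel <- lapply(config$depth_panel_tsv, function(f)
      stage("inputs", read_depth_track(f, layout)))
  }
  report$n_sites <- n_sites(vs)

  ## ---- filter ----------------------------------------------------------
  pass_by_focal <- list()
  if ("filter" %in% config$stages) {
    vs <- stage("filter", annotate_indel_distance(vs))
    filt <- lapply(panel$focal, function(f)
      stage("filter", filter_all(vs, config$filter, layout, f)))
    names(filt) <- panel$focal
    pass_by_focal <- lapply(filt, `[[`, "pass")
    report$filter <- lapply(filt, function(x) as.list(x$summary))
    union_pass_idx <- sort(unique(unlist(lapply(filt, function(x)
      which(x$filter == "PASS")))))
  } else {
    union_pass_idx <- seq_len(n_sites(vs))
    pass_by_focal <- stats::setNames(rep(list(vs), length(panel$focal)),
                                     panel$focal)
  }
  union_pass <- vs[union_pass_idx]

  ## ---- catalog ---------------------------------------------------------
  if ("catalog" %in% config$stages) {
    calls <- stage("catalog", classify_variants(union_pass, panel))
    cat_sum <- stage("catalog", summarize_catalog(union_pass, calls))
    report$catalog <- list(counts = cat_sum$counts,
                           ts_count = cat_sum$ts_count,
                           tv_count = cat_sum$tv_count,
                           ts_tv_ratio = cat_sum$ts_tv_ratio)
  }

  ## ---- paint -----------------------------------------------------------
  if ("paint" %in% config$stages) {
    windows <- make_windows(layout, config$window_width)
    win_chroms <- unique(as.character(GenomeInfoDb::seqnames(windows)))
    report$ancestry <- list()
    report$ancestry_windows <- list()
    for (f in panel$focal) {
      pvs <- pass_by_focal[[f]]
      pvs <- pvs[pvs$sites$chrom %in% win_chroms]
      aw <- stage("paint", paint_windows(
        pvs, windows, mask, panel, focal = f,
        min_sites = config$min_sites,
        mask_threshold = config$mask_threshold))
      asum <- stage("paint", summarize_ancestry(aw))
      report$ancestry[[f]] <- asum
      report$ancestry_windows[[f]] <- aw
    }
  }

  ## ---- depth -----------------------------------------------------------
  if ("depth" %in% config$stages && !is.null(depth_focal)) {
    sex <- stage("depth", infer_sex(depth_focal, layout,
                                    config$sex_threshold))
    callable <- stage("depth", callable_fraction(
      depth_focal, config$callable_threshold))
    norm_focal <- stage("depth", normalize_depth(depth_focal, layout))
    norm_panel <- lapply(depth_panel, function(p)
      stage("depth", normalize_depth(p, layout)))
    cnvs <- stage("depth", call_cnvs(norm_focal, norm_panel, config$cnv))
    screen <- stage("depth", centromere_screen(cnvs, layout))
    report$depth <- list(sex = sex$label, x_auto_ratio = sex$x_auto_ratio,
                         callable_fraction = callable,
                         n_cnv_calls = nrow(cnvs),
                         n_private_cnv_calls = sum(cnvs$private),
                         centromere_private_cnvs =
                           sum(screen$n_private_cnvs))
    report$cnv_calls <- cnvs
    report$centromere_screen <- screen
  }

  report <- structure(report, class = "pipeline_report")
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    if ("filter" %in% config$stages)
      write_vcf(union_pass, file.path(config$outdir, "pass.vcf"))
    if (!is.null(report$ancestry_windows))
      for (f in names(report$ancestry_windows))
        write_ancestry_bed(report$ancestry_windows[[f]],
                           file.path(config$outdir,
                                     sprintf("ancestry_%s.bed", f)))
    if (!is.null(report$cnv_calls))
      write_cnv_bed(report$cnv_calls, file.path(config$outdir, "cnv.bed"))
    for (fmt in c("json", "tsv", "markdown"))
      render_report(report, fmt,
                    file.path(config$outdir,
                              paste0("report.",
                                     c(json = "json", tsv = "tsv",
                                       markdown = "md")[fmt])))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat("  sites:", x$n_sites, "\n")
  if (!is.null(x$filter))
    for (f in names(x$filter))
      cat(sprintf("  filter[%s]: %d/%d pass\n", f, x$filter[[f]]$PASS,
                  x$filter[[f]]$TOTAL))
  if (!is.null(x$catalog))
    cat(sprintf("  catalog: Ts:Tv = %.3f\n", x$catalog$ts_tv_ratio))
  if (!is.null(x$ancestry))
    for (f in names(x$ancestry))
      cat(sprintf("  ancestry[%s]: dom %.1f%%\n", f,
                  100 * x$ancestry[[f]]$fraction[["dom"]]))
  if (!is.null(x$depth))
    cat(sprintf("  depth: sex %s (X:A %.3f), callable %.1f%%, %d CNV call(s)\n",
                x$depth$sex, x$depth$x_auto_ratio,
                100 * x$depth$callable_fraction, x$depth$n_cnv_calls))
  invisible(x)
}

## Flatten a report into an ordered list of scalar key/value pairs; all
## three output formats serialize exactly this, so they agree field by
## field.
flatten_report <- function(report) {
  out <- list()
  put <- function(key, val) out[[key]] <<- val
  put("n_sites", report$n_sites)
  if (!is.null(report$filter))
    for (f in names(report$filter))
      for (k in names(report$filter[[f]]))
        put(paste("filter", f, k, sep = "."), report$filter[[f]][[k]])
  if (!is.null(report$catalog)) {
    cnt <- report$catalog$counts
    for (cat_ in rownames(cnt)) for (cls in colnames(cnt))
      put(paste("catalog", cat_, cls, sep = "."), cnt[cat_, cls])
    put("catalog.ts_count", report$catalog$ts_count)
    put("catalog.tv_count", report$catalog$tv_count)
    put("catalog.ts_tv_ratio", report$catalog$ts_tv_ratio)
  }
  if (!is.null(report$ancestry))
    for (f in names(report$ancestry)) {
      a <- report$ancestry[[f]]
      for (l in names(a$fraction)) {
        put(paste("ancestry", f, "fraction", l, sep = "."), a$fraction[[l]])
        put(paste("ancestry", f, "fraction_bp", l, sep = "."),
            a$fraction_weighted[[l]])
      }
      for (l in names(a$fraction_informative))
        put(paste("ancestry", f, "fraction_informative", l, sep = "."),
            a$fraction_informative[[l]])
      put(paste("ancestry", f, "masked_fraction", sep = "."),
          a$masked_fraction)
      put(paste("ancestry", f, "n_analyzed", sep = "."), a$n_analyzed)
    }
  if (!is.null(report$depth))
    for (k in names(report$depth))
      put(paste("depth", k, sep = "."), report$depth[[k]])
  out
}

#' Render a pipeline report
#'
#' Serializes the scalar content of a report as JSON, TSV or Markdown; the
#' three formats carry numerically identical values.  The Markdown format
#' additionally includes a per-chromosome text table of the ancestry
#' painting.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param format one of `"json"`, `"tsv"`, `"markdown"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, format = c("json", "tsv", "markdown"),
                          path) {
  stopifnot(inherits(report, "pipeline_report"))
  format <- match.arg(format)
  flat <- flatten_report(report)
  if (format == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (format == "tsv") {
    vals <- vapply(flat, function(v)
      if (is.numeric(v)) format(v, digits = 15) else as.character(v), "")
    writeLines(paste(names(flat), vals, sep = "\t"), path)
  } else {
    lines <- c("# Pipeline report", "")
    vals <- vapply(flat, function(v)
      if (is.numeric(v)) format(v, digits = 15) else as.character(v), "")
    lines <- c(lines, "| key | value |", "| --- | --- |",
               sprintf("| %s | %s |", names(flat), vals))
    if (!is.null(report$ancestry_windows)) {
      for (f in names(report$ancestry_windows)) {
        aw <- report$ancestry_windows[[f]]
        tab <- table(aw$chrom, factor(aw$label, levels = ancestry_labels))
        lines <- c(lines, "", sprintf("## Ancestry windows per chromosome (%s)", f),
                   "", paste(c("| chromosome", colnames(tab), ""),
                             collapse = " | "),
                   paste(c("| ---", rep("---", ncol(tab)), ""),
                         collapse = " | "))
        for (ch in rownames(tab))
          lines <- c(lines, paste(c(sprintf("| %s", ch), tab[ch, ], ""),
                                  collapse = " | "))
      }
    }
    writeLines(lines, path)
  }
  invisible(path)
}
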