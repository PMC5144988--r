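test_that("polarization assigns derived alleles via the outgroup", {
  vs <- make_sites("chr1", c(100, 200, 300, 400),
                   ref = "A", alt = c("G", "G", "G", "G,T"))
  vs$gt[, "outgroup"] <- c("0/0", "1/1", "0/1", "0/0")
  vs$gt[, "focal_A"] <- c("1/1", "0/0", "1/1", "1/1")
  pol <- polarize(vs, default_panel())
  # outgroup hom ref -> derived is the alt
  expect_equal(pol$status[1], "ok")
  expect_equal(pol$derived[1], "alt")
  expect_true(pol$focal_has_derived[1])
  # outgroup hom alt -> the REFERENCE allele is derived
  expect_equal(pol$derived[2], "ref")
  expect_true(pol$focal_has_derived[2])  # focal is 0/0 = hom derived here
  # het outgroup is unresolvable
  expect_equal(pol$status[3], "outgroup_unresolved")
  # multiallelic sites are excluded
  expect_equal(pol$status[4], "multiallelic")
})

test_that("exclusive sharing requires exactly one representative", {
  vs <- make_sites("chr1", c(100, 200, 300, 400, 500))
  vs$gt[, "outgroup"] <- "0/0"
  vs$gt[, "focal_A"] <- "1/1"
  vs$gt[, "rep_dom"] <- c("1/1", "1/1", "0/0", "0/0", "./.")
  vs$gt[, "rep_mus"] <- c("0/0", "1/1", "0/0", "0/1", "0/0")
  pol <- polarize(vs, default_panel())
  sh <- exclusive_sharing(pol)
  expect_equal(sh[1], "dom")          # only dom carries the derived allele
  expect_equal(sh[2], "none")         # two sharers: not exclusive
  expect_equal(sh[3], "none")         # nobody shares
  expect_equal(sh[4], "mus")          # het representative still carries it
  expect_true(is.na(sh[5]))           # missing representative: undecidable
})

test_that("window labels follow majority, tie and mask rules", {
  # 36 sites in three 25-kb windows of a 75-kb chromosome
  layout <- genome_layout("chr1", 75000, "autosome")
  win <- make_windows(layout, 25000)
  pos <- c(seq(100, by = 600, length.out = 32),      # window 1: dom-heavy
           25000 + c(100, 200, 300, 400),            # window 2: 2 dom 2 mus
           50000 + seq(100, by = 100, length.out = 0))
  vs <- make_sites("chr1", pos)
  vs$gt[, "outgroup"] <- "0/0"
  vs$gt[, "focal_A"] <- "1/1"
  share <- c(rep("dom", 30), rep("mus", 2), "dom", "dom", "mus", "mus")
  vs$gt[, "rep_dom"] <- ifelse(share == "dom", "1/1", "0/0")
  vs$gt[, "rep_mus"] <- ifelse(share == "mus", "1/1", "0/0")
  aw <- paint_windows(vs, win, panel = default_panel(), min_sites = 4)
  expect_equal(aw$n_dom, c(30L, 2L, 0L))
  expect_equal(aw$n_mus, c(2L, 2L, 0L))
  expect_equal(aw$label, c("dom", "ambiguous", "uninformative"))

  # a mostly-masked window is dropped and carries no counts
  mask <- normalize_mask(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 15000)))
  aw2 <- paint_windows(vs, win, mask, default_panel(), min_sites = 4)
  expect_equal(aw2$label[1], "masked")
  expect_equal(aw2$n_dom[1] + aw2$n_mus[1] + aw2$n_cas[1], 0L)
  expect_equal(aw2$label[-1], aw$label[-1])
})

test_that("sites outside all windows are a coordinate error", {
  layout <- genome_layout("chr1", 50000, "autosome")
  win <- make_windows(layout, 25000)
  vs <- make_sites("chr2", 100)
  vs$gt[, "outgroup"] <- "0/0"
  expect_error(suppressWarnings(paint_windows(vs, win,
                                              panel = default_panel())),
               "outside all windows")
})

test_that("painting matches the brute-force per-site oracle", {
  set.seed(21)
  layout <- genome_layout("chr1", 3e5, "autosome")
  win <- make_windows(layout, 25000)
  n <- 400
  pos <- sort(sample.int(3e5, n))
  vs <- make_sites("chr1", pos)
  vs$gt[, "outgroup"] <- sample(c("0/0", "1/1", "0/1", "./."), n, TRUE,
                                prob = c(0.6, 0.2, 0.1, 0.1))
  vs$gt[, "focal_A"] <- sample(c("1/1", "0/0", "0/1"), n, TRUE,
                               prob = c(0.7, 0.2, 0.1))
  for (r in c("rep_dom", "rep_mus", "rep_cas"))
    vs$gt[, r] <- sample(c("1/1", "0/0", "./."), n, TRUE,
                         prob = c(0.4, 0.5, 0.1))
  mask_df <- data.frame(chrom = "chr1", start = c(0, 150000),
                        end = c(20000, 175000))
  mask <- normalize_mask(GenomicRanges::GRanges(
    mask_df$chrom, IRanges::IRanges(mask_df$start + 1, mask_df$end)))
  aw <- paint_windows(vs, win, mask, default_panel(), min_sites = 3)
  windows_df <- data.frame(chrom = "chr1",
                           start = GenomicRanges::start(win) - 1,
                           end = GenomicRanges::end(win))
  oracle <- oracle_paint(vs, windows_df, mask_df, default_panel(),
                         "focal_A", min_sites = 3)
  expect_equal(aw$n_dom, oracle$n_dom)
  expect_equal(aw$n_mus, oracle$n_mus)
  expect_equal(aw$n_cas, oracle$n_cas)
  expect_equal(aw$label, oracle$label)
})

test_that("per-window bookkeeping identity holds exactly", {
  cfg <- sim_config(layout = sim_layout(n_autosomes = 1,
                                        autosome_length = 5e6,
                                        x_length = 0, mito_length = 0),
                    seed = 17)
  ds <- simulate_dataset(cfg)
  win <- make_windows(cfg$layout, 25000)
  aw <- paint_windows(ds$variants, win, panel = ds$panel)
  # masked windows zero their counts, so restrict to non-masked (none here)
  expect_equal(aw$n_excluded + aw$n_nonderived + aw$n_rep_missing +
                 aw$n_nonexclusive + aw$n_dom + aw$n_mus + aw$n_cas,
               aw$n_sites)
  expect_equal(sum(aw$n_sites), n_sites(ds$variants))
})

test_that("ancestry summary fractions sum to one and track labels", {
  aw <- structure(data.frame(chrom = "chr1",
                             start = seq(0, by = 100, length.out = 100),
                             end = seq(100, by = 100, length.out = 100),
                             label = c(rep("dom", 92), rep("mus", 8))),
                  class = c("ancestry_windows", "data.frame"))
  s <- summarize_ancestry(aw)
  expect_equal(s$fraction[["dom"]], 0.92)
  expect_equal(sum(s$fraction), 1)
  expect_equal(s$masked_fraction, 0)

  one <- structure(data.frame(chrom = "chr1", start = 0, end = 100,
                              label = "cas"),
                   class = c("ancestry_windows", "data.frame"))
  expect_equal(summarize_ancestry(one)$fraction[["cas"]], 1.0)

  all_masked <- structure(data.frame(chrom = "chr1", start = 0, end = 100,
                                     label = "masked"),
                          class = c("ancestry_windows", "data.frame"))
  expect_error(summarize_ancestry(all_masked), "masked")
})

test_that("permuting focal genotypes destroys segment structure", {
  lay <- sim_layout(n_autosomes = 1, autosome_length = 10e6, x_length = 0,
                    mito_length = 0)
  cfg <- sim_config(layout = lay, seed = 8,
                    mosaic_spec = c(dom = 0.5, mus = 0.5),
                    segment_length_mean = 2e6)
  ds <- simulate_dataset(cfg)
  win <- make_windows(lay, 25000)
  aw <- paint_windows(ds$variants, win, panel = ds$panel)
  max_run <- function(aw) {
    r <- rle(aw$label)
    max(r$lengths[r$values %in% c("dom", "mus", "cas")])
  }
  orig <- max_run(aw)
  set.seed(99)
  perm <- ds$variants
  perm$gt[, "focal_A"] <- perm$gt[sample(n_sites(perm)), "focal_A"]
  aw_perm <- paint_windows(perm, win, panel = ds$panel)
  expect_lt(max_run(aw_perm), orig / 2)
})
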