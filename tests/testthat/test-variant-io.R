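write_vcf_text <- function(lines, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"m\">",
           "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"c\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", default_samples), collapse = "\t"))
  writeLines(c(hdr, lines), path)
  path
}

gts <- function(focal_A = "1/1") {
  paste(c(focal_A, rep("0/0", length(default_samples) - 1L)),
        collapse = "\t")
}

test_that("read_vcf parses the supported VCF subset", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(c(
    paste("chr1", 101, ".", "A", "G", ".", ".",
          "DP=50;MQ=40;DP4=10,10,15,15", "GT", gts(), sep = "\t"),
    paste("chr1", 205, ".", "C", "G,T", ".", ".", "DP=60;MQ=35", "GT",
          gts("1/2"), sep = "\t"),
    paste("chr1", 301, ".", "A", "ACCT", ".", ".", "DP=40;MQ=50;DP4=8,8,9,9",
          "GT", gts(), sep = "\t")), f)
  vs <- read_vcf(f, default_panel())
  expect_equal(n_sites(vs), 3L)
  expect_equal(vs$sites$pos, c(101L, 205L, 301L))
  expect_equal(vs$sites$variant_class, c("SNV", "SNV", "indel"))
  expect_equal(vs$sites$multiallelic, c(FALSE, TRUE, FALSE))
  expect_equal(vs$sites$alt_support, c(30, NA, 18))
  expect_equal(vs$sites$dp, c(50, 60, 40))
  expect_equal(nchar(vs$sites$alt[3]) - nchar(vs$sites$ref[3]), 3L)
})

test_that("malformed records are dropped with an accounting trail", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(c(
    paste("chr1", 101, ".", "A", "G", ".", ".", "DP=50;MQ=40", "GT",
          gts(), sep = "\t"),
    paste("chr1", 150, ".", "N", "G", ".", ".", "DP=50;MQ=40", "GT",
          gts(), sep = "\t"),
    paste("chr1", 200, ".", "C", "T", ".", ".", "DP=50;MQ=40", "GT",
          gts(), sep = "\t")), f)
  expect_warning(vs <- read_vcf(f, default_panel()), "malformed")
  # parser never silently drops: in = yielded + malformed
  expect_equal(n_sites(vs) + attr(vs, "n_malformed"), 3L)
  expect_equal(attr(vs, "n_malformed"), 1L)
})

test_that("a required sample missing from the VCF is fatal by name", {
  f <- withr::local_tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "focal_A"), collapse = "\t"),
           paste("chr1", 101, ".", "A", "G", ".", ".", "DP=5", "GT", "1/1",
                 sep = "\t"))
  writeLines(hdr, f)
  expect_error(read_vcf(f, default_panel()), "outgroup")
})

test_that("VCF round-trip is lossless for the supported subset", {
  set.seed(42)
  n <- 60
  chrom <- sort(sample(c("chr1", "chr2"), n, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(i)
    sort(sample.int(1e5, length(i)))), use.names = FALSE)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- ifelse(ref == "C", "A", "C")
  multi <- runif(n) < 0.2
  alt[multi] <- paste0(alt[multi], ",T")
  indel <- !multi & runif(n) < 0.2
  alt[indel] <- paste0(ref[indel], "GATTA")
  dp <- sample(10:90, n, replace = TRUE)
  mq <- round(runif(n, 10, 60), 2)
  alt_support <- sample(0:9, n, replace = TRUE)
  dp[1:3] <- NA; mq[4:6] <- NA
  alt_support[is.na(dp)] <- NA
  gt <- matrix(sample(c("0/0", "0/1", "1/1", "./."), n * 9, replace = TRUE),
               n, 9, dimnames = list(NULL, default_samples))
  gt[multi, 1] <- "2/2"
  vs <- variant_set(data.frame(chrom = chrom, pos = pos, ref = ref,
                               alt = alt, dp = dp, mq = mq,
                               alt_support = alt_support), gt)
  filt <- sample(c("PASS", "LOW_DP;LOW_MQ", "NOT_HOMOZYGOUS"), n,
                 replace = TRUE)

  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vs, f, filter = filt)
  back <- read_vcf(f, default_panel())
  expect_equal(back$sites$chrom, vs$sites$chrom)
  expect_equal(back$sites$pos, vs$sites$pos)
  expect_equal(back$sites$ref, vs$sites$ref)
  expect_equal(back$sites$alt, vs$sites$alt)
  expect_equal(back$sites$dp, vs$sites$dp)
  expect_equal(back$sites$mq, vs$sites$mq)
  expect_equal(back$sites$alt_support, vs$sites$alt_support)
  expect_equal(back$sites$filter, filt)
  expect_identical(back$gt, vs$gt)

  # gzip transparency
  fgz <- withr::local_tempfile(fileext = ".vcf.gz")
  write_vcf(vs, fgz, filter = filt)
  expect_equal(read_vcf(fgz, default_panel())$sites$pos, vs$sites$pos)
})

test_that("an empty variant set writes a valid header-only VCF", {
  vs <- variant_set(data.frame(chrom = character(), pos = integer(),
                               ref = character(), alt = character()),
                    matrix(character(), 0, 9,
                           dimnames = list(NULL, default_samples)))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vs, f)
  back <- read_vcf(f)
  expect_equal(n_sites(back), 0L)
})

test_that("genotype string helpers classify GT codes", {
  expect_equal(gt_code(c("0/0", "0/1", "1/1", "2/2", "./.", "1|0")),
               c("hom_ref", "het", "hom_alt", "hom_alt", "missing", "het"))
})

test_that("depth tracks are validated row by row", {
  df <- data.frame(chrom = "chr1", start = c(0, 25000, 50000),
                   end = c(25000, 50000, 75000),
                   depth_mq20 = c(18, 17, 19), depth_total = c(20, 18, 20))
  tr <- depth_track(df, layout = tiny_layout())
  expect_s3_class(tr, "depth_track")
  expect_equal(nrow(tr), 3L)

  bad <- df; bad$depth_mq20[2] <- 30
  expect_error(depth_track(bad), "row 2")
  neg <- df; neg$depth_total[3] <- -1
  expect_error(depth_track(neg), "row 3")
  out <- df; out$end[3] <- 2e6
  expect_error(depth_track(out, layout = tiny_layout()), "outside")

  f <- withr::local_tempfile(fileext = ".tsv")
  write_depth_track(tr, f)
  back <- read_depth_track(f, layout = tiny_layout(), sample = "sample")
  expect_equal(as.data.frame(back), as.data.frame(tr))

  # empty file with header -> empty track
  writeLines("chromosome\tstart\tend\tdepth_mq20\tdepth_total", f)
  expect_equal(nrow(read_depth_track(f)), 0L)
})
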