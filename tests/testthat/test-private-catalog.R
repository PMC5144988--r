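panel3 <- function() {
  sample_panel(focal = c("focal_A", "focal_B"),
               representatives = c(dom = "rep_dom", mus = "rep_mus",
                                   cas = "rep_cas"),
               outgroup = "outgroup",
               known_panel = c("known_1", "known_2", "known_3"))
}

set_gts <- function(vs, ...) {
  for (nm in names(list(...))) vs$gt[, nm] <- list(...)[[nm]]
  vs
}

test_that("privacy categories follow the allele-absence definition", {
  vs <- make_sites("chr1", 100)
  p <- panel3()
  # alt carried by focal A only, absent from B and the whole panel
  expect_equal(classify_site(set_gts(vs, focal_A = "1/1", focal_B = "0/0"),
                             p), "private_A")
  # both focal strains homozygous alt, panel clean
  expect_equal(classify_site(set_gts(vs, focal_A = "1/1", focal_B = "1/1"),
                             p), "shared_exclusive")
  # one panel strain carries the alt: known regardless of focal genotypes
  expect_equal(classify_site(set_gts(vs, focal_A = "1/1", focal_B = "1/1",
                                     known_2 = "0/1"), p), "known")
  expect_equal(classify_site(set_gts(vs, focal_A = "0/0", focal_B = "1/1",
                                     known_1 = "1/1"), p), "known")
  # a missing panel genotype with no panel hit is undecidable
  expect_equal(classify_site(set_gts(vs, focal_A = "1/1",
                                     known_3 = "./."), p),
               "unclassifiable")
})

test_that("classification matches the exhaustive truth table", {
  p <- panel3()
  states <- c("0/0", "0/1", "1/1", "./.")
  grid <- expand.grid(gA = states, gB = states, p1 = states, p2 = states,
                      p3 = states, stringsAsFactors = FALSE)
  n <- nrow(grid)
  gt <- matrix("0/0", n, length(default_samples),
               dimnames = list(NULL, default_samples))
  gt[, "focal_A"] <- grid$gA
  gt[, "focal_B"] <- grid$gB
  gt[, "known_1"] <- grid$p1
  gt[, "known_2"] <- grid$p2
  gt[, "known_3"] <- grid$p3
  vs <- variant_set(data.frame(chrom = "chr1", pos = seq_len(n),
                               ref = "A", alt = "G"), gt)
  got <- classify_variants(vs, p)$category
  expected <- vapply(seq_len(n), function(i)
    oracle_classify(grid$gA[i], grid$gB[i],
                    c(grid$p1[i], grid$p2[i], grid$p3[i])), character(1))
  expect_identical(got, expected)
})

test_that("swapping focal labels swaps the private categories only", {
  set.seed(12)
  n <- 200
  states <- c("0/0", "0/1", "1/1", "./.")
  gt <- matrix("0/0", n, length(default_samples),
               dimnames = list(NULL, default_samples))
  for (s in c("focal_A", "focal_B", "known_1", "known_2", "known_3"))
    gt[, s] <- sample(states, n, replace = TRUE)
  vs <- variant_set(data.frame(chrom = "chr1", pos = seq_len(n), ref = "C",
                               alt = "T"), gt)
  fwd <- table(classify_variants(vs, panel3())$category)
  swapped <- sample_panel(focal = c("focal_B", "focal_A"),
                          representatives = c(dom = "rep_dom",
                                              mus = "rep_mus",
                                              cas = "rep_cas"),
                          outgroup = "outgroup",
                          known_panel = c("known_1", "known_2", "known_3"))
  rev <- table(classify_variants(vs, swapped)$category)
  getc <- function(tb, k) if (k %in% names(tb)) unname(tb[[k]]) else 0L
  expect_equal(getc(fwd, "private_A"), getc(rev, "private_B"))
  expect_equal(getc(fwd, "private_B"), getc(rev, "private_A"))
  expect_equal(getc(fwd, "shared_exclusive"), getc(rev, "shared_exclusive"))
  expect_equal(getc(fwd, "known"), getc(rev, "known"))
})

test_that("every call lands in exactly one category", {
  set.seed(3)
  vs <- random_filter_sites(300, seed = 3)
  calls <- classify_variants(vs, panel3())
  expect_equal(nrow(calls), n_sites(vs))  # all biallelic here
  expect_true(all(calls$category %in% c("private_A", "private_B",
                                        "shared_exclusive", "known",
                                        "unclassifiable")))
  expect_equal(sum(table(calls$category)), nrow(calls))
})

test_that("transitions and transversions are told apart", {
  expect_true(is_transition("A", "G"))
  expect_true(is_transition("C", "T"))
  expect_true(is_transition("T", "C"))
  expect_false(is_transition("A", "T"))
  expect_false(is_transition("G", "C"))
  expect_error(is_transition("A", "A"), "differ")
  expect_error(is_transition("AC", "A"), "single-base")
})

test_that("catalog summary computes Ts:Tv over novel SNVs", {
  # 12 transitions + 6 transversions, all private -> ratio exactly 2.0
  ref <- c(rep("A", 12), rep("A", 6))
  alt <- c(rep("G", 12), rep("T", 6))
  vs <- make_sites("chr1", seq(100, by = 10, length.out = 18),
                   ref = ref, alt = alt)
  calls <- classify_variants(vs, panel3())
  s <- summarize_catalog(vs, calls)
  expect_identical(s$ts_count, 12L)
  expect_identical(s$tv_count, 6L)
  expect_identical(s$ts_tv_ratio, 2.0)
  expect_equal(unname(s$counts["private_A", "SNV"]), 18)

  # permuting input order leaves all catalog counts unchanged
  perm <- sample(n_sites(vs))
  vs2 <- vs[perm]
  s2 <- summarize_catalog(vs2, classify_variants(vs2, panel3()))
  expect_identical(s2$counts, s$counts)
  expect_identical(s2$ts_tv_ratio, s$ts_tv_ratio)

  # empty input: zero counts, undefined ratio
  empty <- vs[integer(0)]
  s0 <- summarize_catalog(empty, classify_variants(empty, panel3()))
  expect_true(all(s0$counts == 0))
  expect_identical(s0$tv_count, 0L)
  expect_true(is.nan(s0$ts_tv_ratio))
})

test_that("counts land in the right category-by-class cells", {
  vs <- make_sites("chr1", c(100, 200, 300),
                   ref = c("A", "A", "C"), alt = c("G", "T", "CAT"))
  vs$gt[, "focal_A"] <- c("1/1", "1/1", "0/0")
  vs$gt[, "focal_B"] <- c("0/0", "0/0", "1/1")
  s <- summarize_catalog(vs, classify_variants(vs, panel3()))
  expect_equal(unname(s$counts["private_A", "SNV"]), 2)
  expect_equal(unname(s$counts["private_B", "indel"]), 1)
  expect_equal(sum(s$counts), 3)
})

test_that("known panels of any size work, including none", {
  vs <- make_sites("chr1", 100)
  no_panel <- sample_panel(focal = c("focal_A", "focal_B"),
                           representatives = c(dom = "rep_dom",
                                               mus = "rep_mus",
                                               cas = "rep_cas"),
                           outgroup = "outgroup")
  expect_equal(classify_site(vs, no_panel), "private_A")
})
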