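# build a one-site pileup row
pileup_row <- function(site, ref, counts_fwd, counts_rev, quals = NULL) {
  b <- c("A", "C", "G", "T")
  if (is.null(quals)) quals <- setNames(rep(30, 4), b)
  row <- data.frame(site = site, ref = ref, stringsAsFactors = FALSE)
  for (x in b) row[[paste0(x, "_fwd")]] <- counts_fwd[[x]]
  for (x in b) row[[paste0(x, "_rev")]] <- counts_rev[[x]]
  for (x in b) row[[paste0(x, "_qual")]] <-
    if (counts_fwd[[x]] + counts_rev[[x]] > 0) quals[[x]] else NA_real_
  row
}
cnt <- function(A = 0, C = 0, G = 0, T = 0) list(A = A, C = C, G = G, T = T)

test_that("binomial support filters match exact tail probabilities", {
  # 10 alt reads of 1000 at Q30 (p_err 0.001): overwhelming support
  f <- binomial_filters(10, 1000, mean_qual = 30)
  expect_true(f$pass)
  expect_lt(f$p_rate, 1e-6)
  expect_equal(f$p_rate, 1 - pbinom(9, 1000, 1e-3), tolerance = 1e-6)
  # a single alt read is what error alone produces
  f1 <- binomial_filters(1, 1000, mean_qual = 30)
  expect_false(f1$pass)
  expect_equal(f1$p_rate, 1 - 0.999^1000, tolerance = 1e-12)
  # no alt reads: tail probability 1
  f0 <- binomial_filters(0, 1000, mean_qual = 30)
  expect_equal(f0$p_rate, 1)
  expect_false(f0$pass)
  # monotonicity: more alt reads never flips pass -> fail
  p <- vapply(0:50, function(k)
    binomial_filters(k, 1000, mean_qual = 30)$p_rate, numeric(1))
  expect_true(all(diff(p) <= 1e-15))
})

test_that("the five filters give the documented verdicts", {
  # strand support: 2 forward / 5 reverse at 7% MAF
  v1 <- call_variants(pileup_row(100L, "A", cnt(A = 48, G = 2),
                                 cnt(A = 45, G = 5)))
  expect_equal(v1$filters_failed, "strand_support")
  expect_false(v1$pass)
  # repeat region: site 305 (303-311)
  v2 <- call_variants(pileup_row(305L, "C", cnt(C = 475, T = 25),
                                 cnt(C = 475, T = 25)))
  expect_equal(v2$filters_failed, "repeat_region")
  # oxidation: C>A at 8% fails, at 15% passes the oxidation rule
  v3 <- call_variants(pileup_row(2000L, "C", cnt(C = 460, A = 40),
                                 cnt(C = 460, A = 40)))
  expect_equal(v3$filters_failed, "oxidation")
  v4 <- call_variants(pileup_row(2000L, "C", cnt(C = 425, A = 75),
                                 cnt(C = 425, A = 75)))
  expect_true(v4$pass)
  expect_equal(v4$filters_failed, "")
  expect_equal(v4$maf, 0.15)
  # MAF floor
  v5 <- call_variants(pileup_row(2000L, "G", cnt(G = 996, A = 4),
                                 cnt(G = 996, A = 4)))
  expect_true(grepl("maf_floor", v5$filters_failed))
  # several filters can fail together; all reasons recorded
  v6 <- call_variants(pileup_row(305L, "C", cnt(C = 480, A = 20),
                                 cnt(C = 490, A = 10)))
  expect_setequal(strsplit(v6$filters_failed, ",")[[1L]],
                  c("repeat_region", "oxidation"))
})

test_that("quality-aware support uses only confident calls", {
  # alt supported only by low-quality calls fails the quality test
  v <- call_variants(pileup_row(5000L, "T", cnt(T = 480, C = 20),
                                cnt(T = 480, C = 20),
                                quals = c(A = NA, C = 15, G = NA, T = 33)))
  expect_true(grepl("binomial", v$filters_failed))
  expect_gt(v$p_quality, 0.001)
  # same counts at high quality pass
  v2 <- call_variants(pileup_row(5000L, "T", cnt(T = 480, C = 20),
                                 cnt(T = 480, C = 20)))
  expect_true(v2$pass)
})

test_that("pileups round-trip through TSV and MAF is as defined", {
  ref <- toy_reference(100, seed = 8)
  pu <- simulate_pileup(ref, depth = 50L, error_rate = 0, seed = 3)
  b <- c("A", "C", "G", "T")
  m <- as.matrix(pu[, paste0(b, "_fwd")]) + as.matrix(pu[, paste0(b, "_rev")])
  expect_true(all(m[cbind(1:100, match(ref$chars, b))] == 50))
  path <- tempfile(fileext = ".tsv")
  write_pileup_tsv(pu, path)
  expect_equal(read_pileup(path), pu, tolerance = 1e-12)
  expect_equal(nrow(call_variants(pu)), 0L)   # no minor alleles anywhere
})

test_that("origin classification follows the paired-tissue definitions", {
  variant_frame_for_test <- function(sites, alts)
    data.frame(site = sites, ref = "A", alt = alts, maf = 0.1,
               fwd_alt = 10, rev_alt = 10, depth = 200, p_rate = 0,
               p_quality = 0, pass = TRUE, filters_failed = "",
               stringsAsFactors = FALSE)
  tumor <- variant_frame_for_test(c(100L, 200L, 300L), c("C", "G", "T"))
  leu <- variant_frame_for_test(c(200L, 300L), c("G", "T"))
  par <- variant_frame_for_test(300L, "T")
  out <- classify_origin(tumor, leu, par)
  expect_equal(out$origin,
               c("tumor_derived", "somatic_unclassified", "germline"))
  expect_warning(o2 <- classify_origin(tumor, leu, NULL), "missing")
  expect_true(all(is.na(o2$origin)))
})

test_that("copy number is the diploid-normalized depth ratio", {
  expect_equal(copy_number(5000, 10), 1000)
  expect_equal(copy_number(7, 7), 2)
  expect_error(copy_number(10, 0), "> 0")
})

test_that("allele subsets partition the covering fragments", {
  ref <- toy_reference(400, seed = 9)
  fs <- FragmentSet(start = c(10L, 50L, 80L, 380L, 200L),
                    length = c(100L, 60L, 40L, 40L, 50L), L = 400L,
                    alt_site = c(100L, 100L, 100L, NA, NA),
                    alt_base = c("T", "T", NA, NA, NA))
  sub <- fragment_subsets_by_allele(fs, 100L, "T")
  expect_equal(n_fragments(sub$alt), 2L)
  expect_equal(n_fragments(sub$ref), 1L)   # fragment 80..119 covers, untagged
  # wrap coverage: site 5 is covered by the 380..419 fragment
  subw <- fragment_subsets_by_allele(fs, 5L, "T")
  expect_equal(n_fragments(subw$alt) + n_fragments(subw$ref), 1L)
  expect_error(fragment_subsets_by_allele(fs, 300L, "T"), "cover")
})
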