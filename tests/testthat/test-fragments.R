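test_that("BED fragment tables convert coordinates and round-trip", {
  ref <- toy_reference(1000)
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chrM\t100\t200\t+\ts1",
               "chrM\t0\t50\t-\ts1",
               "chrM\t995\t1003\t+\ts1"), bed)   # last row wraps the origin
  fs <- read_fragments_bed(bed, ref, sample_id = "s1")
  expect_equal(fs$frags$start, c(101L, 1L, 996L))
  expect_equal(fs$frags$end, c(200L, 50L, 1003L))
  expect_equal(fs$frags$length, c(100L, 50L, 8L))
  out <- tempfile(fileext = ".bed")
  write_fragments_bed(fs, out)
  fs2 <- read_fragments_bed(out, ref, sample_id = "s1")
  expect_equal(fs2$frags, fs$frags)
})

test_that("malformed BED rows are skipped with a warning", {
  ref <- toy_reference(1000)
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chrM\t100\t200\t+\ts1",
               "chrM\t300\t250\t+\ts1",      # negative length
               "chrM\txx\t250\t+\ts1"), bed) # non-numeric
  expect_warning(fs <- read_fragments_bed(bed, ref), "2 malformed")
  expect_equal(n_fragments(fs), 1L)
})

test_that("5' end bases and motifs follow the strand convention", {
  ref <- MtReference(paste0("ACGT", strrep("A", 16), "GGCC"))  # L = 24
  fs <- FragmentSet(start = 1L, length = 10L, L = 24L)
  e <- five_prime_ends(fs, ref)
  expect_equal(e$light_base, "A")
  expect_equal(e$light_motif, "ACGT")
  # heavy end at site 10 (ref 'A'): complementary base, revcomp motif
  expect_equal(e$heavy_site, 10L)
  expect_equal(e$heavy_base, "T")
  expect_equal(e$heavy_motif, "TTTT")
  # heavy motif wrapping through the origin: fragment ending at site 24
  fs2 <- FragmentSet(start = 15L, length = 10L, L = 24L)
  e2 <- five_prime_ends(fs2, ref)
  expect_equal(e2$heavy_site, 24L)
  # ref 4-mer ending at 24 is "GCC|C"? sites 21..24 = "GGCC" -> revcomp GGCC
  expect_equal(e2$heavy_motif, "GGCC")
  # light motif of a fragment starting at 23 wraps into the head
  fs3 <- FragmentSet(start = 23L, length = 8L, L = 24L)
  e3 <- five_prime_ends(fs3, ref)
  expect_equal(e3$light_motif, "CCAC")  # sites 23,24,1,2
  # fragments shorter than 4 bp have no motif
  fs4 <- FragmentSet(start = 5L, length = 3L, L = 24L)
  expect_true(is.na(five_prime_ends(fs4, ref)$light_motif))
})

test_that("reverse-complementing the genome swaps light and heavy ends", {
  ref <- toy_reference(60, seed = 4)
  rc <- MtReference(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ref$sequence))), name = "rc")
  for (st in c(3L, 20L, 55L)) {
    len <- 12L
    fs <- FragmentSet(start = st, length = len, L = 60L)
    e <- five_prime_ends(fs, ref)
    # the same molecule on the flipped assembly
    en <- ((st + len - 2L) %% 60L) + 1L
    st_rc <- 60L - en + 1L
    fs_rc <- FragmentSet(start = st_rc, length = len, L = 60L)
    e_rc <- five_prime_ends(fs_rc, rc)
    expect_equal(e_rc$light_base, e$heavy_base)
    expect_equal(e_rc$heavy_base, e$light_base)
    expect_equal(e_rc$light_motif, e$heavy_motif)
    expect_equal(e_rc$heavy_motif, e$light_motif)
  }
})

test_that("BAM templates are paired, filtered on MAPQ and flags", {
  ref <- toy_reference(1000, seed = 2)
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:toy\tLN:1000")
  seq50 <- strrep("A", 50)
  q50 <- strrep("I", 50)
  row <- function(name, flag, pos, mapq, mpos, isize)
    paste(name, flag, "toy", pos, mapq, "50M", "=", mpos, isize,
          seq50, q50, sep = "\t")
  writeLines(c(
    hdr,
    row("good", 99, 101, 60, 151, 100), row("good", 147, 151, 60, 101, -100),
    row("lowq", 99, 301, 60, 351, 100), row("lowq", 147, 351, 19, 301, -100),
    row("dup", 1123, 501, 60, 551, 100), row("dup", 1171, 551, 60, 501, -100)
  ), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  fs <- read_fragments_bam(bam, ref, min_mapq = 20L)
  expect_equal(n_fragments(fs), 1L)   # lowq mate and duplicate pair removed
  expect_equal(fs$frags$start, 101L)
  expect_equal(fs$frags$end, 200L)
  expect_equal(fs$frags$length, 100L)
  # reference length mismatch is rejected
  expect_error(read_fragments_bam(bam, toy_reference(999)), "length")
})

test_that("coverage conserves total fragment length, wraps included", {
  ref <- toy_reference(500, seed = 3)
  set.seed(11)
  st <- sample.int(500L, 300L, replace = TRUE)
  len <- sample(20:120, 300L, replace = TRUE)
  fs <- FragmentSet(st, len, L = 500L)
  expect_equal(sum(site_depths(fs)$depth), sum(len))
})

test_that("downsampling is exact, seeded and bounded", {
  ref <- toy_reference(500)
  fs <- FragmentSet(rep(1:100, 10), rep(50L, 1000L), L = 500L)
  expect_identical(downsample(fs, fraction = 1), fs)
  d1 <- downsample(fs, fraction = 0.5, seed = 7)
  d2 <- downsample(fs, fraction = 0.5, seed = 7)
  d3 <- downsample(fs, fraction = 0.5, seed = 8)
  expect_equal(n_fragments(d1), 500L)
  expect_identical(d1$frags, d2$frags)
  expect_false(identical(d1$frags, d3$frags))
  expect_error(downsample(fs, fraction = 1.5), "fraction")
  # target_mean_depth converts through the current mean depth
  d4 <- downsample(fs, target_mean_depth = 50, seed = 1)
  expect_equal(n_fragments(d4), 500L)   # current mean depth is 100x
})

test_that("region assignment counts only 5' ends inside the region", {
  ann <- data.frame(name = "D-loop", class = "D-loop",
                    start = 450L, end = 50L, sub_region = "",
                    stringsAsFactors = FALSE)
  expect_equal(assign_region(c(470L, 30L), ann, 500L),
               c("D-loop", "D-loop"))
  expect_true(is.na(assign_region(200L, ann, 500L)))
})
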