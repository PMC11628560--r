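#' Default repeat-region filter intervals
#'
#' Homopolymer and repeat tracts of the human mitochondrial genome in which
#' apparent heteroplasmies are removed: 66-71, 303-311, 514-523,
#' 12418-12425 and 16184-16193 (rCRS coordinates). For a reference genome
#' in a different coordinate frame, supply the matching intervals to
#' [call_variants()] instead.
#'
#' @return two-column integer matrix of closed intervals.
#' @export
mt_repeat_regions <- function() {
  cbind(start = c(66L, 303L, 514L, 12418L, 16184L),
        end = c(71L, 311L, 523L, 12425L, 16193L))
}

#' Per-site allele counts (pileup) I/O
#'
#' The pileup table is the plain-text interface between alignment data and
#' the variant caller: one row per covered site with strand-split counts of
#' the four bases and the mean Phred quality of the calls for each base.
#' Columns: `site`, `ref`, `A_fwd`..`T_fwd`, `A_rev`..`T_rev`,
#' `A_qual`..`T_qual` (mean Phred, `NA` when the base was never called).
#'
#' @param path pileup TSV path.
#' @return data.frame of allele counts.
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) stop("pileup not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", quote = "")
  need <- pileup_columns()
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("pileup lacks columns: ", paste(miss, collapse = ", "))
  tab
}

#' @rdname read_pileup
#' @param counts allele-count data.frame.
#' @export
write_pileup_tsv <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pileup_columns <- function() {
  c("site", "ref",
    paste0(rep(c("A", "C", "G", "T"), 2), "_",
           rep(c("fwd", "rev"), each = 4)),
    paste0(c("A", "C", "G", "T"), "_qual"))
}

# total depth and per-base counts of one pileup row block (vectorized)
base_counts <- function(counts, strand = c("both", "fwd", "rev")) {
  strand <- match.arg(strand)
  b <- c("A", "C", "G", "T")
  sel <- switch(strand,
                both = sapply(b, function(x)
                  counts[[paste0(x, "_fwd")]] + counts[[paste0(x, "_rev")]]),
                fwd = sapply(b, function(x) counts[[paste0(x, "_fwd")]]),
                rev = sapply(b, function(x) counts[[paste0(x, "_rev")]]))
  matrix(sel, ncol = 4L, dimnames = list(NULL, b))
}

#' Binomial support filters for a candidate heteroplasmy
#'
#' Two one-sided binomial tail tests, both of which must reach
#' `P <= alpha` for the call to pass.
#'
#' The mutant-rate test asks whether the number of mutant reads exceeds
#' what per-base sequencing error would produce:
#' `P(X >= alt_count | n = depth, p = p_err)` with `p_err` the mean
#' Phred-implied error probability over the site's base calls.
#'
#' The mutant-base-quality test repeats the same tail test restricted to
#' high-quality calls (Phred >= `hq_threshold`): a real variant remains
#' supported when only confident base calls are counted, whereas an
#' artifact carried by low-quality calls loses its support. Under uniform
#' qualities the two tests coincide.
#'
#' @param alt_count mutant read count at the site (both strands).
#' @param depth total read count at the site.
#' @param mean_qual mean Phred quality over all calls at the site.
#' @param alt_hq_count,depth_hq counts restricted to calls with Phred >=
#'   `hq_threshold`; default the full counts (uniform-quality data).
#' @param hq_qual mean Phred quality of the high-quality calls (default
#'   `max(mean_qual, hq_threshold)`).
#' @param alpha significance level (default 0.001).
#' @param hq_threshold Phred cutoff defining high-quality calls (default 30).
#' @return list with `pass`, `p_rate`, `p_quality`.
#' @export
binomial_filters <- function(alt_count, depth, mean_qual = 30,
                             alt_hq_count = alt_count, depth_hq = depth,
                             hq_qual = max(mean_qual, hq_threshold),
                             alpha = 0.001, hq_threshold = 30) {
  stopifnot(depth >= alt_count, alt_count >= 0)
  if (depth == 0) stop("zero depth")
  p_err <- 10^(-mean_qual / 10)
  p_rate <- pbinom(alt_count - 1L, depth, p_err, lower.tail = FALSE)
  if (depth_hq > 0) {
    p_err_hq <- 10^(-hq_qual / 10)
    p_quality <- pbinom(alt_hq_count - 1L, depth_hq, p_err_hq,
                        lower.tail = FALSE)
  } else {
    p_quality <- 1
  }
  list(pass = (p_rate <= alpha) && (p_quality <= alpha),
       p_rate = p_rate, p_quality = p_quality)
}

#' Call filtered mitochondrial heteroplasmies from allele counts
#'
#' At each covered site the major allele is the most frequent base and the
#' minor allele the second most frequent; the minor allele frequency (MAF)
#' is minor count over depth. A candidate call passes when all filters
#' hold:
#' \enumerate{
#'   \item strand support: at least `min_strand_reads` mutant reads on each
#'     strand;
#'   \item MAF floor: MAF at least `min_maf`;
#'   \item repeat regions: the site lies outside the supplied repeat
#'     intervals;
#'   \item oxidation: C>A / G>T substitutions with MAF below `oxo_maf` are
#'     removed (guanine-oxidation artifacts of library preparation);
#'   \item binomial support: mutant rate and mutant base quality both pass
#'     the binomial test at `alpha` (see [binomial_filters()]).
#' }
#' Failed calls are retained with their failure reasons rather than
#' dropped, so filter behaviour is auditable.
#'
#' @param counts pileup data.frame (see [read_pileup()]).
#' @param min_strand_reads filter 1 threshold (default 3).
#' @param min_maf filter 2 threshold (default 0.01).
#' @param repeat_regions two-column matrix of closed intervals (default
#'   [mt_repeat_regions()]).
#' @param oxo_maf filter 4 threshold (default 0.10).
#' @param alpha filter 5 significance level (default 0.001).
#' @param hq_threshold Phred cutoff for the quality test (default 30).
#' @return data.frame with one row per site carrying a non-zero minor
#'   allele: `site`, `ref`, `alt`, `maf`, `fwd_alt`, `rev_alt`, `depth`,
#'   `p_rate`, `p_quality`, `pass`, `filters_failed` (comma-separated
#'   labels among strand_support, maf_floor, repeat_region, oxidation,
#'   binomial).
#' @export
call_variants <- function(counts, min_strand_reads = 3L, min_maf = 0.01,
                          repeat_regions = mt_repeat_regions(),
                          oxo_maf = 0.10, alpha = 0.001,
                          hq_threshold = 30) {
  if (!nrow(counts)) return(variant_frame())
  bc <- base_counts(counts, "both")
  fwd <- base_counts(counts, "fwd")
  rev <- base_counts(counts, "rev")
  depth <- rowSums(bc)
  keep <- depth > 0
  out <- vector("list", sum(keep))
  j <- 0L
  bases <- c("A", "C", "G", "T")
  in_repeat <- function(site) {
    any(site >= repeat_regions[, 1L] & site <= repeat_regions[, 2L])
  }
  for (i in which(keep)) {
    cnt <- bc[i, ]
    ord <- order(cnt, decreasing = TRUE)
    major <- bases[ord[1L]]
    minor <- bases[ord[2L]]
    minor_n <- cnt[ord[2L]]
    if (minor_n == 0) next
    refb <- counts$ref[i]
    # substitution reported ref -> alt: the non-reference side of the pair
    alt <- if (minor != refb) minor else major
    maf <- minor_n / depth[i]
    qual <- counts[[paste0(alt, "_qual")]][i]
    site_quals <- vapply(bases, function(b) counts[[paste0(b, "_qual")]][i],
                         numeric(1))
    mean_qual <- sum(site_quals * cnt, na.rm = TRUE) /
      sum(cnt[!is.na(site_quals)])
    alt_n <- cnt[alt]
    # quality split: calls of a base are at its mean Phred; a base whose
    # mean is below the cutoff contributes no high-quality calls
    hq_of <- function(b) if (!is.na(site_quals[b]) &&
                             site_quals[b] >= hq_threshold) cnt[b] else 0
    depth_hq <- sum(vapply(bases, hq_of, numeric(1)))
    alt_hq <- hq_of(alt)
    bf <- binomial_filters(
      alt_count = alt_n, depth = depth[i], mean_qual = mean_qual,
      alt_hq_count = alt_hq, depth_hq = depth_hq,
      hq_qual = if (depth_hq > 0)
        sum(vapply(bases, function(b) hq_of(b) * site_quals[b], numeric(1)),
            na.rm = TRUE) / depth_hq else hq_threshold,
      alpha = alpha, hq_threshold = hq_threshold)
    failed <- character()
    if (fwd[i, alt] < min_strand_reads || rev[i, alt] < min_strand_reads)
      failed <- c(failed, "strand_support")
    if (maf < min_maf) failed <- c(failed, "maf_floor")
    if (in_repeat(counts$site[i])) failed <- c(failed, "repeat_region")
    sub <- paste0(refb, ">", alt)
    if (sub %in% c("C>A", "G>T") && maf < oxo_maf)
      failed <- c(failed, "oxidation")
    if (!bf$pass) failed <- c(failed, "binomial")
    j <- j + 1L
    out[[j]] <- data.frame(
      site = counts$site[i], ref = refb, alt = alt, maf = maf,
      fwd_alt = fwd[i, alt], rev_alt = rev[i, alt], depth = depth[i],
      p_rate = bf$p_rate, p_quality = bf$p_quality,
      pass = !length(failed),
      filters_failed = paste(failed, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!j) return(variant_frame())
  res <- do.call(rbind, out[seq_len(j)])
  rownames(res) <- NULL
  res
}

variant_frame <- function() {
  data.frame(site = integer(), ref = character(), alt = character(),
             maf = numeric(), fwd_alt = numeric(), rev_alt = numeric(),
             depth = numeric(), p_rate = numeric(), p_quality = numeric(),
             pass = logical(), filters_failed = character(),
             stringsAsFactors = FALSE)
}

#' Classify variant origin against paired tissue calls
#'
#' Tumor-derived variants are present in fresh tumor tissue but in neither
#' paired leukocytes nor para-tumor tissue; germline variants are present
#' in tumor tissue and in both paired controls. Tumor variants matching
#' only one control are `somatic_unclassified`. Variant sets are keyed by
#' `(site, alt)` on passing calls.
#'
#' @param tumor_calls variant data.frame from [call_variants()] for the
#'   tumor sample.
#' @param leukocyte_calls,paratumor_calls paired control call sets; with
#'   either `NULL`, classification is skipped (all origins `NA`) with a
#'   warning.
#' @return `tumor_calls` restricted to passing rows, with an `origin`
#'   column in \{tumor_derived, germline, somatic_unclassified\}.
#' @export
classify_origin <- function(tumor_calls, leukocyte_calls = NULL,
                            paratumor_calls = NULL) {
  tum <- tumor_calls[tumor_calls$pass, , drop = FALSE]
  key <- function(x) paste(x$site, x$alt, sep = ":")
  if (is.null(leukocyte_calls) || is.null(paratumor_calls)) {
    warning("missing paired control call set; origin not classified")
    tum$origin <- NA_character_
    return(tum)
  }
  in_leu <- key(tum) %in% key(leukocyte_calls[leukocyte_calls$pass, ])
  in_par <- key(tum) %in% key(paratumor_calls[paratumor_calls$pass, ])
  tum$origin <- ifelse(!in_leu & !in_par, "tumor_derived",
                       ifelse(in_leu & in_par, "germline",
                              "somatic_unclassified"))
  tum
}

#' Relative mitochondrial DNA copy number
#'
#' `CN = 2 * mean mtDNA depth / mean nuclear reference depth`: mtDNA copies
#' per diploid nuclear genome equivalent.
#'
#' @param mean_mt_depth mean sequencing depth over the mitochondrial
#'   genome.
#' @param mean_nuclear_depth mean depth of the nuclear reference locus.
#' @return copy number estimate.
#' @export
copy_number <- function(mean_mt_depth, mean_nuclear_depth) {
  if (mean_nuclear_depth <= 0) stop("nuclear reference depth must be > 0")
  2 * mean_mt_depth / mean_nuclear_depth
}

#' Split covering fragments by carried allele
#'
#' Partitions the fragments covering a variant site into those tagged with
#' the alternate allele and the remaining (wild-type) covering fragments,
#' enabling size and end-feature comparisons between mutant and wild-type
#' molecules.
#'
#' @param fs a [FragmentSet] whose fragments carry `alt_site`/`alt_base`
#'   tags.
#' @param site variant site.
#' @param alt alternate base.
#' @return list of two [FragmentSet]s, `alt` and `ref`.
#' @export
fragment_subsets_by_allele <- function(fs, site, alt) {
  L <- fs$L
  st <- fs$frags$start
  en <- fs$frags$end
  covers <- (site >= st & site <= en) |
    (site + L >= st & site + L <= en)     # wrap: site seen past the origin
  if (!any(covers)) stop("no fragments cover site ", site)
  is_alt <- covers & !is.na(fs$frags$alt_site) & !is.na(fs$frags$alt_base)
  is_alt[is_alt] <- fs$frags$alt_site[is_alt] == site &
    fs$frags$alt_base[is_alt] == alt
  subset_fs <- function(sel) {
    out <- fs
    out$frags <- fs$frags[sel, , drop = FALSE]
    rownames(out$frags) <- NULL
    out
  }
  list(alt = subset_fs(is_alt), ref = subset_fs(covers & !is_alt))
}
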