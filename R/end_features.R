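#' All 4-mers in lexicographic order
#'
#' @param k k-mer length (default 4, giving the 256 motifs).
#' @return character vector of the 4^k k-mers, lexicographically sorted.
#' @export
all_kmers <- function(k = 4L) {
  b <- c("A", "C", "G", "T")
  g <- do.call(expand.grid, c(rep(list(b), k), KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic
  sort(do.call(paste0, g[rev(seq_len(k))]))
}

# both 5' ends of each fragment, optionally restricted to a region
counted_ends <- function(fs, ref, region_sites = NULL) {
  ends <- five_prime_ends(fs, ref)
  sites <- c(ends$light_site, ends$heavy_site)
  bases <- c(ends$light_base, ends$heavy_base)
  motifs <- c(ends$light_motif, ends$heavy_motif)
  if (!is.null(region_sites)) {
    keep <- sites %in% region_sites
    sites <- sites[keep]; bases <- bases[keep]; motifs <- motifs[keep]
  }
  data.frame(site = sites, base = bases, motif = motifs,
             stringsAsFactors = FALSE)
}

#' Proportion of 5' end bases
#'
#' Fraction of counted 5' ends terminating in each base: the number of
#' 5' specific-end fragments over the total of A-, C-, G- and T-end
#' fragments. Both strand ends of every fragment are counted; with a region
#' given, an end counts only if its 5' site falls inside the region.
#'
#' @param fs a [FragmentSet].
#' @param ref matching [MtReference].
#' @param region_sites optional site set from [region_sites()].
#' @return named numeric vector `c(A=,C=,G=,T=)` summing to 1.
#' @export
end_base_proportion <- function(fs, ref, region_sites = NULL) {
  ends <- counted_ends(fs, ref, region_sites)
  ends <- ends[ends$base %in% c("A", "C", "G", "T"), , drop = FALSE]
  if (!nrow(ends)) stop("no counted 5' ends in the requested region")
  tab <- table(factor(ends$base, levels = c("A", "C", "G", "T")))
  p <- as.numeric(tab) / nrow(ends)
  names(p) <- c("A", "C", "G", "T")
  p
}

#' 5' end base preference
#'
#' Observed end-base proportion normalized by the base composition of the
#' reference genome. The default form is the ratio
#' `proportion / genome fraction`, whose no-preference point is 1; the
#' difference form `proportion - genome fraction` (no-preference point 0) is
#' available for sensitivity checks.
#'
#' @param proportions named vector from [end_base_proportion()].
#' @param genome_composition named vector from [base_composition()].
#' @param form `"ratio"` (default) or `"difference"`.
#' @return named numeric vector over A, C, G, T.
#' @export
end_base_preference <- function(proportions, genome_composition,
                                form = c("ratio", "difference")) {
  form <- match.arg(form)
  stopifnot(all(c("A", "C", "G", "T") %in% names(proportions)),
            all(c("A", "C", "G", "T") %in% names(genome_composition)))
  b <- c("A", "C", "G", "T")
  if (form == "ratio") {
    if (any(genome_composition[b] <= 0))
      stop("genome base fraction of zero; ratio preference undefined")
    proportions[b] / genome_composition[b]
  } else {
    proportions[b] - genome_composition[b]
  }
}

#' 5' end 4-mer motif spectrum
#'
#' Normalized frequencies of the 256 possible 5' end 4-mers over all counted
#' ends (both strands, heavy-strand motifs already reverse-complemented into
#' 5'->3' orientation by [five_prime_ends()]). Fragments shorter than 4 bp
#' carry no motif and are excluded from the denominator. Motifs containing N
#' (reference N at the terminus) are likewise excluded.
#'
#' @inheritParams end_base_proportion
#' @return object of class `MotifSpectrum`: list with `proportions` (named
#'   256-vector summing to 1) and `total_ends`.
#' @export
motif_spectrum <- function(fs, ref, region_sites = NULL) {
  ends <- counted_ends(fs, ref, region_sites)
  kmers <- all_kmers(4L)
  motifs <- ends$motif[!is.na(ends$motif) & ends$motif %in% kmers]
  if (!length(motifs)) stop("no motif-eligible 5' ends")
  tab <- table(factor(motifs, levels = kmers))
  p <- as.numeric(tab) / length(motifs)
  names(p) <- kmers
  structure(list(proportions = p, total_ends = length(motifs)),
            class = "MotifSpectrum")
}

#' @export
print.MotifSpectrum <- function(x, ...) {
  cat("MotifSpectrum: ", x$total_ends, " ends, ",
      sum(x$proportions > 0), "/256 motifs observed, MDS = ",
      round(motif_diversity_score(x), 4), "\n", sep = "")
  invisible(x)
}

#' Motif diversity score (normalized Shannon entropy)
#'
#' `MDS = sum_i -P_i log(P_i) / log(256)` over the 256 4-mer frequencies.
#' Zero-frequency motifs contribute nothing; the logarithm base cancels.
#' The score is 0 when a single motif carries all mass and 1 when all 256
#' motifs are equally frequent.
#'
#' @param spectrum a `MotifSpectrum`, or a numeric vector of motif
#'   proportions summing to 1.
#' @return scalar in [0, 1].
#' @export
motif_diversity_score <- function(spectrum) {
  p <- if (inherits(spectrum, "MotifSpectrum")) spectrum$proportions
       else as.numeric(spectrum)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("motif proportions must be non-negative and sum to 1")
  n <- length(p)
  p <- p[p > 0]
  sum(-p * log(p)) / log(n)
}

#' All end features of one sample
#'
#' Convenience wrapper computing end-base proportions, preferences, the
#' motif spectrum and the MDS in one pass, optionally region-restricted.
#'
#' @inheritParams end_base_proportion
#' @param preference_form passed to [end_base_preference()].
#' @return list with `proportion`, `preference`, `spectrum`, `mds`.
#' @export
end_features <- function(fs, ref, region_sites = NULL,
                         preference_form = "ratio") {
  prop <- end_base_proportion(fs, ref, region_sites)
  pref <- end_base_preference(prop, base_composition(ref),
                              form = preference_form)
  spec <- motif_spectrum(fs, ref, region_sites)
  list(proportion = prop, preference = pref, spectrum = spec,
       mds = motif_diversity_score(spec))
}
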