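#' Split fragments into short and long at the sample median
#'
#' Short and long fragments are defined per sample by the median fragment
#' size; a fragment of length less than or equal to the median is short,
#' otherwise long. The tie rule (equal to the median counts as short) is
#' deterministic and stable under duplicated lengths.
#'
#' @param fs a [FragmentSet] with at least 2 fragments.
#' @return list with `median_size` (bp) and `is_long` (logical per
#'   fragment).
#' @export
split_long_short <- function(fs) {
  len <- fs$frags$length
  if (length(len) < 2L) stop("need at least 2 fragments to split")
  m <- median(len)
  list(median_size = m, is_long = len > m)
}

#' Per-site coverage depths of long and short fragments
#'
#' A fragment covers every site of its (possibly origin-wrapping) span.
#' Computed with a circular difference array in O(n + L).
#'
#' @param fs a [FragmentSet].
#' @param is_long optional logical from [split_long_short()]; when missing,
#'   only total depth is returned.
#' @return list with integer vectors `depth`, and (given `is_long`)
#'   `long_depth` and `short_depth`, each of length `L`.
#' @export
site_depths <- function(fs, is_long = NULL) {
  L <- fs$L
  cov1 <- function(start, end) {
    # end may exceed L (wrap); accumulate +1/-1 on a length-(2L) diff array
    d <- numeric(2L * L + 1L)
    if (length(start)) {
      tab1 <- tabulate(start, nbins = 2L * L)
      tab2 <- tabulate(pmin(end, 2L * L) + 1L, nbins = 2L * L + 1L)
      d[seq_len(2L * L)] <- tab1
      d <- d - tab2
    }
    cs <- cumsum(d[seq_len(2L * L)])
    cs[seq_len(L)] + cs[L + seq_len(L)]
  }
  st <- fs$frags$start
  en <- fs$frags$end
  out <- list(depth = as.integer(cov1(st, en)))
  if (!is.null(is_long)) {
    out$long_depth <- as.integer(cov1(st[is_long], en[is_long]))
    out$short_depth <- out$depth - out$long_depth
  }
  out
}

#' Raw fragment size distribution (FSD) score
#'
#' Per-site ratio of long-fragment to short-fragment coverage depth, with a
#' pseudocount on both depths so sites with no coverage map to the neutral
#' ratio 1 and division by zero cannot occur. At the sequencing depths the
#' profile is intended for (hundreds-fold), the pseudocount is negligible.
#'
#' @param long_depth,short_depth integer vectors of length `L`.
#' @param pseudocount added to both depths (default 1).
#' @return numeric vector of length `L`.
#' @export
fsd_raw <- function(long_depth, short_depth, pseudocount = 1) {
  stopifnot(length(long_depth) == length(short_depth))
  (long_depth + pseudocount) / (short_depth + pseudocount)
}

#' LOESS GC correction of a per-site signal
#'
#' Fits a LOESS regression of the raw FSD score on the per-site GC fraction
#' (span 0.75, degree 1) and returns the residual re-centred at the grand
#' mean: `corrected[i] = value[i] - fit(gc[i]) + mean(value)`. After
#' correction the linear dependence of the signal on GC is (near) zero. A
#' constant GC track leaves the values unchanged, with a warning.
#'
#' @param values numeric per-site signal (raw FSD score).
#' @param gc_track per-site GC fraction from [gc_fraction_track()].
#' @param span LOESS span (default 0.75).
#' @param degree LOESS polynomial degree (default 1).
#' @return corrected numeric vector, same length and mean as `values`.
#' @export
gc_correct_loess <- function(values, gc_track, span = 0.75, degree = 1) {
  stopifnot(length(values) == length(gc_track))
  if (length(unique(gc_track)) < 2L) {
    warning("constant GC track; correction is the identity")
    return(values)
  }
  fit <- loess(values ~ gc_track, span = span, degree = degree,
               family = "gaussian",
               control = loess.control(surface = "interpolate"))
  values - fitted(fit) + mean(values)
}

#' z-scale a numeric vector
#'
#' `(x - mean(x)) / sd(x)` using the population (n-denominator) standard
#' deviation: the per-site profile is the full population of sites, not a
#' sample from it. Constant input yields all zeros with a warning.
#'
#' @param x numeric vector.
#' @return numeric vector with mean 0 and population sd 1.
#' @export
zscore <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) {
    warning("zero variance; z-scores set to 0")
    return(rep(0, length(x)))
  }
  (x - m) / s
}

#' Standardized per-site depth
#'
#' z-scaled coverage depth (same kernel as [zscore()]); used to compare
#' fragmentation profiles with protein-occupancy surrogates such as
#' mitochondrial single-cell ATAC coverage.
#'
#' @param depth numeric per-site depth.
#' @return z-scaled depth.
#' @export
standardized_depth <- function(depth) zscore(depth)

#' Per-site fragmentation profile of one sample
#'
#' Runs the full profile pipeline: median split, long/short per-site
#' depths, raw FSD score, LOESS GC correction and z-scaling.
#'
#' @param fs a [FragmentSet].
#' @param ref matching [MtReference].
#' @param gc_track optional precomputed [gc_fraction_track()] (computed at
#'   the default 101-bp window when missing).
#' @param span,degree LOESS parameters (defaults 0.75 and 1).
#' @param pseudocount passed to [fsd_raw()].
#' @return object of class `SiteProfile`: list with per-site vectors
#'   `depth`, `long_depth`, `short_depth`, `fsd_raw`, `fsd_gc_corrected`,
#'   `fsd_z`, and scalar `median_fragment_size`.
#' @export
site_profile <- function(fs, ref, gc_track = NULL, span = 0.75, degree = 1,
                         pseudocount = 1) {
  stopifnot(fs$L == ref$length)
  sp <- split_long_short(fs)
  dep <- site_depths(fs, sp$is_long)
  raw <- fsd_raw(dep$long_depth, dep$short_depth, pseudocount)
  if (is.null(gc_track)) gc_track <- gc_fraction_track(ref)
  corr <- gc_correct_loess(raw, gc_track, span = span, degree = degree)
  structure(list(depth = dep$depth, long_depth = dep$long_depth,
                 short_depth = dep$short_depth, fsd_raw = raw,
                 fsd_gc_corrected = corr, fsd_z = zscore(corr),
                 median_fragment_size = sp$median_size),
            class = "SiteProfile")
}

#' @export
print.SiteProfile <- function(x, ...) {
  cat("SiteProfile: ", length(x$depth), " sites, mean depth ",
      round(mean(x$depth), 1), "x, median fragment size ",
      x$median_fragment_size, " bp\n", sep = "")
  invisible(x)
}

#' Reference fragmentation profile of a healthy panel
#'
#' Site-wise median of the GC-corrected FSD scores of the panel members,
#' then z-scaled. This is the profile each sample is compared against
#' (Spearman correlation, new-peak calls, window distances).
#'
#' @param panel list of `SiteProfile` objects (typically healthy controls).
#' @return numeric z-scaled reference profile of length `L`.
#' @export
reference_profile <- function(panel) {
  if (!length(panel)) stop("empty reference panel")
  stopifnot(all(vapply(panel, inherits, logical(1), "SiteProfile")))
  m <- vapply(panel, function(p) p$fsd_gc_corrected,
              numeric(length(panel[[1L]]$fsd_gc_corrected)))
  zscore(apply(m, 1L, median))
}

#' Spearman correlation between a sample profile and the reference
#'
#' Rank correlation (average ranks for ties) between the z-scaled
#' fragmentation profile of a sample and the reference profile.
#'
#' @param profile_z sample z-scaled profile.
#' @param reference_profile_z reference z-scaled profile, same length.
#' @return rho in [-1, 1].
#' @export
profile_correlation <- function(profile_z, reference_profile_z) {
  stopifnot(length(profile_z) == length(reference_profile_z))
  if (sd(profile_z) == 0 || sd(reference_profile_z) == 0)
    stop("constant profile; correlation undefined")
  cor(profile_z, reference_profile_z, method = "spearman")
}
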