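#' Call peaks on a z-scaled fragmentation profile
#'
#' A peak is a maximal circular run of consecutive sites strictly above
#' (positive peak) or strictly below (negative peak) the baseline; sites
#' exactly at the baseline break runs. Runs shorter than `min_width`
#' (default 5 bp) are discarded. Each peak reports its apex (site of
#' maximum absolute z, ties broken to the smallest genomic index) and its
#' signed area (sum of z over the run).
#'
#' @param profile_z numeric per-site profile (z-scaled FSD score).
#' @param min_width minimum run length in bp (default 5).
#' @param baseline baseline value (default 0).
#' @return data.frame with columns `sign` ("+"/"-"), `start`, `end`
#'   (1-based closed, circular: `end < start` means the run wraps),
#'   `width`, `apex`, `area`.
#' @export
call_peaks <- function(profile_z, min_width = 5L, baseline = 0) {
  L <- length(profile_z)
  s <- sign(profile_z - baseline)   # +1 / 0 / -1, strict
  empty <- data.frame(sign = character(), start = integer(),
                      end = integer(), width = integer(), apex = integer(),
                      area = numeric(), stringsAsFactors = FALSE)
  if (all(s == 0)) return(empty)
  # rotate so position 1 begins a new run (a sign change exists unless the
  # whole circle has one sign)
  if (all(s == s[1L])) {
    rot <- 0L
  } else {
    brk <- which(s != c(s[L], s[-L]))[1L]   # first index where a run starts
    rot <- brk - 1L
  }
  idx <- circ_site(seq_len(L) + rot, L)     # original indices, rotated
  sr <- s[idx]
  zr <- (profile_z - baseline)[idx]
  r <- rle(sr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0 & r$lengths >= min_width
  if (!any(keep)) return(empty)
  out <- lapply(which(keep), function(k) {
    pos <- starts[k]:ends[k]                # positions in rotated frame
    sites <- idx[pos]
    zv <- zr[pos]
    best <- abs(zv) == max(abs(zv))
    apex <- min(sites[best])                # tie -> smallest genomic index
    data.frame(sign = if (r$values[k] > 0) "+" else "-",
               start = sites[1L], end = sites[length(sites)],
               width = length(sites), apex = apex, area = sum(zv),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' New peaks relative to a reference peak set
#'
#' A sample peak is "new" when the circular distance from its apex to every
#' reference apex exceeds `min_distance` (default 20 bp). By default apexes
#' of both signs are compared; `match_sign = TRUE` restricts the comparison
#' to reference peaks of the same sign.
#'
#' @param sample_peaks,reference_peaks peak data.frames from
#'   [call_peaks()].
#' @param L genome length.
#' @param min_distance distance threshold in bp (default 20).
#' @param match_sign compare only same-sign peaks (default FALSE).
#' @return list with `peaks` (the new-peak rows) and `count`.
#' @export
new_peaks <- function(sample_peaks, reference_peaks, L, min_distance = 20L,
                      match_sign = FALSE) {
  if (!nrow(sample_peaks))
    return(list(peaks = sample_peaks, count = 0L))
  is_new <- vapply(seq_len(nrow(sample_peaks)), function(i) {
    refs <- reference_peaks
    if (match_sign)
      refs <- refs[refs$sign == sample_peaks$sign[i], , drop = FALSE]
    if (!nrow(refs)) return(TRUE)
    all(circ_dist(sample_peaks$apex[i], refs$apex, L) > min_distance)
  }, logical(1))
  list(peaks = sample_peaks[is_new, , drop = FALSE], count = sum(is_new))
}

#' Tile the genome into equal windows
#'
#' The genome is divided into `n` windows of width `ceiling(L / n)`; the
#' last window is shorter when `n` does not divide `L`. For the 16,569-bp
#' mitochondrial genome and `n = 255`, windows are 65 bp with a 59-bp final
#' window. The windows tile `1..L` without overlap.
#'
#' @param L genome length.
#' @param n number of windows (default 255).
#' @return data.frame with columns `window`, `start`, `end`.
#' @export
mt_windows <- function(L, n = 255L) {
  stopifnot(n >= 1L)
  w <- ceiling(L / n)
  start <- (seq_len(n) - 1L) * w + 1L
  end <- pmin(seq_len(n) * w, L)
  if (any(start > end)) stop("more windows than sites; reduce n")
  data.frame(window = seq_len(n), start = as.integer(start),
             end = as.integer(end))
}

# window index of each site under a tiling from mt_windows
window_index <- function(L, windows) {
  rep(windows$window, windows$end - windows$start + 1L)
}

#' Positive and negative profile areas per window
#'
#' For each window, the area above and below the baseline of the z-scaled
#' profile: `pos_area = sum(max(z, 0))` and `neg_area = sum(max(-z, 0))`
#' over the window's sites. The full track is integrated (not only sites
#' inside called peaks), so for a z-scaled profile the positive and
#' negative areas balance globally.
#'
#' @param profile_z numeric per-site profile.
#' @param windows window tiling from [mt_windows()].
#' @param baseline baseline (default 0).
#' @return data.frame with columns `window`, `pos_area`, `neg_area`.
#' @export
window_areas <- function(profile_z, windows, baseline = 0) {
  L <- length(profile_z)
  stopifnot(max(windows$end) == L)
  wi <- window_index(L, windows)
  z <- profile_z - baseline
  pos <- vapply(split(pmax(z, 0), wi), sum, numeric(1))
  neg <- vapply(split(pmax(-z, 0), wi), sum, numeric(1))
  data.frame(window = windows$window, pos_area = unname(pos),
             neg_area = unname(neg))
}

#' Per-window Euclidean distance to the reference profile
#'
#' `dist_k = sqrt(sum_{i in window k} (z_i - ref_i)^2)`.
#'
#' @param profile_z sample z-scaled profile.
#' @param reference_profile_z reference z-scaled profile, same length.
#' @param windows window tiling from [mt_windows()].
#' @return data.frame with columns `window`, `euclid_dist`.
#' @export
window_distances <- function(profile_z, reference_profile_z, windows) {
  stopifnot(length(profile_z) == length(reference_profile_z))
  wi <- window_index(length(profile_z), windows)
  d2 <- split((profile_z - reference_profile_z)^2, wi)
  data.frame(window = windows$window,
             euclid_dist = sqrt(vapply(d2, sum, numeric(1), USE.NAMES = FALSE)))
}
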