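#' Per-sample set of cfDNA fragments
#'
#' A `FragmentSet` is the container every feature computation consumes: one
#' row per sequenced fragment on the circular mitochondrial genome, plus the
#' sample-level labels used by the classifiers. Fragment coordinates are
#' 1-based closed; `end < start` is not allowed in the table — instead a
#' fragment that wraps the origin is stored with `end > L` (linearized past
#' the origin), and `end_site()` / coverage code reduce it modulo `L`.
#'
#' @param start integer vector of leftmost fragment sites (1..L).
#' @param length integer vector of fragment lengths in bp.
#' @param L genome length the coordinates refer to.
#' @param sample_id sample identifier.
#' @param group_label cohort group: one of `"MT"`, `"BT"`, `"INF"`, `"HC"`.
#' @param cancer_type cancer type for MT samples (`"NSCLC"`, `"HCC"`,
#'   `"CRC"`, `"SOC"`, `"BC"`, `"ccRCC"`) or `"none"`.
#' @param batch_id sequencing batch identifier.
#' @param alt_site,alt_base optional per-fragment variant tag: the site and
#'   alternate base carried by the fragment (`NA` when none).
#' @return object of class `FragmentSet`: a list with `sample_id`,
#'   `group_label`, `cancer_type`, `batch_id`, `L` and `frags` (data.frame
#'   with columns `start`, `end`, `length`, `alt_site`, `alt_base`).
#' @export
FragmentSet <- function(start, length, L, sample_id = "sample",
                        group_label = "HC", cancer_type = "none",
                        batch_id = "batch1", alt_site = NULL,
                        alt_base = NULL) {
  start <- as.integer(start)
  length <- as.integer(length)
  stopifnot(base::length(start) == base::length(length))
  if (any(start < 1L | start > L)) stop("fragment start outside [1, L]")
  if (any(length < 1L | length > L)) stop("fragment length outside [1, L]")
  if (!group_label %in% c("MT", "BT", "INF", "HC"))
    stop("group_label must be one of MT, BT, INF, HC")
  n <- base::length(start)
  frags <- data.frame(
    start = start,
    end = start + length - 1L,   # may exceed L: wraps through the origin
    length = length,
    alt_site = if (is.null(alt_site)) rep(NA_integer_, n) else as.integer(alt_site),
    alt_base = if (is.null(alt_base)) rep(NA_character_, n) else as.character(alt_base))
  structure(list(sample_id = sample_id, group_label = group_label,
                 cancer_type = cancer_type, batch_id = batch_id,
                 L = as.integer(L), frags = frags),
            class = "FragmentSet")
}

#' @export
print.FragmentSet <- function(x, ...) {
  cat("FragmentSet '", x$sample_id, "' (", x$group_label,
      if (x$cancer_type != "none") paste0("/", x$cancer_type), "): ",
      nrow(x$frags), " fragments on ", x$L, " bp circular genome\n", sep = "")
  invisible(x)
}

#' Number of fragments in a FragmentSet
#' @param fs a [FragmentSet].
#' @return integer count.
#' @export
n_fragments <- function(fs) nrow(fs$frags)

# rightmost site reduced onto 1..L
end_site <- function(fs) circ_site(fs$frags$end, fs$L)

#' Read fragments from a coordinate-sorted paired-end BAM
#'
#' One fragment per properly-paired, non-duplicate, non-secondary template
#' whose two mates both have mapping quality at or above `min_mapq`
#' (default 20). The fragment is the outer span of the pair on the
#' linearized reference; templates that would wrap the origin cannot be
#' represented unambiguously in a linear BAM and are not reconstructed.
#'
#' @param bam_path path to an indexed or unindexed BAM aligned to the
#'   mitochondrial reference.
#' @param ref the [MtReference] the BAM was aligned against; the BAM header
#'   must contain exactly one reference of matching length.
#' @param min_mapq minimum mapping quality for both mates.
#' @param ... labels passed to [FragmentSet()] (`sample_id`, `group_label`,
#'   `cancer_type`, `batch_id`).
#' @return a [FragmentSet].
#' @export
read_fragments_bam <- function(bam_path, ref, min_mapq = 20L, ...) {
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1L]]$targets
  if (!length(hdr)) stop("BAM has no mapped reference: ", bam_path)
  if (length(hdr) != 1L)
    stop("BAM header has ", length(hdr), " references; expected 1")
  if (unname(hdr[1L]) != ref$length)
    stop("BAM reference length ", unname(hdr[1L]),
         " does not match MtReference length ", ref$length)
  flag <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isProperPair = TRUE, isDuplicate = FALSE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = min_mapq)
  pairs <- GenomicAlignments::readGAlignmentPairs(bam_path, param = param)
  if (!length(pairs)) {
    return(FragmentSet(integer(), integer(), L = ref$length, ...))
  }
  gr <- GenomicAlignments::granges(pairs)   # outer span of each template
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  FragmentSet(st, en - st + 1L, L = ref$length, ...)
}

#' Read and write fragment tables in BED-like TSV form
#'
#' Plain-text interchange format: tab-separated columns `chrom`,
#' `start` (0-based half-open), `end`, `strand` (orientation of read 1) and
#' `sample_id`, without a header. Fragments wrapping the origin are written
#' with `end > L` (linearized past the origin), which round-trips losslessly.
#' Malformed rows (non-numeric coordinates or non-positive length) are
#' skipped with a warning reporting the count.
#'
#' @param tsv_path input path (plain or gzip).
#' @param ref the [MtReference] the coordinates refer to.
#' @param ... labels passed to [FragmentSet()].
#' @return [FragmentSet] (strand of read 1 is attached as attribute
#'   `"strand"` when present).
#' @export
read_fragments_bed <- function(tsv_path, ref, ...) {
  if (!file.exists(tsv_path)) stop("fragment table not found: ", tsv_path)
  tab <- read.table(tsv_path, header = FALSE, sep = "\t",
                    col.names = c("chrom", "start", "end", "strand",
                                  "sample_id"),
                    colClasses = c("character", "character", "character",
                                   "character", "character"), quote = "")
  st0 <- suppressWarnings(as.integer(tab$start))
  en <- suppressWarnings(as.integer(tab$end))
  bad <- is.na(st0) | is.na(en) | en - st0 < 1L | st0 < 0L | st0 >= ref$length
  if (any(bad))
    warning(sum(bad), " malformed fragment row(s) skipped in ", tsv_path)
  keep <- !bad
  fs <- FragmentSet(st0[keep] + 1L, en[keep] - st0[keep], L = ref$length, ...)
  attr(fs, "strand") <- tab$strand[keep]
  fs
}

#' @rdname read_fragments_bed
#' @param fs a [FragmentSet] to write.
#' @param path output path.
#' @param chrom chromosome name to write.
#' @export
write_fragments_bed <- function(fs, path, chrom = "chrM") {
  strand <- attr(fs, "strand")
  if (is.null(strand)) strand <- rep("+", n_fragments(fs))
  tab <- data.frame(chrom = chrom, start = fs$frags$start - 1L,
                    end = fs$frags$end, strand = strand,
                    sample_id = fs$sample_id)
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Strand-aware 5' terminal bases and 4-mer motifs
#'
#' Every sequenced fragment exposes two 5' ends: the light-strand end at its
#' leftmost site (reference base, motif read left to right) and the
#' heavy-strand end at its rightmost site (complement of the reference base,
#' motif the reverse complement of the reference 4-mer ending there). Both
#' are taken from the reference sequence at the terminal coordinates, with
#' circular wrap, so BED-mode fragment tables need no read bases.
#' Fragments shorter than 4 bp yield `NA` motifs.
#'
#' @param fs a [FragmentSet].
#' @param ref matching [MtReference].
#' @return data.frame with columns `light_site`, `heavy_site`,
#'   `light_base`, `heavy_base`, `light_motif`, `heavy_motif`.
#' @export
five_prime_ends <- function(fs, ref) {
  L <- ref$length
  stopifnot(fs$L == L)
  ls <- fs$frags$start
  hs <- end_site(fs)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  light_base <- ref$chars[ls]
  heavy_base <- unname(comp[ref$chars[hs]])
  eligible <- fs$frags$length >= 4L
  light_motif <- rep(NA_character_, length(ls))
  heavy_motif <- rep(NA_character_, length(ls))
  if (any(eligible)) {
    light_motif[eligible] <- circ_kmer(ref, ls[eligible], 4L)
    hm <- circ_kmer(ref, circ_site(hs[eligible] - 3L, L), 4L)
    heavy_motif[eligible] <- revcomp(hm)
  }
  data.frame(light_site = ls, heavy_site = hs,
             light_base = light_base, heavy_base = heavy_base,
             light_motif = light_motif, heavy_motif = heavy_motif,
             stringsAsFactors = FALSE)
}

# forward k-mer starting at each position, circular
circ_kmer <- function(ref, pos, k = 4L) {
  L <- ref$length
  idx <- outer(pos - 1L, 0L:(k - 1L), "+") %% L + 1L
  m <- matrix(ref$chars[idx], nrow = length(pos))
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Assign 5' end sites to functional regions
#'
#' Region-restricted end features count a fragment end if and only if its 5'
#' terminal site lies inside the region; a fragment merely overlapping the
#' region does not count.
#'
#' @param sites integer vector of 5' end sites.
#' @param annotations annotation data.frame.
#' @param L genome length.
#' @return character vector of region classes (`NA` outside all regions).
#' @export
assign_region <- function(sites, annotations, L) {
  region_of_site(annotations, sites, L)
}

#' Randomly downsample a FragmentSet
#'
#' Uniform subsampling without replacement, deterministic under `seed`.
#' Either `fraction` (0 < f <= 1) or `target_mean_depth` must be given; the
#' latter is converted to a fraction using the current mean per-site depth.
#'
#' @param fs a [FragmentSet].
#' @param fraction fraction of fragments to keep.
#' @param target_mean_depth alternative: desired mean per-site coverage.
#' @param seed integer RNG seed.
#' @return downsampled [FragmentSet].
#' @export
downsample <- function(fs, fraction = NULL, target_mean_depth = NULL,
                       seed = 1L) {
  n <- n_fragments(fs)
  if (is.null(fraction)) {
    if (is.null(target_mean_depth))
      stop("give either fraction or target_mean_depth")
    cur <- sum(fs$frags$length) / fs$L
    fraction <- min(1, target_mean_depth / cur)
  }
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(fs)
  keep_n <- round(fraction * n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  keep <- sort(sample.int(n, keep_n))
  out <- fs
  out$frags <- fs$frags[keep, , drop = FALSE]
  rownames(out$frags) <- NULL
  if (!is.null(attr(fs, "strand"))) attr(out, "strand") <- attr(fs, "strand")[keep]
  out
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
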