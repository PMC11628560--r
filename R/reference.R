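#' @importFrom stats median sd cor loess loess.control fitted predict pbinom
#'   quantile rnorm runif rbinom setNames
#' @importFrom utils read.table write.table head
NULL

#' Circular mitochondrial reference genome
#'
#' An `MtReference` holds a single circular DNA sequence in 1-based, closed
#' coordinates: site `L` is adjacent to site 1, and intervals with
#' `start > end` wrap through the origin. The human mitochondrial genome is
#' ~16.6 kb; sequences longer than 100 kb are rejected as unlikely to be
#' mitochondrial.
#'
#' @param sequence character scalar over A/C/G/T/N.
#' @param name sequence identifier.
#' @return An object of class `MtReference` with elements `name`, `sequence`
#'   (uppercase string), `chars` (per-site character vector) and `length`.
#' @export
MtReference <- function(sequence, name = "mtDNA") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("reference sequence contains characters outside {A,C,G,T,N}")
  L <- nchar(sequence)
  if (L < 1L) stop("empty reference sequence")
  if (L > 100000L)
    stop("sequence of ", L, " bp is not mitochondrial-scale (> 100 kb)")
  structure(
    list(name = name, sequence = sequence,
         chars = strsplit(sequence, "", fixed = TRUE)[[1L]], length = L),
    class = "MtReference")
}

#' @export
print.MtReference <- function(x, ...) {
  cat("MtReference '", x$name, "': circular, ", x$length, " bp\n", sep = "")
  invisible(x)
}

#' Load a mitochondrial reference genome and its region annotations
#'
#' Reads a single-record FASTA into an [MtReference] and, optionally, a
#' tab-separated annotation table with columns `name`, `class`, `start`,
#' `end`, `sub_region`. Coordinates are 1-based closed; `start > end`
#' encodes an origin-wrapping interval. `class` assigns each interval to one
#' of the functional region classes (typically D-loop, mRNA, rRNA, tRNA);
#' `sub_region` optionally splits the D-loop into its 7S and non-7S parts.
#'
#' @param fasta_path path to a FASTA file containing exactly one sequence.
#' @param annotation_path optional path to the annotation TSV.
#' @return list with elements `reference` ([MtReference]) and `annotations`
#'   (data.frame, zero rows when no table is given).
#' @export
load_reference <- function(fasta_path, annotation_path = NULL) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("no FASTA records in ", fasta_path)
  if (length(seqs) > 1L)
    stop(length(seqs), " FASTA records in ", fasta_path, "; expected exactly 1")
  ref <- MtReference(as.character(seqs[[1L]]),
                     name = sub("\\s.*$", "", names(seqs)[1L]))
  ann <- empty_annotations()
  if (!is.null(annotation_path)) {
    if (!file.exists(annotation_path))
      stop("annotation table not found: ", annotation_path)
    ann <- read.table(annotation_path, header = TRUE, sep = "\t",
                      colClasses = c("character", "character", "integer",
                                     "integer", "character"),
                      na.strings = NULL, quote = "")
    if (nrow(ann)) ann <- validate_annotations(ann, ref$length)
  }
  list(reference = ref, annotations = ann)
}

empty_annotations <- function() {
  data.frame(name = character(), class = character(), start = integer(),
             end = integer(), sub_region = character(),
             stringsAsFactors = FALSE)
}

validate_annotations <- function(ann, L) {
  need <- c("name", "class", "start", "end", "sub_region")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(ann$start < 1L | ann$start > L | ann$end < 1L | ann$end > L))
    stop("annotation interval outside [1, ", L, "]")
  ann$sub_region[is.na(ann$sub_region)] <- ""
  ann
}

#' Default vendored mitochondrial reference
#'
#' Loads the human mitochondrial genome shipped with the package
#' (NC_001807.4, 16,571 bp) together with its functional-region annotation
#' table: the standard mitochondrial gene coordinates (D-loop, the 13
#' protein-coding mRNAs, 12S/16S rRNA, 22 tRNAs, and the 7S segment of the
#' D-loop), expressed in this sequence's own coordinate frame.
#'
#' @return list with `reference` and `annotations`, as [load_reference()].
#' @export
mt_reference <- function() {
  load_reference(
    system.file("extdata", "human_mt_NC_001807.fasta", package = "mefi"),
    system.file("extdata", "mt_regions_NC_001807.tsv", package = "mefi"))
}

#' Expand annotation intervals into site indices
#'
#' Returns the (unique, sorted) 1-based sites covered by all intervals of a
#' region class, honouring origin-wrapping intervals.
#'
#' @param annotations annotation data.frame (see [load_reference()]).
#' @param region_class region class to select, e.g. "D-loop".
#' @param L genome length.
#' @param sub_region optional sub-region filter ("7S" or "non-7S"); rows with
#'   an empty `sub_region` are used when `sub_region` is `NULL`.
#' @return integer vector of sites.
#' @export
region_sites <- function(annotations, region_class, L, sub_region = NULL) {
  rows <- annotations[annotations$class == region_class, , drop = FALSE]
  if (is.null(sub_region)) {
    rows <- rows[rows$sub_region == "", , drop = FALSE]
  } else {
    rows <- rows[rows$sub_region == sub_region, , drop = FALSE]
  }
  if (!nrow(rows)) return(integer())
  sites <- unlist(lapply(seq_len(nrow(rows)), function(i) {
    expand_interval(rows$start[i], rows$end[i], L)
  }), use.names = FALSE)
  sort(unique(sites))
}

expand_interval <- function(start, end, L) {
  if (start <= end) start:end else c(start:L, 1:end)
}

#' Map sites to their functional region class
#'
#' @param annotations annotation data.frame.
#' @param site integer vector of 1-based sites.
#' @param L genome length.
#' @return character vector of region classes, `NA` for unannotated sites.
#' @export
region_of_site <- function(annotations, site, L) {
  if (any(site < 1L | site > L)) stop("site outside [1, ", L, "]")
  out <- rep(NA_character_, length(site))
  rows <- annotations[annotations$sub_region == "", , drop = FALSE]
  for (cls in unique(rows$class)) {
    in_cls <- site %in% region_sites(annotations, cls, L)
    out[is.na(out) & in_cls] <- cls
  }
  out
}

#' Base composition of a genome or region
#'
#' Fractions of A, C, G and T among the counted sites; N sites are excluded
#' from both numerator and denominator.
#'
#' @param ref an [MtReference].
#' @param sites optional integer vector restricting the computation to a
#'   region (e.g. from [region_sites()]); default whole genome.
#' @return named numeric vector `c(A=,C=,G=,T=)` summing to 1.
#' @export
base_composition <- function(ref, sites = NULL) {
  b <- if (is.null(sites)) ref$chars else ref$chars[sites]
  b <- b[b != "N"]
  if (!length(b)) stop("region contains no non-N sites")
  tab <- table(factor(b, levels = c("A", "C", "G", "T")))
  as.numeric(tab) / length(b) -> p
  names(p) <- c("A", "C", "G", "T")
  p
}

#' G+C fraction of a set of sites
#'
#' @inheritParams base_composition
#' @return scalar in [0, 1].
#' @export
gc_content <- function(ref, sites = NULL) {
  p <- base_composition(ref, sites)
  unname(p["G"] + p["C"])
}

#' Per-site GC fraction in a circular window
#'
#' GC covariate used for LOESS correction of the fragmentation profile: at
#' each site the G+C fraction of the circular window `[i - hw, i + hw]`
#' (2*hw + 1 sites). With `hw >= L/2` every window covers the whole circle
#' and the track is the global GC fraction everywhere.
#'
#' @param ref an [MtReference].
#' @param window_halfwidth window half-width in bp (default 50, i.e. 101 bp
#'   windows).
#' @return numeric vector of length `L` with values in [0, 1].
#' @export
gc_fraction_track <- function(ref, window_halfwidth = 50L) {
  stopifnot(window_halfwidth >= 0L)
  L <- ref$length
  hw <- min(as.integer(window_halfwidth), L)
  isgc <- as.numeric(ref$chars %in% c("G", "C"))
  w <- 2L * hw + 1L
  if (w >= L) return(rep(mean(isgc), L))
  # circular rolling mean via cumulative sums on a padded copy
  padded <- c(isgc[(L - hw + 1L):L], isgc, isgc[1L:hw])
  cs <- c(0, cumsum(padded))
  (cs[(w + 1L):(w + L)] - cs[1L:L]) / w
}

# 1-based circular index
circ_site <- function(i, L) ((i - 1L) %% L) + 1L

# circular distance between two site vectors
circ_dist <- function(a, b, L) {
  d <- abs(a - b)
  pmin(d, L - d)
}
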