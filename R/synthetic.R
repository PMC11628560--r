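#' Configuration of the fragment-cohort simulator
#'
#' Builds the generative model every synthetic sample is drawn from. The
#' simulator emulates the statistical structure the analysis assumes:
#' region-specific fragment lengths, site-specific cleavage protection
#' (a protein-binding surrogate producing fragmentation-profile peaks),
#' 5' end base bias, group-specific effects (malignant samples have
#' shorter fragments, extra cancer-type-specific protected loci and a
#' flatter end-motif distribution, i.e. higher MDS), and minor-allele
#' spike-ins with strand counts and base qualities.
#'
#' Defaults are anchored to healthy-plasma capture data: mean fragment
#' length 128 bp (sd 35), ~60x mean coverage per sample, G/A-favoured 5'
#' cleavage, and a D-loop < rRNA ~ mRNA < tRNA ordering of protection.
#'
#' @param ref an [MtReference] (default: the vendored genome).
#' @param annotations matching annotation table.
#' @param n_fragments fragments per sample (default 8000, ~60x).
#' @param mean_length,sd_length base fragment-length law in bp.
#' @param end_bias named per-base cleavage multipliers at the 5' cut site.
#' @param region_length_offsets named bp offsets added to the mean length
#'   by region class of the cut site.
#' @param protection_track optional per-site protection weights (>= 0);
#'   default built from region multipliers plus fixed Gaussian bumps.
#' @param protection_length_gain bp of extra length per unit protection
#'   above baseline at the (mid-fragment) protected site.
#' @param group_size_shift named bp shifts of the mean length per group.
#' @param group_motif_temp named exponents applied to the cleavage weights
#'   per group; values below 1 flatten the end-motif distribution and so
#'   raise the MDS (malignant default 0.7).
#' @param mt_peak_amplitude protection amplitude of the cancer-type loci.
#' @param mt_effect_scale scales all malignant effects (0 = none).
#' @param spike list of spike-ins, each a list with `site`, `alt`,
#'   `fraction`, `length_offset`, `strand_balance`, `base_quality`.
#' @return object of class `SimConfig`.
#' @export
sim_config <- function(ref = NULL, annotations = NULL, n_fragments = 30000L,
                       mean_length = 128, sd_length = 35,
                       end_bias = c(A = 1.2, C = 0.9, G = 1.4, T = 0.8),
                       region_length_offsets = c("D-loop" = -8, mRNA = 2,
                                                 rRNA = 2, tRNA = 8),
                       protection_track = NULL,
                       protection_length_gain = 6,
                       group_size_shift = c(HC = 0, BT = -2, INF = -3,
                                            MT = -10),
                       group_motif_temp = c(HC = 1, BT = 1, INF = 1.05,
                                            MT = 0.6),
                       mt_peak_amplitude = 4,
                       mt_effect_scale = 1,
                       spike = list()) {
  if (is.null(ref)) {
    loaded <- mt_reference()
    ref <- loaded$reference
    if (is.null(annotations)) annotations <- loaded$annotations
  }
  if (is.null(annotations)) annotations <- empty_annotations()
  L <- ref$length
  region_by_site <- if (nrow(annotations))
    region_of_site(annotations, seq_len(L), L) else rep(NA_character_, L)
  if (is.null(protection_track))
    protection_track <- default_protection_track(L, region_by_site)
  stopifnot(length(protection_track) == L, all(protection_track >= 0),
            all(is.finite(protection_track)))
  len_mean_site <- mean_length +
    ifelse(is.na(region_by_site), 0,
           unname(region_length_offsets[region_by_site]))
  len_mean_site[is.na(len_mean_site)] <- mean_length
  structure(list(
    ref = ref, annotations = annotations, L = L,
    n_fragments = as.integer(n_fragments),
    mean_length = mean_length, sd_length = sd_length,
    end_bias = end_bias, region_by_site = region_by_site,
    len_mean_site = len_mean_site,
    protection_track = protection_track,
    protection_length_gain = protection_length_gain,
    group_size_shift = group_size_shift,
    group_motif_temp = group_motif_temp,
    mt_peak_amplitude = mt_peak_amplitude,
    mt_effect_scale = mt_effect_scale,
    motif_ids = match(circ_kmer(ref, seq_len(L)), all_kmers(4L)),
    spike = spike), class = "SimConfig")
}

# region-multiplier baseline plus 12 fixed Gaussian protection bumps:
# every simulated individual shares the same "biology"
default_protection_track <- function(L, region_by_site) {
  mult <- c("D-loop" = 0.8, mRNA = 1.25, rRNA = 1.2, tRNA = 1.6)
  p <- rep(1, L)
  known <- !is.na(region_by_site)
  p[known] <- unname(mult[region_by_site[known]])
  loci <- round(L * seq_len(12L) / 13)
  add_bumps(p, loci, amplitude = 4, width = 15)
}

add_bumps <- function(p, loci, amplitude, width) {
  L <- length(p)
  x <- seq_len(L)
  for (c0 in loci) {
    d <- circ_dist(x, c0, L)
    p <- p + amplitude * exp(-d^2 / (2 * width^2))
  }
  p
}

# two fixed protected loci per cancer type, away from the shared bumps
mt_type_loci <- function(L) {
  frac <- list(NSCLC = c(0.070, 0.520), HCC = c(0.160, 0.600),
               CRC = c(0.240, 0.680), SOC = c(0.330, 0.760),
               BC = c(0.410, 0.840), ccRCC = c(0.470, 0.930),
               none = numeric())
  lapply(frac, function(f) round(L * f))
}

# fixed per-type end-motif perturbation (log-normal multipliers)
type_motif_mult <- function(cancer_type, strength = 0.5) {
  kmers <- all_kmers(4L)
  types <- c("NSCLC", "HCC", "CRC", "SOC", "BC", "ccRCC")
  if (!cancer_type %in% types) return(rep(1, length(kmers)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(7000L + match(cancer_type, types))
  exp(strength * rnorm(length(kmers)))
}

#' Simulate one fragment sample
#'
#' Two-cut generative model: a 5' cut site is drawn with probability
#' proportional to `end_bias(base) ^ temp * motif multiplier /
#' protection`, a fragment length is drawn from the region's length law
#' (plus the group size shift and extra length where the fragment midpoint
#' is protected), and the implied second cut closes the fragment on the
#' circle. Spiked variants are then placed on the configured fraction of
#' fragments covering the spike site, with their length offset applied
#' while preserving coverage of the site.
#'
#' @param cfg a [sim_config()].
#' @param group_label `"MT"`, `"BT"`, `"INF"` or `"HC"`.
#' @param cancer_type for MT samples, one of NSCLC, HCC, CRC, SOC, BC,
#'   ccRCC (or `"none"`).
#' @param sample_id,batch_id sample labels.
#' @param seed integer RNG seed; same seed, same sample.
#' @return a [FragmentSet] with ground-truth attributes `"protection"`
#'   (the per-site protection track used) and `"type_loci"`.
#' @export
simulate_sample <- function(cfg, group_label = "HC", cancer_type = "none",
                            sample_id = "sim", batch_id = "batch1",
                            seed = 1L) {
  stopifnot(inherits(cfg, "SimConfig"))
  L <- cfg$L
  n <- cfg$n_fragments
  scale <- if (group_label == "MT") cfg$mt_effect_scale else 1
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  prot <- cfg$protection_track
  loci <- integer()
  if (group_label == "MT" && cancer_type != "none") {
    loci <- mt_type_loci(L)[[cancer_type]]
    prot <- add_bumps(prot, loci, amplitude = cfg$mt_peak_amplitude * scale,
                      width = 12)
  }

  temp <- unname(cfg$group_motif_temp[group_label])
  if (group_label == "MT") temp <- 1 + (temp - 1) * scale
  w <- unname(cfg$end_bias[cfg$ref$chars])
  w[is.na(w)] <- mean(cfg$end_bias)          # N sites: neutral
  if (group_label == "MT" && cancer_type != "none") {
    mm <- type_motif_mult(cancer_type, strength = 0.25 * scale)
    w <- w * mm[cfg$motif_ids]
  }
  # temp < 1 models less motif-specific nuclease activity: it flattens the
  # whole per-motif cut-rate distribution, including the genome's own 4-mer
  # abundance, which is what raises the observed MDS
  abund <- tabulate(cfg$motif_ids, nbins = 256L) / L
  w <- (w^temp) * (pmax(abund[cfg$motif_ids], 1 / L)^(temp - 1)) / prot
  if (sum(w) <= 0) stop("zero total cleavage weight")

  cut <- sample.int(L, n, replace = TRUE, prob = w)
  shift <- unname(cfg$group_size_shift[group_label])
  if (group_label == "MT") shift <- shift * scale
  mid <- circ_site(cut + 60L, L)
  mu <- cfg$len_mean_site[cut] + shift +
    cfg$protection_length_gain * (prot[mid] - 1)
  len <- pmax(min(20L, L), pmin(min(400L, L), round(rnorm(n, mu, cfg$sd_length))))

  alt_site <- rep(NA_integer_, n)
  alt_base <- rep(NA_character_, n)
  for (sp in cfg$spike) {
    en <- cut + len - 1L
    covers <- (sp$site >= cut & sp$site <= en) |
      (sp$site + L >= cut & sp$site + L <= en)
    tag <- covers & runif(n) < sp$fraction
    if (!any(tag)) next
    off <- if (is.null(sp$length_offset)) 0L else sp$length_offset
    len2 <- pmax(20L, len[tag] + as.integer(off))
    # redraw the cut so the shortened fragment still covers the site
    pos_in_frag <- vapply(len2, function(l) sample.int(l, 1L), integer(1))
    cut[tag] <- circ_site(sp$site - pos_in_frag + 1L, L)
    len[tag] <- len2
    alt_site[tag] <- sp$site
    alt_base[tag] <- sp$alt
  }

  fs <- FragmentSet(cut, len, L = L, sample_id = sample_id,
                    group_label = group_label, cancer_type = cancer_type,
                    batch_id = batch_id, alt_site = alt_site,
                    alt_base = alt_base)
  attr(fs, "protection") <- prot
  attr(fs, "type_loci") <- loci
  fs
}

#' Simulate a labelled cohort with ground truth
#'
#' Per-sample seeds are derived from the master seed, so the same master
#' seed reproduces the same cohort. Samples are assigned to batches
#' round-robin.
#'
#' @param cfg a [sim_config()].
#' @param n_per_group named integer vector, e.g. `c(MT = 100, HC = 100)`.
#' @param seed master seed.
#' @param cancer_types types cycled over the MT samples (default all six).
#' @param n_batches number of batches (default 2).
#' @return list with `samples` (list of [FragmentSet]) and `truth`
#'   (data.frame: `sample_id`, `group`, `cancer_type`, `batch`, `seed`).
#' @export
simulate_cohort <- function(cfg, n_per_group, seed = 1L,
                            cancer_types = c("NSCLC", "HCC", "CRC", "SOC",
                                             "BC", "ccRCC"),
                            n_batches = 2L) {
  stopifnot(all(names(n_per_group) %in% c("MT", "BT", "INF", "HC")),
            all(n_per_group > 0))
  groups <- rep(names(n_per_group), n_per_group)
  n <- length(groups)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max %/% 2L, n)
  types <- rep("none", n)
  mt_idx <- which(groups == "MT")
  types[mt_idx] <- rep_len(cancer_types, length(mt_idx))
  batches <- paste0("batch", rep_len(seq_len(n_batches), n))
  ids <- sprintf("%s_%03d", groups, stats::ave(seq_len(n), groups,
                                               FUN = seq_along))
  samples <- lapply(seq_len(n), function(i)
    simulate_sample(cfg, groups[i], types[i], sample_id = ids[i],
                    batch_id = batches[i], seed = sample_seeds[i]))
  truth <- data.frame(sample_id = ids, group = groups, cancer_type = types,
                      batch = batches, seed = sample_seeds,
                      stringsAsFactors = FALSE)
  list(samples = samples, truth = truth)
}

#' Simulate a sequencing pileup
#'
#' Per-site strand-split base counts with Bernoulli sequencing errors and
#' Phred qualities implied by the error rate. Either a per-site depth
#' vector (error-only simulation) or a [FragmentSet] (whose coverage and
#' spiked alt tags define depth and true alt counts) drives the counts.
#'
#' @param ref an [MtReference].
#' @param depth integer scalar or per-site vector of depths.
#' @param error_rate per-base error probability (<= 0.1).
#' @param seed RNG seed.
#' @param alt_counts optional named list: per-site alt counts to inject,
#'   as a data.frame with `site`, `alt`, `count`, `quality`,
#'   `strand_balance`.
#' @return pileup data.frame (see [read_pileup()]).
#' @export
simulate_pileup <- function(ref, depth, error_rate = 1e-3, seed = 1L,
                            alt_counts = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 0.1)
  L <- ref$length
  if (length(depth) == 1L) depth <- rep(as.integer(depth), L)
  stopifnot(length(depth) == L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  q_err <- if (error_rate > 0) round(-10 * log10(error_rate)) else 40
  cnt <- matrix(0L, L, 4L, dimnames = list(NULL, bases))
  refb <- ref$chars
  refb[!refb %in% bases] <- "A"   # N sites: count toward an arbitrary base
  ref_idx <- match(refb, bases)
  cnt[cbind(seq_len(L), ref_idx)] <- depth
  # spiked alts replace reference reads
  if (!is.null(alt_counts) && nrow(alt_counts)) {
    for (i in seq_len(nrow(alt_counts))) {
      s <- alt_counts$site[i]
      a <- match(alt_counts$alt[i], bases)
      k <- min(alt_counts$count[i], cnt[s, ref_idx[s]])
      cnt[s, ref_idx[s]] <- cnt[s, ref_idx[s]] - k
      cnt[s, a] <- cnt[s, a] + k
    }
  }
  # sequencing errors move reference reads onto the three other bases
  if (error_rate > 0) {
    n_err <- rbinom(L, cnt[cbind(seq_len(L), ref_idx)], error_rate)
    e1 <- rbinom(L, n_err, 1 / 3)
    e2 <- rbinom(L, n_err - e1, 1 / 2)
    e3 <- n_err - e1 - e2
    others <- t(vapply(ref_idx, function(r) setdiff(1:4, r), integer(3)))
    cnt[cbind(seq_len(L), ref_idx)] <-
      cnt[cbind(seq_len(L), ref_idx)] - n_err
    cnt[cbind(seq_len(L), others[, 1L])] <-
      cnt[cbind(seq_len(L), others[, 1L])] + e1
    cnt[cbind(seq_len(L), others[, 2L])] <-
      cnt[cbind(seq_len(L), others[, 2L])] + e2
    cnt[cbind(seq_len(L), others[, 3L])] <-
      cnt[cbind(seq_len(L), others[, 3L])] + e3
  }
  fwd <- matrix(rbinom(4L * L, cnt, 0.5), L, 4L, dimnames = list(NULL, bases))
  rev <- cnt - fwd
  # strand-balance override for spikes
  if (!is.null(alt_counts) && nrow(alt_counts)) {
    for (i in seq_len(nrow(alt_counts))) {
      s <- alt_counts$site[i]; a <- match(alt_counts$alt[i], bases)
      sb <- alt_counts$strand_balance[i]
      if (!is.null(sb) && !is.na(sb)) {
        fwd[s, a] <- rbinom(1L, cnt[s, a], sb)
        rev[s, a] <- cnt[s, a] - fwd[s, a]
      }
    }
  }
  qual <- matrix(NA_real_, L, 4L, dimnames = list(NULL, bases))
  qual[cnt > 0] <- q_err
  if (!is.null(alt_counts) && nrow(alt_counts)) {
    for (i in seq_len(nrow(alt_counts))) {
      s <- alt_counts$site[i]; a <- match(alt_counts$alt[i], bases)
      qv <- alt_counts$quality[i]
      if (!is.null(qv) && !is.na(qv) && cnt[s, a] > 0) qual[s, a] <- qv
    }
  }
  out <- data.frame(site = seq_len(L), ref = ref$chars,
                    stringsAsFactors = FALSE)
  for (b in bases) out[[paste0(b, "_fwd")]] <- fwd[, b]
  for (b in bases) out[[paste0(b, "_rev")]] <- rev[, b]
  for (b in bases) out[[paste0(b, "_qual")]] <- qual[, b]
  out
}

#' Pileup of a simulated FragmentSet
#'
#' Derives per-site depth from the fragments' coverage and true alt counts
#' from their spike tags, then simulates strand-split counts and errors
#' with [simulate_pileup()].
#'
#' @param fs a [FragmentSet] from [simulate_sample()].
#' @param ref matching [MtReference].
#' @param error_rate per-base error probability.
#' @param seed RNG seed.
#' @param spike_quality Phred quality of spiked alt calls (default 33).
#' @param spike_strand_balance forward-strand fraction of spiked alt calls.
#' @return pileup data.frame.
#' @export
fragment_pileup <- function(fs, ref, error_rate = 1e-3, seed = 1L,
                            spike_quality = 33, spike_strand_balance = 0.5) {
  depth <- site_depths(fs)$depth
  tagged <- !is.na(fs$frags$alt_site)
  alt_counts <- NULL
  if (any(tagged)) {
    tab <- stats::aggregate(
      list(count = rep(1L, sum(tagged))),
      by = list(site = fs$frags$alt_site[tagged],
                alt = fs$frags$alt_base[tagged]), FUN = sum)
    tab$quality <- spike_quality
    tab$strand_balance <- spike_strand_balance
    alt_counts <- tab
  }
  simulate_pileup(ref, depth, error_rate = error_rate, seed = seed,
                  alt_counts = alt_counts)
}
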