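# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately share no code with the implementation.

# random circular toy genome
toy_reference <- function(L, seed = 1, name = "toy") {
  set.seed(seed)
  MtReference(paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                    collapse = ""), name = name)
}

# toy genome with exactly equal base counts (composition-balanced)
balanced_reference <- function(L = 400, seed = 1) {
  stopifnot(L %% 4 == 0)
  set.seed(seed)
  MtReference(paste(sample(rep(c("A", "C", "G", "T"), L / 4)),
                    collapse = ""), name = "balanced")
}

# brute-force circular run finder: walk forward from every circular run
# boundary, counting sites of constant non-zero sign
oracle_peaks <- function(z, min_width = 5, baseline = 0) {
  L <- length(z)
  s <- sign(z - baseline)
  record <- function(sites) {
    zv <- (z - baseline)[sites]
    apex <- min(sites[abs(zv) == max(abs(zv))])
    data.frame(sign = if (s[sites[1]] > 0) "+" else "-",
               start = sites[1], end = sites[length(sites)],
               width = length(sites), apex = apex, area = sum(zv),
               stringsAsFactors = FALSE)
  }
  if (all(s == 0)) return(NULL)
  if (all(s == s[1])) {
    res <- record(seq_len(L))
    return(if (res$width >= min_width) res else NULL)
  }
  out <- list()
  for (i in seq_len(L)) {
    prev <- s[if (i == 1) L else i - 1]
    if (s[i] == 0 || s[i] == prev) next
    sites <- i
    j <- i %% L + 1
    while (s[j] == s[i]) {
      sites <- c(sites, j)
      j <- j %% L + 1
    }
    if (length(sites) >= min_width) out[[length(out) + 1]] <- record(sites)
  }
  res <- do.call(rbind, out)
  if (!is.null(res)) rownames(res) <- NULL
  res
}

# brute-force Spearman rho via the Pearson formula on average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force AUC: mean over all (pos, neg) pairs, ties counting 1/2
oracle_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# brute-force Shannon entropy normalized to [0, 1]
oracle_mds <- function(p) {
  h <- 0
  for (v in p) if (v > 0) h <- h - v * log(v)
  h / log(length(p))
}

# sort peaks for comparison
peak_key <- function(pk) {
  if (is.null(pk) || !nrow(pk)) return(character())
  sort(paste(pk$sign, pk$start, pk$end, pk$width, pk$apex,
             round(pk$area, 9)))
}
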