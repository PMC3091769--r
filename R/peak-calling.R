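#' Call enriched regions on a tiled promoter track by permutation
#'
#' Scores every run of `min_probes` consecutive probes within one promoter
#' tile by its mean track value, builds a null distribution of window
#' scores by permuting probe values within each chromosome (seeded), and
#' keeps windows whose score exceeds the smallest threshold at which the
#' estimated false-discovery proportion — mean permuted windows at or above
#' the threshold per permutation, divided by observed windows at or above
#' it — is at most `fdr`. Overlapping significant windows (sharing at least
#' one probe) are merged into peaks; a peak's score is the mean over its
#' merged probes. Ties with the null threshold count against significance
#' (the null exceedance count includes equal scores), which is the
#' conservative choice.
#'
#' @param track A `norm_track` (ratio or delta mode).
#' @param min_probes Window width in probes (>= 2).
#' @param fdr Target false-discovery proportion.
#' @param n_permutations Number of within-chromosome permutations (>= 50).
#' @param seed Integer seed for the permutation machinery.
#' @return `data.frame` of peaks: chrom, start, end (0-based half-open),
#'   name, score, n_probes, fdr_q. Zero rows when nothing is significant
#'   or no tile holds `min_probes` probes.
#' @export
call_peaks <- function(track, min_probes = 4L, fdr = 0.05,
                       n_permutations = 200L, seed = 1L) {
  if (min_probes < 2) stop_input("min_probes must be >= 2")
  if (n_permutations < 50) stop_input("n_permutations must be >= 50")
  mp <- as.integer(min_probes)
  tr <- as.data.frame(track)
  tr <- tr[order(tr$chrom, tr$start), ]
  n <- nrow(tr)

  ws <- window_starts(tr, mp)
  if (!length(ws)) return(empty_peaks())
  obs <- frollmean(tr$value, mp, align = "left")[ws]

  null_ge <- null_exceedance_counts(tr, ws, mp, sort(unique(obs)),
                                    n_permutations, seed)
  u <- sort(unique(obs))             # ascending; null_ge aligned to u
  r_ge <- rev(cumsum(rev(tabulate(match(obs, u), length(u))))) # obs >= u
  fdr_hat <- (null_ge / n_permutations) / r_ge
  ok <- which(fdr_hat <= fdr)
  if (!length(ok)) return(empty_peaks())
  thr_i <- min(ok)                   # smallest admissible threshold
  thr <- u[thr_i]
  sig <- ws[obs >= thr]
  merge_windows(tr, sort(sig), mp, fdr_hat[thr_i])
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), n_probes = integer(),
             fdr_q = numeric(), stringsAsFactors = FALSE)
}

# indices i such that probes i..i+mp-1 lie in one (chrom, promoter tile)
window_starts <- function(tr, mp) {
  n <- nrow(tr)
  if (n < mp) return(integer())
  key <- ifelse(tr$is_background | is.na(tr$gene_id),
                paste0(".bg", seq_len(n)), paste(tr$chrom, tr$gene_id))
  blk <- cumsum(c(1L, as.integer(key[-1] != key[-n])))
  i <- seq_len(n - mp + 1L)
  i[!tr$is_background[i] & !is.na(tr$gene_id[i]) &
      blk[i] == blk[i + mp - 1L]]
}

# for each threshold (ascending), total permuted-window scores >= threshold
null_exceedance_counts <- function(tr, ws, mp, thresholds, B, seed) {
  groups <- split(seq_len(nrow(tr)), tr$chrom)
  counts <- numeric(length(thresholds))
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      v <- tr$value
      for (g in groups) v[g] <- v[g][sample.int(length(g))]
      sc <- frollmean(v, mp, align = "left")[ws]
      ssc <- sort(sc)
      # count(sc >= t) = length - count(sc < t)
      counts <- counts + (length(ssc) -
        findInterval(thresholds, ssc, left.open = TRUE))
    }
  })
  counts
}

merge_windows <- function(tr, sig, mp, fdr_q) {
  gap <- which(diff(sig) > mp - 1L |
                 tr$gene_id[sig[-1]] != tr$gene_id[sig[-length(sig)]])
  first <- sig[c(1L, gap + 1L)]
  last <- sig[c(gap, length(sig))] + mp - 1L
  score <- mapply(function(a, b) mean(tr$value[a:b]), first, last)
  data.frame(chrom = tr$chrom[first], start = tr$start[first],
             end = tr$end[last],
             name = sprintf("peak%05d", seq_along(first)),
             score = score, n_probes = last - first + 1L,
             fdr_q = fdr_q, stringsAsFactors = FALSE)
}

#' Per-gene gain/loss score on a differentiation delta track
#'
#' For each promoter, slides a `min_probes`-wide window over the gene's
#' probes on the delta track and reports the windowed mean of largest
#' magnitude, keeping its sign: positive for gain, negative for loss of
#' the modification relative to the progenitor. Promoters with fewer than
#' `min_probes` probes use a single window over all their probes; promoters
#' with no probes get NA and `callable = FALSE`.
#'
#' @param delta_track A `norm_track` with mode "delta".
#' @param windows Promoter windows (gene universe).
#' @param min_probes Window width in probes.
#' @return `data.frame`: gene_id, score, n_probes, callable.
#' @export
gene_delta_score <- function(delta_track, windows, min_probes = 4L) {
  if (!identical(attr(delta_track, "mode"), "delta"))
    stop_input("gene_delta_score requires a delta-mode track")
  tr <- as.data.frame(delta_track)
  tr <- tr[!tr$is_background & !is.na(tr$gene_id), ]
  tr <- tr[order(tr$chrom, tr$start), ]
  by_gene <- split(tr$value, tr$gene_id)
  score <- rep(NA_real_, nrow(windows))
  npr <- integer(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    v <- by_gene[[windows$gene_id[i]]]
    if (is.null(v)) next
    npr[i] <- length(v)
    k <- min(as.integer(min_probes), length(v))
    sc <- frollmean(v, k, align = "left")
    sc <- sc[!is.na(sc)]
    score[i] <- sc[which.max(abs(sc))]
  }
  data.frame(gene_id = windows$gene_id, score = score, n_probes = npr,
             callable = npr > 0L, stringsAsFactors = FALSE)
}

#' Write / read called peaks as BED6+
#'
#' BED6 columns (name = peak id, score = mean log2 ratio x 100, rounded,
#' strand '.') plus extra columns n_probes, fdr_q and the unrounded score,
#' so that `read_peaks` restores the peak table losslessly.
#'
#' @param peaks Peak `data.frame` from [call_peaks()].
#' @param path File path.
#' @return `read_peaks` returns the peak `data.frame`.
#' @export
write_peaks <- function(peaks, path) {
  bed <- data.frame(chrom = peaks$chrom, start = peaks$start,
                    end = peaks$end, name = peaks$name,
                    score = round(peaks$score * 100), strand = ".",
                    extra1 = peaks$n_probes, extra2 = peaks$fdr_q,
                    extra3 = peaks$score, stringsAsFactors = FALSE)
  write_bed(bed, path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  bed <- read_bed(path)
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             name = bed$name, score = as.numeric(bed$extra3),
             n_probes = as.integer(bed$extra1),
             fdr_q = as.numeric(bed$extra2), stringsAsFactors = FALSE)
}
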