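#' Assign called peaks to promoters
#'
#' A gene is marked when at least one peak overlaps its promoter window by
#' at least 1 bp (0-based half-open intervals, so a peak ending exactly at
#' the window start does not overlap). The mark's score is the maximum
#' score among overlapping peaks. Every gene in `windows` is reported;
#' genes without any overlapping peak come back unmarked with score NA.
#'
#' @param peaks Peak `data.frame` ([call_peaks()] output).
#' @param windows Promoter windows ([promoter_windows()] output).
#' @param cell_type,modification Labels stamped onto the calls.
#' @return `data.frame` of mark calls: gene_id, cell_type, modification,
#'   marked, score (NA iff unmarked).
#' @export
assign_peaks <- function(peaks, windows, cell_type = NA_character_,
                         modification = NA_character_) {
  marked <- rep(FALSE, nrow(windows))
  score <- rep(NA_real_, nrow(windows))
  if (nrow(peaks)) {
    pk <- to_granges(peaks$chrom, peaks$start, peaks$end)
    wn <- to_granges(windows$chrom, windows$start, windows$end)
    hits <- GenomicRanges::findOverlaps(pk, wn, minoverlap = 1L)
    if (length(hits)) {
      best <- tapply(peaks$score[S4Vectors::queryHits(hits)],
                     S4Vectors::subjectHits(hits), max)
      idx <- as.integer(names(best))
      marked[idx] <- TRUE
      score[idx] <- as.numeric(best)
    }
  }
  data.frame(gene_id = windows$gene_id, cell_type = cell_type,
             modification = modification, marked = marked, score = score,
             stringsAsFactors = FALSE)
}

#' TSS-anchored metaprofile of a normalized track
#'
#' Converts each non-background probe's midpoint to a signed TSS-relative
#' coordinate (strand-aware: upstream negative, downstream positive) and
#' averages track values in fixed-width bins tiling
#' `[-upstream, +downstream]`. This is the "average density around the
#' TSS" view used to compare the spatial shape of active marks (bimodal
#' with a dip at the TSS) to H3K27me3 (flat across the promoter).
#'
#' @param track A `norm_track`.
#' @param annotation Gene annotation supplying TSS and strand.
#' @param bin_size Bin width in bp (> 0).
#' @param upstream,downstream Profile extent in bp around the TSS.
#' @return `data.frame`: bin_center (signed bp), mean (mean track value,
#'   NA for empty bins), n (probes in bin).
#' @export
metaprofile <- function(track, annotation, bin_size = 50L,
                        upstream = 2000L, downstream = 500L) {
  if (bin_size <= 0) stop_input("bin_size must be positive")
  tr <- as.data.frame(track)
  tr <- tr[!tr$is_background & !is.na(tr$gene_id), ]
  ann <- annotation[match(tr$gene_id, annotation$gene_id), ]
  if (anyNA(ann$gene_id))
    stop_input("track contains genes absent from the annotation")
  mid <- (tr$start + tr$end) / 2
  rel <- tss_relative(mid, ann$tss, ann$strand)
  breaks <- seq(-upstream, downstream, by = bin_size)
  if (tail(breaks, 1) < downstream) breaks <- c(breaks, downstream)
  bin <- cut(rel, breaks, right = FALSE, include.lowest = TRUE)
  keep <- !is.na(bin)
  mean_v <- tapply(tr$value[keep], bin[keep], mean)
  n_v <- tapply(rep(1L, sum(keep)), bin[keep], sum)
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  out <- data.frame(bin_center = centers,
                    mean = as.numeric(mean_v[levels(bin)]),
                    n = as.integer(ifelse(is.na(n_v[levels(bin)]), 0L,
                                          n_v[levels(bin)])))
  rownames(out) <- NULL
  out
}
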