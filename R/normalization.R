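#' Scale every channel to a common random-genomic background level
#'
#' Each "cell:antibody" column is multiplied by a factor that brings the
#' median intensity of its background (random genomic) probes to a common
#' reference — the grand median of the per-channel background medians.
#' This removes per-channel gain differences before any ratio is formed;
#' being multiplicative, it cancels exactly in downstream log2 ratios
#' whenever both channels were already on the same scale.
#'
#' @param intensities Intensity table (probe_id + channel columns, linear).
#' @param probes Probe table carrying the is_background flag.
#' @return Intensity table of the same shape, background-scaled, with the
#'   per-channel scale factors in `attr(, "scale_factors")`.
#' @export
background_normalize <- function(intensities, probes) {
  bg_ids <- probes$probe_id[probes$is_background]
  if (!length(bg_ids))
    stop_input("no background probes; cannot normalize to genomic background")
  bg_rows <- intensities$probe_id %in% bg_ids
  if (!any(bg_rows))
    stop_input("intensity table contains none of the background probes")
  chans <- setdiff(names(intensities), "probe_id")
  med <- vapply(chans, function(ch) median(intensities[[ch]][bg_rows]),
                numeric(1))
  if (any(med <= 0)) stop_input("non-positive background median")
  ref <- median(med)
  factors <- ref / med
  out <- intensities
  for (ch in chans) out[[ch]] <- out[[ch]] * factors[[ch]]
  attr(out, "scale_factors") <- factors
  out
}

new_norm_track <- function(probes, value, cell_type, modification, mode) {
  stopifnot(mode %in% c("ratio", "delta"))
  if (any(!is.finite(value)))
    stop_input("non-finite values in normalized track")
  tr <- data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                   start = probes$start, end = probes$end,
                   gene_id = probes$gene_id,
                   is_background = probes$is_background,
                   value = value, stringsAsFactors = FALSE)
  attr(tr, "cell_type") <- cell_type
  attr(tr, "modification") <- modification
  attr(tr, "mode") <- mode
  class(tr) <- c("norm_track", "data.frame")
  tr
}

#' Normalize a modification channel against total histone H3
#'
#' The track value at each probe is the log2 ratio of the (background
#' scaled) modification intensity to the H3 intensity of the same cell
#' type: `log2(mod) - log2(H3)`. This controls for nucleosome occupancy
#' and probe behaviour, leaving modification-specific enrichment.
#'
#' @param intensities Intensity table (ideally after
#'   [background_normalize()]).
#' @param probes Probe table (coordinates and background flags are carried
#'   onto the track).
#' @param cell_type,modification Which channel pair to use; the H3 channel
#'   of the same cell type is the reference.
#' @return A `norm_track` (probe-level data.frame with a `value` column and
#'   cell_type / modification / mode metadata; mode "ratio").
#' @export
h3_normalize <- function(intensities, probes, cell_type, modification) {
  if (!modification %in% MOD_MARKS)
    stop_input("modification must be one of ", paste(MOD_MARKS, collapse = ", "))
  mod_ch <- channel_id(cell_type, modification)
  h3_ch <- channel_id(cell_type, "H3")
  miss <- setdiff(c(mod_ch, h3_ch), names(intensities))
  if (length(miss))
    stop_input("missing channel(s): ", paste(miss, collapse = ", "))
  m <- match(probes$probe_id, intensities$probe_id)
  if (anyNA(m)) stop_input("probes missing from the intensity table")
  mod <- intensities[[mod_ch]][m]
  h3 <- intensities[[h3_ch]][m]
  if (any(mod <= 0) || any(h3 <= 0))
    stop_input("intensities must be strictly positive for log2 ratios")
  new_norm_track(probes, log2(mod) - log2(h3), cell_type, modification,
                 "ratio")
}

#' Differentiation delta track: derived cell type minus progenitor
#'
#' Per-probe subtraction of the progenitor (monocyte) H3-normalized track
#' from the corresponding track of a derived cell type, exposing gain
#' (positive) or loss (negative) of a modification during differentiation.
#'
#' @param track_cell,track_ref `norm_track`s for the same modification over
#'   the same probe universe (e.g. MF and MO).
#' @return A `norm_track` with mode "delta" and the derived cell's label.
#' @export
differentiation_delta <- function(track_cell, track_ref) {
  if (!identical(track_cell$probe_id, track_ref$probe_id))
    stop_input("tracks are not over the same probes (order included)")
  mod_a <- attr(track_cell, "modification")
  if (!identical(mod_a, attr(track_ref, "modification")))
    stop_input("tracks profile different modifications")
  new_norm_track(track_cell, track_cell$value - track_ref$value,
                 attr(track_cell, "cell_type"), mod_a, "delta")
}

#' Serialize a normalized track as TSV plus a YAML metadata sidecar
#'
#' The TSV holds probe_id, chrom, start, end, gene_id, is_background and
#' value; `<path>.yaml` records cell_type, modification and mode so that
#' [read_track()] restores the full object.
#'
#' @param track A `norm_track`.
#' @param path TSV path; metadata goes to `<path>.yaml`.
#' @return `read_track` returns the restored `norm_track`.
#' @export
write_track <- function(track, path) {
  write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(cell_type = attr(track, "cell_type"),
               modification = attr(track, "modification"),
               mode = attr(track, "mode"))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  df$gene_id <- as.character(df$gene_id)
  new_norm_track(df, df$value, meta$cell_type, meta$modification, meta$mode)
}
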