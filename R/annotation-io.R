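#' Strand-aware promoter windows around each TSS
#'
#' The promoter of a gene is the interval from `upstream` bp upstream to
#' `downstream` bp downstream of its TSS, in transcription orientation.
#' Coordinates are 0-based half-open: for a plus-strand gene the window is
#' `[tss - upstream, tss + downstream)`; for a minus-strand gene it is the
#' mirror image `[tss - downstream + 1, tss + upstream + 1)`. Windows are
#' clipped at position 0.
#'
#' @param annotation `data.frame` with gene_id, chrom, strand, tss.
#' @param upstream,downstream Extent in bp (defaults 2000 / 500).
#' @return `data.frame`: gene_id, chrom, start, end.
#' @export
#' @examples
#' ann <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+", tss = 10000)
#' promoter_windows(ann)  # [8000, 10500)
promoter_windows <- function(annotation, upstream = 2000L,
                             downstream = 500L) {
  validate_annotation(annotation)
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$tss - upstream,
                  annotation$tss - downstream + 1L)
  end <- ifelse(plus, annotation$tss + downstream,
                annotation$tss + upstream + 1L)
  data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
             start = pmax(as.integer(start), 0L), end = as.integer(end),
             stringsAsFactors = FALSE)
}

validate_annotation <- function(annotation) {
  need <- c("gene_id", "chrom", "strand", "tss")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop_input("annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(annotation$gene_id))
    stop_input("duplicate gene_id in annotation")
  bad <- !annotation$strand %in% c("+", "-")
  if (any(bad))
    stop_input("unknown strand for gene(s): ",
               paste(head(annotation$gene_id[bad], 5), collapse = ", "))
  if (any(annotation$tss < 0))
    stop_input("negative TSS coordinates")
  invisible(annotation)
}

#' Read / write gene annotation as TSV
#'
#' Tab-delimited with header `gene_id  chrom  strand  tss`; a leading
#' comment line records that tss is 0-based. Round-trip write -> read is
#' the identity.
#'
#' @param path File path.
#' @param annotation Annotation `data.frame`.
#' @return `read_annotation` returns the annotation `data.frame`.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$tss <- as.integer(df$tss)
  validate_annotation(df)
  df
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  validate_annotation(annotation)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# gene annotation; tss is the 0-based first transcribed base",
             con)
  write.table(annotation, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Accepts a GFF3 file and keeps `gene`-type features only. The TSS is the
#' 0-based first transcribed base: the feature start for plus-strand genes,
#' the feature end for minus-strand genes. Gene ids come from the ID
#' attribute. Requires the rtracklayer package.
#'
#' @param path GFF3 file path.
#' @return Annotation `data.frame` (gene_id, chrom, strand, tss).
#' @export
read_gff3_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_input("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (!length(gr)) stop_input("no gene features in ", path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop_input("gene feature(s) without strand in ", path)
  # GFF3 is 1-based closed; convert to a 0-based TSS position
  tss <- ifelse(strand == "+", GenomicRanges::start(gr) - 1L,
                GenomicRanges::end(gr) - 1L)
  ann <- data.frame(
    gene_id = as.character(gr$ID %||% gr$Name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand, tss = as.integer(tss), stringsAsFactors = FALSE)
  validate_annotation(ann)
  ann
}

#' Read / write BED intervals
#'
#' Minimal BED3/BED6 support with 0-based half-open coordinates and
#' per-line validation: malformed rows, negative coordinates or start >=
#' end raise an error naming the offending line. Extra columns beyond the
#' sixth are preserved by `read_bed` (as `extra1`, `extra2`, ...) and
#' written by `write_bed` when present.
#'
#' @param path File path.
#' @param intervals `data.frame` with chrom, start, end and optionally
#'   name, score, strand plus extra columns.
#' @return `read_bed` returns a `data.frame` with chrom, start, end and
#'   (when present) name, score, strand, extras.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) stop_input("no interval records in ", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop_input("line ", idx[which(nf < 3)[1]], " of ", path,
               ": fewer than 3 BED fields")
  ncol <- min(nf)
  get <- function(j) vapply(fields, `[[`, character(1), j)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop_input("line ", idx[which(bad)[1]], " of ", path,
               ": non-numeric coordinates")
  bad <- start < 0 | end <= start
  if (any(bad))
    stop_input("line ", idx[which(bad)[1]], " of ", path,
               ": requires 0 <= start < end")
  out <- data.frame(chrom = get(1), start = start, end = end,
                    stringsAsFactors = FALSE)
  if (ncol >= 4) out$name <- get(4)
  if (ncol >= 5) out$score <- suppressWarnings(as.numeric(get(5)))
  if (ncol >= 6) out$strand <- get(6)
  if (ncol >= 7)
    for (j in 7:ncol) out[[paste0("extra", j - 6)]] <- get(j)
  out
}

#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(intervals))
  if (length(miss))
    stop_input("intervals lack column(s): ", paste(miss, collapse = ", "))
  if (any(intervals$start < 0) || any(intervals$end <= intervals$start))
    stop_input("intervals must satisfy 0 <= start < end")
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  extras <- grep("^extra[0-9]+$", names(intervals), value = TRUE)
  write.table(intervals[, c(cols, extras)], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write the probe layout
#'
#' Probes are serialized as BED6 (name = probe id, score = 0, strand '.').
#' On reading, gene assignment and the background flag are re-derived by
#' interval overlap with the supplied promoter windows: a probe overlapping
#' no window is a background probe.
#'
#' @param path File path.
#' @param probes Probe `data.frame` (see [simulate_probes()]).
#' @param windows Promoter windows used to re-derive gene_id/is_background.
#' @return `read_probes` returns the probe `data.frame`.
#' @export
write_probes <- function(probes, path) {
  bed <- data.frame(chrom = probes$chrom, start = probes$start,
                    end = probes$end, name = probes$probe_id,
                    score = 0L, strand = ".", stringsAsFactors = FALSE)
  write_bed(bed, path)
}

#' @rdname write_probes
#' @export
read_probes <- function(path, windows) {
  bed <- read_bed(path)
  if (is.null(bed$name)) stop_input("probe BED must carry names (BED6)")
  if (anyDuplicated(bed$name)) stop_input("duplicate probe ids in ", path)
  pr <- to_granges(bed$chrom, bed$start, bed$end)
  wn <- to_granges(windows$chrom, windows$start, windows$end)
  hits <- GenomicRanges::findOverlaps(pr, wn)
  gene <- rep(NA_character_, nrow(bed))
  gene[S4Vectors::queryHits(hits)] <- windows$gene_id[S4Vectors::subjectHits(hits)]
  data.frame(probe_id = bed$name, chrom = bed$chrom, start = bed$start,
             end = bed$end, gene_id = gene, is_background = is.na(gene),
             stringsAsFactors = FALSE)
}

read_matrix_tsv <- function(path, id_col) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != id_col)
    stop_input(path, ": first column must be ", id_col)
  if (anyDuplicated(df[[1]]))
    stop_input(path, ": duplicate ids")
  df
}

#' Read / write intensity and expression matrices as TSV
#'
#' Intensity tables have a probe_id column plus one positive linear-scale
#' column per "cell:antibody" channel; expression tables have a gene_id
#' column plus "cell:replicate" columns. Headers are preserved verbatim.
#'
#' @param path File path.
#' @param x Matrix-like `data.frame` to write.
#' @return Readers return the `data.frame`.
#' @export
read_intensities <- function(path) {
  df <- read_matrix_tsv(path, "probe_id")
  vals <- as.matrix(df[-1])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_input(path, ": intensities must be positive and finite")
  df
}

#' @rdname read_intensities
#' @export
write_intensities <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_intensities
#' @export
read_expression <- function(path) read_matrix_tsv(path, "gene_id")

#' @rdname read_intensities
#' @export
write_expression <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
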