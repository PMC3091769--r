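#' Chromatin-state transition table between two cell types
#'
#' Cross-tabulates the 8-way promoter state of each gene in a progenitor
#' cell type against its state in a derived cell type (e.g. monocyte vs
#' macrophage). Genes with a missing (NA) state in either cell type are
#' excluded from the table and counted separately.
#'
#' @param states_from,states_to State `data.frame`s (gene_id, cell_type,
#'   state) for the two endpoints; the gene universes must intersect.
#' @return Object of class `transition_table`: list with `counts` (8x8
#'   integer matrix, rows = from-state), `fractions` (row-normalized; NA
#'   rows for empty starting states), `n_excluded`, `from_cell`, `to_cell`.
#' @export
transitions <- function(states_from, states_to) {
  genes <- intersect(states_from$gene_id, states_to$gene_id)
  if (!length(genes)) stop_input("disjoint gene universes")
  a <- states_from$state[match(genes, states_from$gene_id)]
  b <- states_to$state[match(genes, states_to$gene_id)]
  ok <- !is.na(a) & !is.na(b)
  counts <- table(factor(a[ok], levels = STATE_LEVELS),
                  factor(b[ok], levels = STATE_LEVELS))
  counts <- matrix(as.integer(counts), 8, 8,
                   dimnames = list(STATE_LEVELS, STATE_LEVELS))
  rs <- rowSums(counts)
  fractions <- counts / ifelse(rs == 0, NA_real_, rs)
  structure(list(counts = counts, fractions = fractions,
                 n_excluded = sum(!ok),
                 from_cell = states_from$cell_type[1],
                 to_cell = states_to$cell_type[1]),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat("Chromatin-state transitions:", x$from_cell, "->", x$to_cell, "\n")
  cat(sum(x$counts), "genes;", x$n_excluded, "excluded (missing state)\n")
  print(x$counts)
  invisible(x)
}

#' Per-state persistence and conversion summary
#'
#' For each starting state: the number of genes, the fraction retaining
#' the state, the full fraction row to every destination state, and —
#' because the fate of lone active marks is the biologically interesting
#' statistic — `lost_or_double`, the fraction moving to "none" or to the
#' H3K4me3+AcH3 double mark. Starting states with no genes come back with
#' NA fractions (flagged, not dropped).
#'
#' @param tt A `transition_table`.
#' @return `data.frame`: from_state, n, retained, lost_or_double, and one
#'   `to_<state>` column per destination state.
#' @export
persistence_summary <- function(tt) {
  stopifnot(inherits(tt, "transition_table"))
  fr <- tt$fractions
  out <- data.frame(from_state = STATE_LEVELS,
                    n = as.integer(rowSums(tt$counts)),
                    retained = diag(fr),
                    lost_or_double = fr[, "none"] + fr[, "K4+Ac"],
                    stringsAsFactors = FALSE)
  # keep the diagonal out of the "moved to double mark" reading
  out$lost_or_double[out$from_state == "none"] <- fr["none", "K4+Ac"]
  out$lost_or_double[out$from_state == "K4+Ac"] <- fr["K4+Ac", "none"]
  to <- as.data.frame(fr)
  names(to) <- paste0("to_", STATE_LEVELS)
  out <- cbind(out, to)
  rownames(out) <- NULL
  out
}

#' Write a transition table and its summary as TSV
#'
#' @param tt A `transition_table`.
#' @param path Output TSV for the count matrix; the per-state summary is
#'   written next to it as `<path base>_summary.tsv`.
#' @return Invisibly, the two paths.
#' @export
write_transitions <- function(tt, path) {
  counts <- data.frame(from_state = rownames(tt$counts), tt$counts,
                       check.names = FALSE)
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  spath <- sub("(\\.[^.]+)?$", "_summary\\1", path)
  if (identical(spath, path)) spath <- paste0(path, "_summary")
  write.table(persistence_summary(tt), spath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(path, spath))
}
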