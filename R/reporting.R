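#' Expression-band and mark-flag grid for a functional gene group
#'
#' For a user-supplied gene list, tabulates each gene's expression band
#' (quartile of the normalized signal across all genes, 1 = lowest) and
#' its three mark flags in every cell type — the integrated
#' "expression level vs modification status" display used for functional
#' gene groups such as antigen presentation or phagocytosis. Unknown gene
#' ids raise an error listing them rather than being dropped.
#'
#' @param gene_list Character vector of gene ids.
#' @param states State `data.frame` from [classify_states()].
#' @param expression Expression matrix (gene_id + "cell:replicate"
#'   columns).
#' @return List: `matrix` — `data.frame` with gene_id, cell_type, band
#'   (1-4), K4, Ac, K27; `n_double_marked` — per cell type, how many genes
#'   in the group carry the H3K4me3+AcH3 double mark (with or without
#'   H3K27me3).
#' @export
gene_group_matrix <- function(gene_list, states, expression) {
  unknown <- setdiff(gene_list,
                     intersect(states$gene_id, expression$gene_id))
  if (length(unknown))
    stop_input("unknown gene id(s): ", paste(unknown, collapse = ", "))
  cells <- unique(states$cell_type)
  rows <- list(); dbl <- setNames(integer(length(cells)), cells)
  for (cell in cells) {
    expr_cols <- grep(paste0("^", cell, ":"), names(expression))
    all_means <- rowMeans(expression[, expr_cols, drop = FALSE])
    qs <- quantile(all_means, c(0.25, 0.5, 0.75), names = FALSE)
    st <- states[states$cell_type == cell, ]
    s <- st$state[match(gene_list, st$gene_id)]
    fl <- flags_from_state(s)
    gm <- all_means[match(gene_list, expression$gene_id)]
    band <- findInterval(gm, qs) + 1L
    rows[[cell]] <- data.frame(gene_id = gene_list, cell_type = cell,
                               band = band, K4 = fl$K4, Ac = fl$Ac,
                               K27 = fl$K27, stringsAsFactors = FALSE)
    dbl[[cell]] <- sum(fl$K4 & fl$Ac)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(matrix = out, n_double_marked = dbl)
}

#' Summarize differentiation deltas over gene clusters
#'
#' For each cluster (a named list of gene ids, e.g. a genomic chemokine
#' cluster), reports the fraction of members gaining the modification
#' (positive delta score) and the concordance between delta sign and the
#' differential-expression direction (up goes with gain, down with loss;
#' genes called unchanged are left out of the concordance denominator).
#'
#' @param clusters Named list of character vectors of gene ids.
#' @param delta_scores [gene_delta_score()] output.
#' @param de_results [call_differential()] output (same contrast).
#' @return `data.frame`: cluster, n, n_scored, gain_fraction,
#'   de_concordance.
#' @export
cluster_delta_summary <- function(clusters, delta_scores, de_results) {
  if (!length(clusters) || is.null(names(clusters)))
    stop_input("clusters must be a non-empty named list")
  rows <- lapply(names(clusters), function(cl) {
    members <- clusters[[cl]]
    if (!length(members)) stop_input("empty cluster: ", cl)
    miss <- setdiff(members, delta_scores$gene_id)
    if (length(miss))
      stop_input("cluster ", cl, " member(s) not scored: ",
                 paste(miss, collapse = ", "))
    d <- delta_scores$score[match(members, delta_scores$gene_id)]
    ok <- !is.na(d)
    de <- de_results$call[match(members, de_results$gene_id)]
    dirn <- ifelse(de == "up", 1, ifelse(de == "down", -1, NA))
    conc <- sign(d) == dirn
    data.frame(cluster = cl, n = length(members), n_scored = sum(ok),
               gain_fraction = mean(d[ok] > 0),
               de_concordance = if (any(!is.na(conc[ok])))
                 mean(conc[ok], na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
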