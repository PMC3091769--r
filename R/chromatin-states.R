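#' Combine per-mark calls into 8-way combinatorial promoter states
#'
#' Maps the three boolean mark calls (H3K4me3, AcH3, H3K27me3) of each
#' (gene, cell type) to one of the eight states in [state_levels()]
#' ("none" through "K4+Ac+K27"). Every gene/cell must carry a call for all
#' three modifications.
#'
#' @param mark_calls Long `data.frame` of calls ([assign_peaks()] output,
#'   concatenated over modifications and cell types).
#' @return `data.frame`: gene_id, cell_type, state.
#' @export
classify_states <- function(mark_calls) {
  need <- c("gene_id", "cell_type", "modification", "marked")
  miss <- setdiff(need, names(mark_calls))
  if (length(miss))
    stop_input("mark_calls lack column(s): ", paste(miss, collapse = ", "))
  key <- interaction(mark_calls$gene_id, mark_calls$cell_type, drop = TRUE)
  got <- tapply(mark_calls$modification, key,
                function(m) sum(MOD_MARKS %in% m))
  if (any(got < 3)) {
    bad <- names(got)[got < 3]
    stop_input("missing modification call(s) for: ",
               paste(head(bad, 5), collapse = ", "),
               if (length(bad) > 5) " ...")
  }
  grab <- function(mk) {
    sub <- mark_calls[mark_calls$modification == mk, ]
    sub[order(sub$gene_id, sub$cell_type), ]
  }
  k4 <- grab("H3K4me3"); ac <- grab("AcH3"); k27 <- grab("H3K27me3")
  stopifnot(identical(k4$gene_id, ac$gene_id),
            identical(k4$gene_id, k27$gene_id))
  data.frame(gene_id = k4$gene_id, cell_type = k4$cell_type,
             state = state_from_flags(k4$marked, ac$marked, k27$marked),
             stringsAsFactors = FALSE)
}

#' Split state vectors back into per-mark boolean calls
#'
#' Inverse of [classify_states()] (scores are not recoverable and come
#' back NA).
#'
#' @param states `data.frame` with gene_id, cell_type, state.
#' @return Long mark-call `data.frame`.
#' @export
split_states <- function(states) {
  fl <- flags_from_state(states$state)
  out <- do.call(rbind, lapply(MOD_MARKS, function(mk) {
    data.frame(gene_id = states$gene_id, cell_type = states$cell_type,
               modification = mk, marked = fl[[mark_token[[mk]]]],
               score = NA_real_, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' State frequencies over a gene subset
#'
#' Percentage of genes in each of the eight combinatorial states, per cell
#' type, over the whole universe or a supplied subset (e.g. expressed or
#' inactive genes).
#'
#' @param states State `data.frame` from [classify_states()].
#' @param gene_subset Optional character vector of gene ids.
#' @param cell_type Optional single cell type to restrict to.
#' @return `data.frame`: cell_type, state, n, pct; percentages sum to 100
#'   per cell type.
#' @export
state_frequencies <- function(states, gene_subset = NULL,
                              cell_type = NULL) {
  df <- states
  if (!is.null(cell_type)) df <- df[df$cell_type %in% cell_type, ]
  if (!is.null(gene_subset)) {
    extra <- setdiff(gene_subset, states$gene_id)
    if (length(extra))
      stop_input("subset gene(s) not in the state table: ",
                 paste(head(extra, 5), collapse = ", "))
    df <- df[df$gene_id %in% gene_subset, ]
  }
  if (!nrow(df)) stop_input("empty gene subset")
  out <- do.call(rbind, lapply(split(df, df$cell_type), function(d) {
    n <- table(factor(d$state, levels = STATE_LEVELS))
    data.frame(cell_type = d$cell_type[1], state = STATE_LEVELS,
               n = as.integer(n), pct = 100 * as.numeric(n) / nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pearson correlation across (modification, cell type) mark vectors
#'
#' Builds a gene-by-channel matrix with one column per (cell type,
#' modification) pair — binary 0/1 mark indicators by default, or
#' continuous peak scores (unmarked genes contribute 0) — and returns the
#' full Pearson correlation matrix (9x9 for three marks in three cell
#' types). Channels with zero variance yield NA entries and a warning
#' rather than a silent 0.
#'
#' @param mark_calls Long mark-call `data.frame`.
#' @param use "binary" (default) or "score".
#' @return Symmetric correlation matrix with "cell:modification" labels.
#' @export
mark_correlation <- function(mark_calls, use = c("binary", "score")) {
  use <- match.arg(use)
  genes <- sort(unique(mark_calls$gene_id))
  if (length(genes) < 3) stop_input("need >= 3 genes for correlation")
  combos <- unique(mark_calls[c("cell_type", "modification")])
  combos <- combos[order(match(combos$cell_type,
                               unique(mark_calls$cell_type)),
                         match(combos$modification, MOD_MARKS)), ]
  m <- sapply(seq_len(nrow(combos)), function(i) {
    sub <- mark_calls[mark_calls$cell_type == combos$cell_type[i] &
                        mark_calls$modification == combos$modification[i], ]
    v <- if (use == "binary") as.numeric(sub$marked) else
      ifelse(sub$marked, sub$score, 0)
    v[match(genes, sub$gene_id)]
  })
  colnames(m) <- paste(combos$cell_type, combos$modification, sep = ":")
  sds <- apply(m, 2, sd)
  cm <- suppressWarnings(cor(m))
  if (any(sds == 0)) {
    warning("zero-variance channel(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            "; correlations set to NA", call. = FALSE)
    cm[sds == 0, ] <- NA; cm[, sds == 0] <- NA
  }
  diag(cm) <- ifelse(sds == 0, NA, 1)
  cm
}

#' Mark enrichment among highly vs lowly expressed genes
#'
#' Ranks genes by mean expression in one cell type (ties broken by stable
#' gene-id order), takes the top-n and bottom-n sets, and reports the
#' percentage of each set carrying the modification together with the
#' two-sided exact hypergeometric (Fisher) P-value of the 2x2 table
#' top/bottom x marked/unmarked.
#'
#' @param mark_calls Long mark-call `data.frame`.
#' @param expression Expression matrix (gene_id + "cell:replicate" columns).
#' @param cell_type Cell type whose expression and calls are used.
#' @param modification One of [mark_names()].
#' @param n Set size (default 2000); requires >= 2n rankable genes.
#' @return List: `result` — `data.frame` with one row per set (modification,
#'   set, n, n_marked, frequency in percent); `p_value` — Fisher exact
#'   two-sided P.
#' @export
expression_enrichment <- function(mark_calls, expression, cell_type,
                                  modification, n = 2000L) {
  calls <- mark_calls[mark_calls$cell_type == cell_type &
                        mark_calls$modification == modification, ]
  if (!nrow(calls)) stop_input("no calls for ", cell_type, "/", modification)
  expr_cols <- grep(paste0("^", cell_type, ":"), names(expression))
  if (!length(expr_cols))
    stop_input("no expression columns for cell type ", cell_type)
  genes <- intersect(calls$gene_id, expression$gene_id)
  if (length(genes) < 2 * n)
    stop_input("need at least 2n = ", 2 * n, " rankable genes, have ",
               length(genes))
  genes <- sort(genes)  # stable tie-break order
  mean_expr <- rowMeans(expression[match(genes, expression$gene_id),
                                   expr_cols, drop = FALSE])
  ord <- order(-mean_expr, genes)
  top <- genes[ord[seq_len(n)]]
  bottom <- genes[ord[seq(length(genes) - n + 1L, length(genes))]]
  marked <- setNames(calls$marked, calls$gene_id)
  k_top <- sum(marked[top]); k_bot <- sum(marked[bottom])
  p <- fisher.test(matrix(c(k_top, n - k_top, k_bot, n - k_bot), 2L,
                          byrow = TRUE))$p.value
  res <- data.frame(
    modification = modification,
    set = c(sprintf("top-%d", n), sprintf("bottom-%d", n)),
    n = n, n_marked = c(k_top, k_bot),
    frequency = 100 * c(k_top, k_bot) / n,
    stringsAsFactors = FALSE)
  list(result = res, p_value = p)
}

#' Flag expressed genes against a background signal model
#'
#' A gene counts as expressed in a cell type when its mean linear signal
#' exceeds the `background_quantile`-th quantile of a background signal
#' distribution — by default the pooled expression values of the matrix
#' itself, or an explicit `background` vector (e.g. draws from the
#' simulator's unexpressed-state distribution) when available.
#'
#' @param expression Expression matrix.
#' @param cell_type Cell type to evaluate.
#' @param background Optional numeric vector of background signals.
#' @param background_quantile Quantile defining the detection threshold
#'   (default 0.75).
#' @return Named logical vector over gene ids.
#' @export
expressed_genes <- function(expression, cell_type, background = NULL,
                            background_quantile = 0.75) {
  expr_cols <- grep(paste0("^", cell_type, ":"), names(expression))
  if (!length(expr_cols))
    stop_input("no expression columns for cell type ", cell_type)
  m <- rowMeans(expression[, expr_cols, drop = FALSE])
  bg <- background %||% unlist(expression[-1], use.names = FALSE)
  thr <- quantile(bg, background_quantile, names = FALSE)
  setNames(m > thr, expression$gene_id)
}
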