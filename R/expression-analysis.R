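#' Rank-invariant scaling of expression columns to a reference
#'
#' For each sample column, genes whose expression rank differs from the
#' reference column's rank by less than `rank_tol` x (number of genes)
#' form the rank-invariant set; the column is divided by the median
#' signal ratio (column / reference) over that set. Because ranks are
#' unchanged by a global scaling, the procedure converges after the first
#' pass; it nevertheless iterates and verifies convergence (step factor
#' within `tol` of 1) within `max_iter` rounds.
#'
#' @param expression Expression matrix (gene_id + sample columns, linear).
#' @param reference Reference column name or index among the sample
#'   columns (default: the first sample column).
#' @param rank_tol Rank-difference tolerance as a fraction of the gene
#'   count (default 0.05).
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the per-step scale factor.
#' @return The normalized matrix, with cumulative per-column scale factors
#'   in `attr(, "scale_factors")`.
#' @export
rank_invariant_normalize <- function(expression, reference = 1L,
                                     rank_tol = 0.05, max_iter = 10L,
                                     tol = 1e-8) {
  samp <- setdiff(names(expression), "gene_id")
  ref <- if (is.character(reference)) reference else samp[reference]
  if (!ref %in% samp) stop_input("unknown reference column: ", reference)
  out <- expression
  ng <- nrow(out)
  cutoff <- rank_tol * ng
  r_ref <- rank(out[[ref]], ties.method = "average")
  factors <- setNames(rep(1, length(samp)), samp)
  for (col in samp) {
    for (it in seq_len(max_iter)) {
      r_col <- rank(out[[col]], ties.method = "average")
      inv <- abs(r_col - r_ref) < cutoff
      if (!any(inv))
        stop_input("empty rank-invariant set for column ", col,
                   "; increase rank_tol")
      f <- median(out[[col]][inv] / out[[ref]][inv])
      out[[col]] <- out[[col]] / f
      factors[[col]] <- factors[[col]] * f
      if (abs(log2(f)) < tol) break
      if (it == max_iter)
        stop_input("rank-invariant normalization did not converge for ",
                   col)
    }
  }
  attr(out, "scale_factors") <- factors
  out
}

#' Differential expression by fold change and per-gene P-value
#'
#' For each gene, the fold change is the ratio of arithmetic means of the
#' linear replicate signals (`cell_a` over `cell_b`), and the P-value
#' comes from a two-sided two-sample t comparison of the log2 replicate
#' values. With the typical 2-3 replicates per cell type the pooled
#' (equal-variance) test is the default: the Welch degrees-of-freedom
#' estimate is so noisy at these sizes that the unequal-variance test runs
#' markedly below its nominal size, while the pooled test is exactly
#' calibrated for equal replicate counts; set `var_equal = FALSE` for
#' Welch when replicate variances genuinely differ. A gene is called "up"
#' when fold >= `fold` and p < `alpha`, "down" when fold <= 1/`fold` and
#' p < `alpha`, otherwise "unchanged". No multiple-testing correction is
#' applied by default — the selection criterion is the raw fold + P pair —
#' but `adjust = "BH"` switches the threshold to Benjamini-Hochberg
#' adjusted values. A zero mean in the denominator is floored to the
#' smallest positive value in the matrix, with a warning.
#'
#' @param expression Expression matrix (gene_id + "cell:replicate"
#'   columns, linear scale).
#' @param cell_a,cell_b The contrast, reported as "cell_a vs cell_b".
#' @param fold Fold-change threshold (inclusive, default 2).
#' @param alpha P-value threshold (default 0.05).
#' @param adjust "none" (default) or "BH".
#' @param var_equal Pooled-variance t-test (default) vs Welch.
#' @return `data.frame`: gene_id, contrast, fold_change, p_value, call.
#' @export
call_differential <- function(expression, cell_a, cell_b, fold = 2,
                              alpha = 0.05, adjust = c("none", "BH"),
                              var_equal = TRUE) {
  adjust <- match.arg(adjust)
  cols_a <- grep(paste0("^", cell_a, ":"), names(expression))
  cols_b <- grep(paste0("^", cell_b, ":"), names(expression))
  if (length(cols_a) < 2 || length(cols_b) < 2)
    stop_input("need >= 2 replicates per cell type")
  ma <- as.matrix(expression[cols_a])
  mb <- as.matrix(expression[cols_b])
  mean_a <- rowMeans(ma); mean_b <- rowMeans(mb)
  if (any(mean_b <= 0) || any(c(ma, mb) <= 0)) {
    floor_v <- min(c(ma, mb)[c(ma, mb) > 0])
    warning("nonpositive signal floored to ", signif(floor_v, 3),
            call. = FALSE)
    ma <- pmax(ma, floor_v); mb <- pmax(mb, floor_v)
    mean_b <- pmax(mean_b, floor_v)
  }
  fc <- mean_a / mean_b
  la <- log2(ma); lb <- log2(mb)
  p <- two_sample_p(la, lb, var_equal)
  p_eff <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  call <- rep("unchanged", nrow(expression))
  call[which(fc >= fold & p_eff < alpha)] <- "up"
  call[which(fc <= 1 / fold & p_eff < alpha)] <- "down"
  data.frame(gene_id = expression$gene_id,
             contrast = paste(cell_a, "vs", cell_b),
             fold_change = fc, p_value = p, call = call,
             stringsAsFactors = FALSE)
}

# vectorized two-sided two-sample t-test over matrix rows (log2 scale);
# matches stats::t.test(var.equal = var_equal) row by row
two_sample_p <- function(la, lb, var_equal = TRUE) {
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- rowSums((la - ma)^2) / (na - 1)
  vb <- rowSums((lb - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(ma))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate rows: both sides constant
  const <- se2 == 0
  p[const] <- ifelse(ma[const] == mb[const], 1, 0)
  p
}

#' Two-way overlap accounting of differential calls
#'
#' Counts genes called up (and down) exclusively in each of two contrasts
#' and in both, in the style of a two-column differentiation comparison,
#' and reports per-contrast totals (exclusive + shared).
#'
#' @param de_a,de_b `data.frame`s from [call_differential()] over the same
#'   gene universe (e.g. MF vs MO and DC vs MO).
#' @param labels Length-2 display labels (default: the contrast strings).
#' @return `data.frame`: direction, a_only, b_only, shared, a_total,
#'   b_total, with the labels in `attr(, "labels")`.
#' @export
overlap_table <- function(de_a, de_b, labels = NULL) {
  if (!setequal(de_a$gene_id, de_b$gene_id))
    stop_input("differential results are not over the same gene universe")
  labels <- labels %||% c(de_a$contrast[1], de_b$contrast[1])
  row_for <- function(dir) {
    a <- de_a$gene_id[de_a$call == dir]
    b <- de_b$gene_id[de_b$call == dir]
    shared <- length(intersect(a, b))
    data.frame(direction = dir,
               a_only = length(a) - shared, b_only = length(b) - shared,
               shared = shared,
               a_total = length(a), b_total = length(b),
               stringsAsFactors = FALSE)
  }
  out <- rbind(row_for("up"), row_for("down"))
  attr(out, "labels") <- labels
  out
}
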