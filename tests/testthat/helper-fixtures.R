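# shared fixture builders; everything is generated in code, seeded

small_params <- function(n_genes = 60, n_chroms = 2, seed = 42, ...) {
  sim_params(n_genes = n_genes, n_chroms = n_chroms,
             n_background_probes = 100, seed = seed, ...)
}

# hand-built normalized track over one or more contiguous tiles
make_track <- function(values, gene_id, chrom = "chr1", start = NULL,
                       mode = "ratio", cell = "MO",
                       modification = "H3K4me3",
                       is_background = FALSE) {
  n <- length(values)
  if (is.null(start)) start <- seq(0L, by = 100L, length.out = n)
  probes <- data.frame(
    probe_id = sprintf("t%04d", seq_len(n)), chrom = chrom,
    start = start, end = start + 50L,
    gene_id = gene_id, is_background = is_background,
    stringsAsFactors = FALSE)
  promstate:::new_norm_track(probes, values, cell, modification, mode)
}

# long mark-call table from explicit per-mark logical vectors
make_calls <- function(gene_id, k4, ac, k27, cell = "MO") {
  do.call(rbind, list(
    data.frame(gene_id = gene_id, cell_type = cell,
               modification = "H3K4me3", marked = k4, score = NA_real_),
    data.frame(gene_id = gene_id, cell_type = cell,
               modification = "AcH3", marked = ac, score = NA_real_),
    data.frame(gene_id = gene_id, cell_type = cell,
               modification = "H3K27me3", marked = k27,
               score = NA_real_)))
}

# all permutations of a vector (exhaustive oracle machinery; small n only)
all_perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  do.call(rbind, lapply(seq_along(v), function(i)
    cbind(v[i], all_perms(v[-i]), deparse.level = 0)))
}

# exhaustive two-sided hypergeometric p by enumerating every placement of
# m marked genes among N = 2n ranked genes; observed statistic is the
# number of marked genes in the top n
enum_enrichment_p <- function(n, m, k_obs) {
  N <- 2L * n
  combos <- utils::combn(N, max(m, 1L))
  if (m == 0L) combos <- matrix(integer(0), nrow = 0, ncol = 1)
  ks <- if (m == 0L) 0L else apply(combos, 2, function(s) sum(s <= n))
  p_obs <- stats::dhyper(k_obs, n, n, m)
  mean(stats::dhyper(ks, n, n, m) <= p_obs * (1 + 1e-7))
}
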