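test_that("no signal yields no peaks and inputs are validated", {
  tr <- make_track(rep(0, 50), gene_id = rep(c("g1", "g2"), each = 25))
  expect_equal(nrow(call_peaks(tr, seed = 1)), 0L)
  expect_error(call_peaks(tr, min_probes = 1), "min_probes")
  expect_error(call_peaks(tr, n_permutations = 10), "n_permutations")
  # every tile shorter than the window: empty result, not an error
  short <- make_track(rep(1, 3), gene_id = rep("g1", 3))
  expect_equal(nrow(call_peaks(short, seed = 1)), 0L)
})

test_that("an isolated clean run of enriched probes becomes one exact peak", {
  v <- rep(0, 30); v[11:16] <- 3.0
  tr <- make_track(v, gene_id = rep("g1", 30))
  pk <- call_peaks(tr, seed = 5)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$n_probes, 6L)
  expect_equal(pk$score, 3.0)
  expect_equal(pk$start, tr$start[11])
  expect_equal(pk$end, tr$end[16])
})

test_that("permutation machinery is seeded and shift-monotone", {
  set.seed(3)
  v <- rnorm(75, 0, 0.5); v[20:27] <- v[20:27] + 2.5
  tr <- make_track(v, gene_id = rep(c("g1", "g2", "g3"), each = 25))
  pk1 <- call_peaks(tr, seed = 11)
  pk2 <- call_peaks(tr, seed = 11)
  expect_identical(pk1, pk2)

  up <- tr; up$value <- up$value + 10
  pk_up <- call_peaks(up, seed = 11)
  expect_equal(pk_up$score, pk1$score + 10)
  expect_identical(pk_up[c("chrom", "start", "end", "n_probes")],
                   pk1[c("chrom", "start", "end", "n_probes")])
})

test_that("the sampled permutation null matches exhaustive enumeration on a toy track", {
  v <- c(0, 1, 0, 2, 5, 1)
  tr <- make_track(v, gene_id = rep("g1", 6))
  tr <- tr[order(tr$chrom, tr$start), ]
  mp <- 4L
  ws <- promstate:::window_starts(tr, mp)
  expect_equal(ws, 1:3)
  # exact null: all 6! assignments of values to positions, all 3 windows
  pm <- all_perms(v)
  exact_scores <- c(apply(pm, 1, function(row)
    c(mean(row[1:4]), mean(row[2:5]), mean(row[3:6]))))
  thresholds <- c(1.0, 1.5, 2.0)
  exact_p <- vapply(thresholds, function(t) mean(exact_scores >= t),
                    numeric(1))
  B <- 4000L
  counts <- promstate:::null_exceedance_counts(tr, ws, mp, thresholds,
                                               B, seed = 9)
  sampled_p <- counts / (B * length(ws))
  # window scores within one permutation are dependent; bound the MC error
  # by the per-permutation spread (conservative 3-sigma envelope)
  for (k in seq_along(thresholds)) {
    se <- sqrt(exact_p[k] * (1 - exact_p[k]) / B) # >= se of the mean of 3
    expect_lt(abs(sampled_p[k] - exact_p[k]), 3 * se + 1e-9)
  }
})

test_that("planted promoter peaks are recovered with high sensitivity and low FDR", {
  p <- sim_params(n_genes = 300, seed = 5)
  sim <- simulate_dataset(p)
  norm <- background_normalize(sim$intensities, sim$probes)
  tr <- h3_normalize(norm, sim$probes, "MO", "H3K4me3")
  pk <- call_peaks(tr, seed = 5)
  truth <- sim$truth$peaks
  tp <- truth[truth$cell_type == "MO" & truth$modification == "H3K4me3", ]
  pk_gr <- promstate:::to_granges(pk$chrom, pk$start, pk$end)
  tp_gr <- promstate:::to_granges(tp$chrom, tp$start, tp$end)
  hits <- GenomicRanges::findOverlaps(pk_gr, tp_gr)
  sens <- length(unique(S4Vectors::subjectHits(hits))) / nrow(tp)
  fdr <- 1 - length(unique(S4Vectors::queryHits(hits))) / nrow(pk)
  expect_gte(sens, 0.85)
  expect_lte(fdr, 0.15)
})

test_that("per-gene delta scores localize planted gains and report uncallable genes", {
  tr <- make_track(rep(0, 50), gene_id = rep(c("g1", "g2"), each = 25),
                   mode = "delta")
  win <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                    start = c(0, 2500, 9000), end = c(2500, 5000, 11500))
  ds0 <- gene_delta_score(tr, win)
  expect_equal(ds0$score[1:2], c(0, 0))
  expect_true(is.na(ds0$score[3]))
  expect_false(ds0$callable[3])

  v <- rep(0, 50); v[5:10] <- 2       # a 6-probe lobe on g1
  tr2 <- make_track(v, gene_id = rep(c("g1", "g2"), each = 25),
                    mode = "delta")
  ds <- gene_delta_score(tr2, win)
  expect_equal(ds$score[ds$gene_id == "g1"], 2)
  expect_equal(ds$score[ds$gene_id == "g2"], 0)
  expect_error(gene_delta_score(make_track(1:5, gene_id = rep("g", 5)),
                                win), "delta-mode")
})

test_that("delta sign agreement with planted truth is high at default noise", {
  kern <- diag(8); dimnames(kern) <- list(state_levels(), state_levels())
  kern["none", ] <- 0; kern["none", "K4"] <- 1
  kern["K4+Ac", ] <- 0; kern["K4+Ac", "Ac"] <- 1
  pri <- setNames(c(0.5, 0, 0, 0, 0.5, 0, 0, 0), state_levels())
  p <- small_params(n_genes = 200, n_chroms = 2, state_priors = pri,
                    transition_kernel = kern, seed = 31)
  sim <- simulate_dataset(p)
  norm <- background_normalize(sim$intensities, sim$probes)
  delta <- differentiation_delta(
    h3_normalize(norm, sim$probes, "DC", "H3K4me3"),
    h3_normalize(norm, sim$probes, "MO", "H3K4me3"))
  ds <- gene_delta_score(delta, sim$windows)
  st <- sim$truth$states
  mo <- st$state[st$cell_type == "MO"][match(ds$gene_id,
          st$gene_id[st$cell_type == "MO"])]
  truth_sign <- ifelse(mo == "none", 1, -1)  # none->K4 gain, K4+Ac->Ac loss
  expect_gte(mean(sign(ds$score) == truth_sign), 0.95)
})
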