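test_that("simulate_genome is seeded, valid at the boundary, and keeps promoter windows disjoint", {
  one <- simulate_genome(1, 1, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_gte(one$tss, 2000L)

  expect_identical(simulate_genome(50, 3, seed = 7),
                   simulate_genome(50, 3, seed = 7))
  expect_false(identical(simulate_genome(50, 3, seed = 7),
                         simulate_genome(50, 3, seed = 8)))

  ann <- simulate_genome(2000, 5, seed = 3)
  win <- promoter_windows(ann)
  # brute-force pairwise interval scan per chromosome
  for (ch in unique(win$chrom)) {
    w <- win[win$chrom == ch, ]
    w <- w[order(w$start), ]
    expect_true(all(w$start[-1] >= w$end[-nrow(w)]))
  }
  expect_error(simulate_genome(0, 1), "positive")
})

test_that("plant_states honours priors, kernels, and degenerate settings", {
  ann <- simulate_genome(200, 2, seed = 1)
  ident <- diag(8)
  dimnames(ident) <- list(state_levels(), state_levels())
  p_id <- small_params(n_genes = 200, transition_kernel = ident)
  tr <- plant_states(ann, p_id)
  wide <- split(tr$states$state, tr$states$cell_type)
  expect_identical(wide$MO, wide$MF)
  expect_identical(wide$MO, wide$DC)

  pri <- setNames(c(1, rep(0, 7)), state_levels())
  p_none <- small_params(n_genes = 200, state_priors = pri,
                         transition_kernel = ident)
  tr2 <- plant_states(ann, p_none)
  expect_true(all(tr2$states$state == "none"))
  expect_null(tr2$peaks)

  bad <- default_transition_kernel(); bad[1, 1] <- 0.5
  expect_error(plant_states(ann, local({
    p <- small_params(); p$transition_kernel <- bad; p
  })), "sum to 1")

  # marginal recovery at 3 binomial sigmas
  ann_big <- simulate_genome(20000, 5, seed = 11)
  pr <- default_state_priors()
  tr3 <- plant_states(ann_big, sim_params(n_genes = 20000, seed = 11))
  mo <- tr3$states$state[tr3$states$cell_type == "MO"]
  for (target in c("K4+Ac", "none", "K27")) {
    p0 <- pr[[target]]
    se <- sqrt(p0 * (1 - p0) / 20000)
    expect_lt(abs(mean(mo == target) - p0), 3 * se)
  }
})

test_that("intensity model is exact without noise and calibrated with it", {
  p0 <- small_params(n_genes = 30, noise_sd = 0, seed = 5)
  sim <- simulate_dataset(p0)
  st <- sim$truth$states
  mo_state <- setNames(st$state[st$cell_type == "MO"],
                       st$gene_id[st$cell_type == "MO"])

  unmarked <- names(mo_state)[mo_state == "none"]
  idx <- sim$probes$gene_id %in% unmarked
  expect_equal(sim$intensities[["MO:H3K4me3"]][idx],
               sim$intensities[["MO:H3"]][idx])

  k4g <- names(mo_state)[grepl("K4", mo_state)]
  expect_gt(length(k4g), 0)
  ann <- sim$annotation
  pr <- sim$probes[sim$probes$gene_id %in% k4g & !sim$probes$is_background, ]
  tssv <- ann$tss[match(pr$gene_id, ann$gene_id)]
  rel <- ifelse(ann$strand[match(pr$gene_id, ann$gene_id)] == "+",
                (pr$start + pr$end) / 2 - tssv,
                tssv - (pr$start + pr$end) / 2)
  lobe <- (rel >= -800 & rel < -200) | (rel >= 100 & rel < 400)
  i <- match(pr$probe_id, sim$intensities$probe_id)
  ratio <- log2(sim$intensities[["MO:H3K4me3"]][i]) -
    log2(sim$intensities[["MO:H3"]][i])
  expect_equal(unique(ratio[lobe]), 2.0)

  # with default noise the lobe mean stays near peak_height
  p1 <- small_params(n_genes = 500, n_chroms = 3, seed = 9)
  sim1 <- simulate_dataset(p1)
  st1 <- sim1$truth$states
  k4g1 <- st1$gene_id[st1$cell_type == "MO" & grepl("K4", st1$state)]
  pr1 <- sim1$probes[sim1$probes$gene_id %in% k4g1 &
                       !sim1$probes$is_background, ]
  ann1 <- sim1$annotation
  tss1 <- ann1$tss[match(pr1$gene_id, ann1$gene_id)]
  rel1 <- ifelse(ann1$strand[match(pr1$gene_id, ann1$gene_id)] == "+",
                 (pr1$start + pr1$end) / 2 - tss1,
                 tss1 - (pr1$start + pr1$end) / 2)
  lobe1 <- (rel1 >= -800 & rel1 < -200) | (rel1 >= 100 & rel1 < 400)
  j <- match(pr1$probe_id[lobe1], sim1$intensities$probe_id)
  m <- mean(log2(sim1$intensities[["MO:H3K4me3"]][j]) -
              log2(sim1$intensities[["MO:H3"]][j]))
  expect_lt(abs(m - p1$peak_height), 0.1)
})

test_that("expression replicates follow the planted state means and couple to K4", {
  p0 <- small_params(n_genes = 40, expr_noise_sd = 0, seed = 3)
  sim <- simulate_dataset(p0)
  em <- sim$truth$expr_mean
  mo_mean <- em$mean_log2[em$cell_type == "MO"][
    match(sim$expression$gene_id, em$gene_id[em$cell_type == "MO"])]
  for (r in 1:3)
    expect_equal(sim$expression[[paste0("MO:", r)]], 2^mo_mean)

  p1 <- sim_params(n_genes = 2000, seed = 13)
  ann <- simulate_genome(2000, 5, seed = 13)
  truth <- plant_states(ann, p1)
  expr <- simulate_expression(truth, p1)
  st <- truth$states
  k4 <- grepl("K4", st$state[st$cell_type == "MO"])
  mo_expr <- rowMeans(expr[, paste0("MO:", 1:3)])
  # rank-based two-group comparison as the independent coupling oracle
  wt <- wilcox.test(mo_expr[k4], mo_expr[!k4], alternative = "greater")
  expect_lt(wt$p.value, 1e-6)
})

test_that("all simulator stages are bit-reproducible for a fixed seed", {
  a <- simulate_dataset(small_params(n_genes = 25, seed = 77))
  b <- simulate_dataset(small_params(n_genes = 25, seed = 77))
  for (part in c("annotation", "probes", "intensities", "expression"))
    expect_identical(a[[part]], b[[part]])
  expect_identical(a$truth$states, b$truth$states)
})

test_that("sim_params validates its invariants", {
  expect_error(sim_params(n_replicates = 1), "n_replicates")
  expect_error(sim_params(noise_sd = -1), "noise")
  pri <- default_state_priors(); pri[1] <- pri[1] + 0.2
  expect_error(sim_params(state_priors = pri), "sum to 1")
})
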