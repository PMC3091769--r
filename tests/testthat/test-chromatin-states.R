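test_that("3-bit mark patterns map bijectively onto the 8 states", {
  grid <- expand.grid(k4 = c(FALSE, TRUE), ac = c(FALSE, TRUE),
                      k27 = c(FALSE, TRUE))
  calls <- make_calls(sprintf("g%d", 1:8), grid$k4, grid$ac, grid$k27)
  st <- classify_states(calls)
  expect_setequal(st$state, state_levels())
  expect_equal(st$state[st$gene_id ==
    sprintf("g%d", which(grid$k4 & grid$ac & !grid$k27))], "K4+Ac")
  expect_equal(st$state[st$gene_id ==
    sprintf("g%d", which(!grid$k4 & !grid$ac & !grid$k27))], "none")

  # split -> classify is the identity on states
  back <- classify_states(split_states(st))
  m <- match(st$gene_id, back$gene_id)
  expect_equal(back$state[m], st$state)

  incomplete <- calls[calls$modification != "AcH3" | calls$gene_id != "g3", ]
  expect_error(classify_states(incomplete), "missing modification.*g3")
})

test_that("state frequencies are percentages that conserve over subsets", {
  st <- data.frame(gene_id = sprintf("g%d", 1:4), cell_type = "MO",
                   state = "K4+Ac")
  f <- state_frequencies(st)
  expect_equal(f$pct[f$state == "K4+Ac"], 100)
  expect_equal(sum(f$pct), 100)
  f1 <- state_frequencies(st, gene_subset = "g2")
  expect_equal(f1$pct[f1$state == "K4+Ac"], 100)
  expect_error(state_frequencies(st, gene_subset = character()), "empty")

  # uniform synthetic states: each near 12.5% at 3 binomial sigmas
  set.seed(1)
  n <- 4000
  stu <- data.frame(gene_id = sprintf("g%d", 1:n), cell_type = "MO",
                    state = sample(state_levels(), n, replace = TRUE))
  fu <- state_frequencies(stu)
  se <- 100 * sqrt(0.125 * 0.875 / n)
  expect_true(all(abs(fu$pct - 12.5) < 3 * se))

  # disjoint subsets recombine to the universe by weighted average
  sub1 <- sprintf("g%d", 1:1500); sub2 <- sprintf("g%d", 1501:n)
  fa <- state_frequencies(stu, sub1); fb <- state_frequencies(stu, sub2)
  recomb <- (1500 * fa$pct + 2500 * fb$pct) / n
  expect_equal(recomb, fu$pct, tolerance = 1e-12)
})

test_that("mark correlations hit the exact identities and planted structure", {
  v <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  calls <- rbind(
    make_calls(sprintf("g%d", 1:5), v, v, !v),
    make_calls(sprintf("g%d", 1:5), v, v, !v, cell = "MF"))
  cm <- mark_correlation(calls)
  expect_equal(unname(diag(cm)), rep(1, 6))
  expect_equal(cm["MO:H3K4me3", "MO:AcH3"], 1)
  expect_equal(cm["MO:H3K4me3", "MO:H3K27me3"], -1)
  expect_equal(cm["MO:H3K4me3", "MF:H3K4me3"], 1)
  expect_true(isSymmetric(cm))

  zv <- make_calls(sprintf("g%d", 1:5), v, rep(TRUE, 5), !v)
  expect_warning(cmz <- mark_correlation(zv), "zero-variance")
  expect_true(all(is.na(cmz["MO:AcH3", ])))

  # planted K4/Ac co-occurrence dominates K4/K27 in every cell type
  p <- sim_params(n_genes = 2000, seed = 19)
  truth <- plant_states(simulate_genome(2000, 5, seed = 19), p)
  tc <- split_states(truth$states)
  cmt <- mark_correlation(tc)
  for (cell in c("MO", "MF", "DC")) {
    expect_gt(cmt[paste0(cell, ":H3K4me3"), paste0(cell, ":AcH3")],
              cmt[paste0(cell, ":H3K4me3"), paste0(cell, ":H3K27me3")])
  }
})

test_that("enrichment p-values equal exhaustive enumeration on all small instances", {
  for (n in 2:5) {
    N <- 2L * n
    genes <- sprintf("g%02d", 1:N)
    expr <- data.frame(gene_id = genes, check.names = FALSE)
    expr[["MO:1"]] <- rev(seq_len(N)) + 0  # g01 highest
    expr[["MO:2"]] <- expr[["MO:1"]]
    for (m in 0:N) {
      k_feasible <- max(0L, m - n):min(n, m)
      for (k in k_feasible) {
        marked <- c(rep(TRUE, k), rep(FALSE, n - k),
                    rep(TRUE, m - k), rep(FALSE, n - (m - k)))
        calls <- make_calls(genes, marked, marked, marked)
        res <- expression_enrichment(calls, expr, "MO", "H3K4me3", n = n)
        expect_equal(res$p_value, enum_enrichment_p(n, m, k),
                     tolerance = 1e-10,
                     info = sprintf("n=%d m=%d k=%d", n, m, k))
        expect_equal(res$result$n_marked, c(k, m - k))
      }
    }
  }
})

test_that("equal mark frequency in both sets gives p = 1", {
  genes <- sprintf("g%02d", 1:8)
  expr <- data.frame(gene_id = genes, `MO:1` = 8:1, `MO:2` = 8:1,
                     check.names = FALSE)
  marked <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  res <- expression_enrichment(make_calls(genes, marked, marked, marked),
                               expr, "MO", "H3K4me3", n = 4)
  expect_equal(res$p_value, 1)
  expect_error(expression_enrichment(make_calls(genes, marked, marked,
                                                marked),
                                     expr, "MO", "H3K4me3", n = 5),
               "2n")
})

test_that("planted K4-expression coupling is detected strongly", {
  p <- sim_params(n_genes = 4000, seed = 23)
  truth <- plant_states(simulate_genome(4000, 5, seed = 23), p)
  expr <- simulate_expression(truth, p)
  calls <- split_states(truth$states)
  res <- expression_enrichment(calls, expr, "MO", "H3K4me3", n = 400)
  top <- res$result$frequency[res$result$set == "top-400"]
  bottom <- res$result$frequency[res$result$set == "bottom-400"]
  expect_gt(top, bottom)
  expect_lt(res$p_value, 1e-10)
})
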