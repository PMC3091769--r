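#' Default chromatin-state prior for the first cell type
#'
#' Probabilities over the eight combinatorial states chosen so that the
#' single-mark marginals approximate genome-wide promoter frequencies in
#' monocytes (H3K4me3 ~44\%, AcH3 ~31\%, H3K27me3 ~24\%, no mark ~36\%,
#' H3K4me3+AcH3 double mark ~26\%). These defaults emulate published
#' magnitudes; they are not fitted to any dataset.
#'
#' @return Named numeric vector over [state_levels()], summing to 1.
#' @export
default_state_priors <- function() {
  c(none        = 0.360,
    K4          = 0.115,
    Ac          = 0.025,
    K27         = 0.160,
    `K4+Ac`     = 0.260,
    `K4+K27`    = 0.055,
    `Ac+K27`    = 0.015,
    `K4+Ac+K27` = 0.010)
}

#' Default state-transition kernel for one differentiation step
#'
#' Row-stochastic 8x8 matrix over [state_levels()] describing how promoter
#' states move from the progenitor cell type to a derived cell type. The
#' defaults encode the qualitative dynamics of monocyte differentiation:
#' the H3K4me3+AcH3 double mark is persistent, H3K4me3 or AcH3 alone are
#' unstable (mostly lost or converted to the double mark), and H3K27me3
#' alone is stable.
#'
#' @return 8x8 row-stochastic matrix with state labels on both dimensions.
#' @export
default_transition_kernel <- function() {
  k <- matrix(0, 8, 8, dimnames = list(STATE_LEVELS, STATE_LEVELS))
  k["none", ]        <- c(0.86, 0.04, 0.03, 0.03, 0.03, 0.00, 0.00, 0.01)
  k["K4", ]          <- c(0.45, 0.20, 0.05, 0.00, 0.30, 0.00, 0.00, 0.00)
  k["Ac", ]          <- c(0.60, 0.10, 0.15, 0.00, 0.15, 0.00, 0.00, 0.00)
  k["K27", ]         <- c(0.08, 0.00, 0.00, 0.85, 0.00, 0.05, 0.02, 0.00)
  k["K4+Ac", ]       <- c(0.10, 0.08, 0.05, 0.00, 0.75, 0.00, 0.00, 0.02)
  k["K4+K27", ]      <- c(0.10, 0.10, 0.00, 0.25, 0.05, 0.50, 0.00, 0.00)
  k["Ac+K27", ]      <- c(0.20, 0.00, 0.10, 0.30, 0.00, 0.00, 0.40, 0.00)
  k["K4+Ac+K27", ]   <- c(0.10, 0.00, 0.00, 0.10, 0.25, 0.15, 0.00, 0.40)
  stopifnot(all(abs(rowSums(k) - 1) < 1e-12))
  k
}

#' Default mean log2 expression per chromatin state
#'
#' Ordering encodes the expected coupling between promoter state and
#' transcription: double-marked (K4+Ac) promoters are most expressed,
#' single active marks intermediate, bivalent (K4+K27) low, unmarked lower,
#' and H3K27me3-only lowest.
#'
#' @return Named numeric vector of log2 means over [state_levels()].
#' @export
default_expr_state_means <- function() {
  c(none        = 6.0,
    K4          = 8.5,
    Ac          = 8.5,
    K27         = 4.5,
    `K4+Ac`     = 10.0,
    `K4+K27`    = 7.0,
    `Ac+K27`    = 6.5,
    `K4+Ac+K27` = 7.5)
}

#' Simulation parameters for the synthetic tiling-array study
#'
#' Bundles every knob of the synthetic-data generator that emulates a
#' promoter tiling-array ChIP study with matched expression arrays: three
#' cell types (monocyte MO, macrophage MF, dendritic cell DC by default),
#' four antibody channels (H3, H3K4me3, AcH3, H3K27me3), ~2.5 kb promoter
#' tiles of 50-mer probes at 100 bp spacing, planted 8-way chromatin states
#' with a differentiation transition kernel, and expression coupled to state.
#'
#' Active marks (H3K4me3, AcH3) are planted as two enrichment lobes flanking
#' the TSS (`lobe_up`, `lobe_down`, TSS-relative bp) with a fractional dip
#' at the TSS itself; H3K27me3 enrichment is uniform over the promoter
#' window. Signal is lognormal around a geometric-mean baseline of 1000
#' with Gaussian noise on the log2 scale.
#'
#' @param n_genes Number of genes to simulate.
#' @param n_chroms Number of chromosomes.
#' @param cell_types Ordered character vector of cell-type labels; the first
#'   is the progenitor from which the others are derived.
#' @param state_priors Probability vector over [state_levels()] for the
#'   first cell type.
#' @param transition_kernel 8x8 row-stochastic matrix applied from the first
#'   cell type to each derived cell type.
#' @param peak_height Log2 enrichment of a marked promoter over baseline.
#' @param tss_dip_depth Fractional reduction of active-mark enrichment at
#'   the TSS (0 = no dip, 1 = full dip to baseline).
#' @param noise_sd Gaussian noise standard deviation on the log2 scale,
#'   applied independently per probe and channel.
#' @param probe_spacing,probe_length Tiling geometry in bp.
#' @param n_background_probes Number of random genomic (background) probes.
#' @param lobe_up,lobe_down TSS-relative half-open intervals (bp) of the two
#'   active-mark enrichment lobes.
#' @param expr_state_means Named log2 expression mean per state.
#' @param expr_noise_sd Log2-scale sd of expression replicates.
#' @param n_replicates Expression replicates per cell type (>= 2).
#' @param baseline_log2 Log2 of the lognormal baseline geometric mean.
#' @param seed Integer seed driving all random draws.
#'
#' @return Object of class `sim_params` (a validated list).
#' @export
#' @examples
#' p <- sim_params(n_genes = 50, seed = 1)
#' p$peak_height
sim_params <- function(n_genes = 2000,
                       n_chroms = 5,
                       cell_types = c("MO", "MF", "DC"),
                       state_priors = default_state_priors(),
                       transition_kernel = default_transition_kernel(),
                       peak_height = 2.0,
                       tss_dip_depth = 0.5,
                       noise_sd = 0.5,
                       probe_spacing = 100L,
                       probe_length = 50L,
                       n_background_probes = 500L,
                       lobe_up = c(-800L, -200L),
                       lobe_down = c(100L, 400L),
                       expr_state_means = default_expr_state_means(),
                       expr_noise_sd = 0.5,
                       n_replicates = 3L,
                       baseline_log2 = log2(1000),
                       seed = 1L) {
  if (n_genes < 1 || n_chroms < 1)
    stop_input("n_genes and n_chroms must be positive")
  if (length(cell_types) < 1 || anyDuplicated(cell_types))
    stop_input("cell_types must be a non-empty set of unique labels")
  if (length(state_priors) != 8 ||
      !setequal(names(state_priors), STATE_LEVELS))
    stop_input("state_priors must be named over the 8 state levels")
  state_priors <- state_priors[STATE_LEVELS]
  if (any(state_priors < 0) || abs(sum(state_priors) - 1) > 1e-8)
    stop_input("state_priors must be nonnegative and sum to 1")
  check_kernel(transition_kernel)
  if (noise_sd < 0 || expr_noise_sd < 0)
    stop_input("noise sds must be >= 0")
  if (n_replicates < 2)
    stop_input("n_replicates must be >= 2")
  if (!setequal(names(expr_state_means), STATE_LEVELS))
    stop_input("expr_state_means must be named over the 8 state levels")
  structure(list(
    n_genes = as.integer(n_genes), n_chroms = as.integer(n_chroms),
    cell_types = cell_types, state_priors = state_priors,
    transition_kernel = transition_kernel,
    peak_height = peak_height, tss_dip_depth = tss_dip_depth,
    noise_sd = noise_sd,
    probe_spacing = as.integer(probe_spacing),
    probe_length = as.integer(probe_length),
    n_background_probes = as.integer(n_background_probes),
    lobe_up = as.integer(lobe_up), lobe_down = as.integer(lobe_down),
    expr_state_means = expr_state_means[STATE_LEVELS],
    expr_noise_sd = expr_noise_sd,
    n_replicates = as.integer(n_replicates),
    baseline_log2 = baseline_log2,
    seed = as.integer(seed)),
    class = "sim_params")
}

check_kernel <- function(k) {
  if (!is.matrix(k) || !all(dim(k) == c(8, 8)))
    stop_input("transition_kernel must be an 8x8 matrix")
  if (is.null(rownames(k)) || !setequal(rownames(k), STATE_LEVELS) ||
      !setequal(colnames(k), STATE_LEVELS))
    stop_input("transition_kernel must have state labels on rows and columns")
  if (any(k < 0) || any(abs(rowSums(k) - 1) > 1e-8))
    stop_input("transition_kernel rows must be nonnegative and sum to 1")
  invisible(k[STATE_LEVELS, STATE_LEVELS])
}

#' Simulate a gene annotation with non-overlapping promoter windows
#'
#' Genes are laid out left to right on each chromosome with inter-TSS gaps
#' large enough that no two 2.5 kb promoter windows can overlap, and the
#' first 2.5 kb of every chromosome is kept gene-free as a reservoir for
#' background probes. Strand is drawn ~50/50.
#'
#' @param n_genes,n_chroms Positive counts.
#' @param seed Integer seed; the result is bit-reproducible for a fixed seed.
#' @return `data.frame` with columns gene_id, chrom, strand, tss
#'   (0-based position of the first transcribed base).
#' @export
simulate_genome <- function(n_genes, n_chroms, seed = 1L) {
  if (n_genes < 1 || n_chroms < 1)
    stop_input("n_genes and n_chroms must be positive")
  withr::with_seed(seed, {
    chrom <- paste0("chr", rep_len(seq_len(n_chroms), n_genes))
    chrom <- sort(chrom)  # contiguous blocks per chromosome
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    tss <- integer(n_genes)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      gaps <- 6000L + sample.int(1000L, length(idx), replace = TRUE)
      tss[idx] <- 5000L + cumsum(gaps) - gaps[1]
    }
  })
  data.frame(gene_id = sprintf("gene%05d", seq_len(n_genes)),
             chrom = chrom, strand = strand, tss = tss,
             stringsAsFactors = FALSE)
}

#' Tile promoter windows with probes and add background probes
#'
#' Non-background probes tile each promoter window at `probe_spacing` bp;
#' background ("random genomic") probes are placed in the gene-free head
#' region of random chromosomes.
#'
#' @param windows Promoter windows from [promoter_windows()].
#' @param params `sim_params` object (tiling geometry + background count).
#' @param seed Integer seed for background placement.
#' @return `data.frame`: probe_id, chrom, start, end (0-based half-open),
#'   gene_id (NA for background), is_background.
#' @export
simulate_probes <- function(windows, params, seed = params$seed + 1L) {
  sp <- params$probe_spacing; pl <- params$probe_length
  starts <- lapply(seq_len(nrow(windows)), function(i) {
    seq(windows$start[i], windows$end[i] - pl, by = sp)
  })
  n_per <- lengths(starts)
  prom <- data.frame(
    probe_id = sprintf("p%07d", seq_len(sum(n_per))),
    chrom = rep(windows$chrom, n_per),
    start = unlist(starts),
    gene_id = rep(windows$gene_id, n_per),
    is_background = FALSE,
    stringsAsFactors = FALSE)
  prom$end <- prom$start + pl
  nb <- params$n_background_probes
  if (nb > 0) {
    chroms <- unique(windows$chrom)
    withr::with_seed(seed, {
      bchrom <- sample(chroms, nb, replace = TRUE)
      bstart <- sample.int(2500L - pl, nb, replace = TRUE) - 1L
    })
    bg <- data.frame(
      probe_id = sprintf("bg%05d", seq_len(nb)),
      chrom = bchrom, start = bstart, gene_id = NA_character_,
      is_background = TRUE, stringsAsFactors = FALSE)
    bg$end <- bg$start + pl
    prom <- rbind(prom, bg)
  }
  ord <- order(prom$chrom, prom$start)
  rownames(prom) <- NULL
  prom[ord, c("probe_id", "chrom", "start", "end", "gene_id",
              "is_background")]
}

#' Plant per-gene chromatin states and derive the simulation ground truth
#'
#' States for the first cell type are drawn from `state_priors`; each later
#' cell type is drawn gene-wise from the first cell type's state through
#' `transition_kernel` (independent draws per derived cell type, matching a
#' progenitor-to-daughter study design). Planted peak intervals follow the
#' signal model: for active marks the union of the two lobes plus the TSS
#' dip region, for H3K27me3 the whole promoter window.
#'
#' @param annotation Gene annotation from [simulate_genome()].
#' @param params `sim_params`.
#' @param seed Integer seed.
#' @return Object of class `sim_truth`: list with `states` (gene_id,
#'   cell_type, state), `peaks` (planted enrichment intervals per gene,
#'   cell type and modification), and `expr_mean` (planted log2 expression
#'   mean per gene and cell type).
#' @export
plant_states <- function(annotation, params, seed = params$seed + 2L) {
  check_kernel(params$transition_kernel)
  n <- nrow(annotation)
  cells <- params$cell_types
  kern <- params$transition_kernel[STATE_LEVELS, STATE_LEVELS]
  withr::with_seed(seed, {
    s0 <- sample(STATE_LEVELS, n, replace = TRUE, prob = params$state_priors)
    states <- list(s0)
    if (length(cells) > 1) {
      for (j in 2:length(cells)) {
        states[[j]] <- vapply(s0, function(s) {
          sample(STATE_LEVELS, 1L, prob = kern[s, ])
        }, character(1), USE.NAMES = FALSE)
      }
    }
  })
  st <- data.frame(
    gene_id = rep(annotation$gene_id, length(cells)),
    cell_type = rep(cells, each = n),
    state = unlist(states),
    stringsAsFactors = FALSE)

  peaks <- truth_peaks(st, annotation, params)
  em <- params$expr_state_means[st$state]
  expr_mean <- data.frame(gene_id = st$gene_id, cell_type = st$cell_type,
                          mean_log2 = unname(em), stringsAsFactors = FALSE)
  structure(list(states = st, peaks = peaks, expr_mean = expr_mean),
            class = "sim_truth")
}

# genomic interval of the planted enrichment for each (gene, cell, mark)
truth_peaks <- function(states, annotation, params) {
  fl <- flags_from_state(states$state)
  ann <- annotation[match(states$gene_id, annotation$gene_id), ]
  rel_to_genomic <- function(a, b, tss, strand) {
    # rel half-open [a, b) -> genomic half-open, mirrored on minus strand
    start <- ifelse(strand == "+", tss + a, tss - b + 1L)
    end   <- ifelse(strand == "+", tss + b, tss - a + 1L)
    cbind(start, end)
  }
  out <- list()
  active_a <- params$lobe_up[1]; active_b <- params$lobe_down[2]
  for (mk in MOD_MARKS) {
    marked <- fl[[mark_token[[mk]]]]
    if (!any(marked)) next
    tss <- ann$tss[marked]; strand <- ann$strand[marked]
    if (mk == "H3K27me3") {
      iv <- rel_to_genomic(-2000L, 500L, tss, strand)
    } else {
      iv <- rel_to_genomic(active_a, active_b, tss, strand)
    }
    out[[mk]] <- data.frame(
      gene_id = states$gene_id[marked],
      cell_type = states$cell_type[marked],
      modification = mk,
      chrom = ann$chrom[marked],
      start = pmax(iv[, 1], 0L), end = iv[, 2],
      stringsAsFactors = FALSE)
  }
  pk <- do.call(rbind, out)
  rownames(pk) <- NULL
  pk
}

# TSS-relative coordinate of a position (strand-aware; upstream negative)
tss_relative <- function(pos, tss, strand) {
  ifelse(strand == "+", pos - tss, tss - pos)
}

#' Simulate probe intensities for all cell types and antibody channels
#'
#' The H3 channel is a lognormal baseline everywhere. For promoters planted
#' with an active mark (H3K4me3 or AcH3), that channel gains `peak_height`
#' log2 enrichment over two lobes flanking the TSS, reduced by
#' `tss_dip_depth` in the inter-lobe TSS region; H3K27me3 enrichment is
#' uniform across the window. Background probes carry baseline only.
#' Independent Gaussian noise (sd `noise_sd`) is added on the log2 scale to
#' every probe/channel, then values are returned on the linear scale.
#'
#' @param probes Probe table from [simulate_probes()].
#' @param truth `sim_truth` from [plant_states()].
#' @param annotation Gene annotation (for TSS/strand lookup).
#' @param params `sim_params`.
#' @param seed Integer seed.
#' @return `data.frame` with probe_id plus one positive linear-intensity
#'   column per "cell:antibody" channel.
#' @export
simulate_intensities <- function(probes, truth, annotation, params,
                                 seed = params$seed + 3L) {
  if (any(!probes$is_background & is.na(probes$gene_id)))
    stop_input("non-background probe without a promoter window")
  n <- nrow(probes)
  ann <- annotation[match(probes$gene_id, annotation$gene_id), ]
  mid <- (probes$start + probes$end) / 2
  rel <- tss_relative(mid, ann$tss, ann$strand)  # NA for background

  in_lobe <- !is.na(rel) &
    ((rel >= params$lobe_up[1] & rel < params$lobe_up[2]) |
     (rel >= params$lobe_down[1] & rel < params$lobe_down[2]))
  in_dip <- !is.na(rel) & rel >= params$lobe_up[2] & rel < params$lobe_down[1]

  st <- truth$states
  state_of <- function(cell) {
    s <- st$state[st$cell_type == cell][match(probes$gene_id,
                                              st$gene_id[st$cell_type == cell])]
    s
  }
  cols <- list(probe_id = probes$probe_id)
  withr::with_seed(seed, {
    for (cell in params$cell_types) {
      s <- state_of(cell)
      fl <- flags_from_state(ifelse(is.na(s), "none", s))
      for (ab in ANTIBODIES) {
        enrich <- numeric(n)
        if (ab != "H3") {
          marked <- fl[[mark_token[[ab]]]] & !probes$is_background
          if (ab == "H3K27me3") {
            enrich[marked] <- params$peak_height
          } else {
            enrich[marked & in_lobe] <- params$peak_height
            enrich[marked & in_dip] <-
              params$peak_height * (1 - params$tss_dip_depth)
          }
        }
        noise <- if (params$noise_sd > 0) rnorm(n, 0, params$noise_sd) else 0
        cols[[channel_id(cell, ab)]] <-
          2^(params$baseline_log2 + enrich + noise)
      }
    }
  })
  out <- data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate replicate gene-expression values coupled to chromatin state
#'
#' Each replicate is lognormal around the planted per-state log2 mean:
#' value = 2^(mean + N(0, expr_noise_sd)). With zero noise every replicate
#' equals its state mean exactly (on the linear scale).
#'
#' @param truth `sim_truth`.
#' @param params `sim_params` (needs n_replicates >= 2).
#' @param seed Integer seed.
#' @return `data.frame` with gene_id plus one column per "cell:replicate".
#' @export
simulate_expression <- function(truth, params, seed = params$seed + 4L) {
  if (params$n_replicates < 2)
    stop_input("n_replicates must be >= 2")
  em <- truth$expr_mean
  genes <- unique(em$gene_id)
  cols <- list(gene_id = genes)
  withr::with_seed(seed, {
    for (cell in params$cell_types) {
      mu <- em$mean_log2[em$cell_type == cell][match(genes,
              em$gene_id[em$cell_type == cell])]
      if (anyNA(mu))
        stop_input("missing expression state mean for some genes in ", cell)
      for (r in seq_len(params$n_replicates)) {
        noise <- if (params$expr_noise_sd > 0)
          rnorm(length(genes), 0, params$expr_noise_sd) else 0
        cols[[paste(cell, r, sep = ":")]] <- 2^(mu + noise)
      }
    }
  })
  data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study with ground truth
#'
#' Convenience wrapper chaining [simulate_genome()], [promoter_windows()],
#' [simulate_probes()], [plant_states()], [simulate_intensities()] and
#' [simulate_expression()], all seeded from `params$seed`.
#'
#' @param params `sim_params`.
#' @return List: annotation, windows, probes, truth, intensities,
#'   expression, params.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_params(n_genes = 20, seed = 1))
#' names(sim)
simulate_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  annotation <- simulate_genome(params$n_genes, params$n_chroms, params$seed)
  windows <- promoter_windows(annotation)
  probes <- simulate_probes(windows, params)
  truth <- plant_states(annotation, params)
  intensities <- simulate_intensities(probes, truth, annotation, params)
  expression <- simulate_expression(truth, params)
  list(annotation = annotation, windows = windows, probes = probes,
       truth = truth, intensities = intensities, expression = expression,
       params = params)
}
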