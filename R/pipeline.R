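#' Run the full promoter chromatin-state pipeline
#'
#' Drives simulate (optional) -> background/H3 normalization -> peak
#' calling -> peak-to-promoter assignment -> state classification ->
#' state dynamics -> differentiation deltas -> expression normalization
#' and differential calls -> overlap accounting -> metaprofiles, writing
#' every product as TSV/BED under `outdir` together with a JSON manifest
#' (file checksums, parameters, seed, package version). Each stage logs to
#' stderr; a failing stage aborts with its name.
#'
#' The YAML/list config has either a `simulate` block (arguments to
#' [sim_params()]) or an `inputs` block naming annotation, probes,
#' intensities and expression files, plus optional `peaks`
#' (min_probes/fdr/n_permutations) and a top-level `seed`.
#'
#' @param config Path to a YAML file or an equivalent named list.
#' @param outdir Output directory (created; overrides `config$outdir`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_input("config must be a list or a YAML path")
  outdir <- outdir %||% config$outdir
  if (is.null(outdir)) stop_input("config must name an output directory")
  seed <- as.integer(config$seed %||% 1L)

  # ---- validate before any compute ----
  if (is.null(config$simulate) && is.null(config$inputs))
    stop_input("config needs a 'simulate' or an 'inputs' block")
  if (!is.null(config$inputs)) {
    need <- c("annotation", "probes", "intensities", "expression")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss))
      stop_input("config inputs missing: ", paste(miss, collapse = ", "))
    absent <- !file.exists(unlist(config$inputs[need]))
    if (any(absent))
      stop_input("input file(s) not found: ",
                 paste(unlist(config$inputs[need])[absent], collapse = ", "))
  }
  pk_cfg <- config$peaks %||% list()
  min_probes <- pk_cfg$min_probes %||% 4L
  pk_fdr <- pk_cfg$fdr %||% 0.05
  n_perm <- pk_cfg$n_permutations %||% 200L

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  register <- function(path) {
    files[[length(files) + 1L]] <<- path
    path
  }
  emit <- function(rel) {
    path <- file.path(outdir, rel)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    register(path)
  }
  stage <- function(name, expr) {
    message("[promstate] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$simulate)) {
    dat <- stage("simulate", {
      args <- config$simulate
      args$seed <- args$seed %||% seed
      sim <- simulate_dataset(do.call(sim_params, args))
      write_annotation(sim$annotation, emit("annotation.tsv"))
      write_probes(sim$probes, emit("probes.bed"))
      write_intensities(sim$intensities, emit("intensities.tsv"))
      write_expression(sim$expression, emit("expression.tsv"))
      write.table(sim$truth$states, emit("truth_states.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(annotation = sim$annotation, probes = sim$probes,
           intensities = sim$intensities, expression = sim$expression,
           cell_types = sim$params$cell_types)
    })
  } else {
    dat <- stage("load inputs", {
      annotation <- read_annotation(config$inputs$annotation)
      probes <- read_probes(config$inputs$probes,
                            promoter_windows(annotation))
      intens <- read_intensities(config$inputs$intensities)
      list(annotation = annotation, probes = probes,
           intensities = intens,
           expression = read_expression(config$inputs$expression),
           cell_types = config$cell_types %||%
             unique(sub(":.*$", "", setdiff(names(intens), "probe_id"))))
    })
  }
  annotation <- dat$annotation
  windows <- promoter_windows(annotation)
  cell_types <- dat$cell_types
  ref <- cell_types[1]

  norm <- stage("normalize",
                background_normalize(dat$intensities, dat$probes))
  tracks <- stage("h3 normalize", {
    tl <- list()
    for (cell in cell_types)
      for (mk in MOD_MARKS) {
        tr <- h3_normalize(norm, dat$probes, cell, mk)
        write_track(tr, emit(file.path("tracks",
                                       paste0(cell, "_", mk, ".tsv"))))
        register(file.path(outdir, "tracks",
                           paste0(cell, "_", mk, ".tsv.yaml")))
        tl[[channel_id(cell, mk)]] <- tr
      }
    tl
  })

  peaks <- stage("call peaks", {
    pl <- list(); i <- 0L
    for (id in names(tracks)) {
      i <- i + 1L
      pk <- call_peaks(tracks[[id]], min_probes = min_probes,
                       fdr = pk_fdr, n_permutations = n_perm,
                       seed = seed + 100L + i)
      write_peaks(pk, emit(file.path("peaks",
                                     paste0(sub(":", "_", id), ".bed"))))
      pl[[id]] <- pk
    }
    pl
  })

  calls <- stage("assign peaks", {
    mc <- do.call(rbind, lapply(names(peaks), function(id) {
      parts <- strsplit(id, ":", fixed = TRUE)[[1]]
      assign_peaks(peaks[[id]], windows, parts[1], parts[2])
    }))
    write.table(mc, emit("mark_calls.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    mc
  })

  states <- stage("classify states", {
    st <- classify_states(calls)
    write.table(st, emit("states.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(state_frequencies(st), emit("state_frequencies.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    st
  })

  stage("state dynamics", {
    for (cell in setdiff(cell_types, ref)) {
      tt <- transitions(states[states$cell_type == ref, ],
                        states[states$cell_type == cell, ])
      paths <- write_transitions(tt, emit(paste0("transitions_", ref,
                                                 "_to_", cell, ".tsv")))
      register(paths[2])
    }
  })

  stage("differentiation deltas", {
    for (cell in setdiff(cell_types, ref))
      for (mk in MOD_MARKS) {
        dt <- differentiation_delta(tracks[[channel_id(cell, mk)]],
                                    tracks[[channel_id(ref, mk)]])
        ds <- gene_delta_score(dt, windows, min_probes)
        write.table(ds, emit(file.path("delta",
                    paste0(cell, "_", mk, "_scores.tsv"))),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
  })

  stage("expression", {
    nexpr <- rank_invariant_normalize(dat$expression)
    write_expression(nexpr, emit("expression_normalized.tsv"))
    de <- list()
    for (cell in setdiff(cell_types, ref)) {
      de[[cell]] <- call_differential(nexpr, cell, ref)
      write.table(de[[cell]], emit(paste0("de_", cell, "_vs_", ref,
                                          ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (length(de) >= 2) {
      ov <- overlap_table(de[[1]], de[[2]])
      write.table(ov, emit("overlap_table.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  })

  stage("metaprofiles", {
    for (mk in MOD_MARKS) {
      mp <- metaprofile(tracks[[channel_id(ref, mk)]], annotation)
      write.table(mp, emit(file.path("metaprofiles",
                  paste0(ref, "_", mk, ".tsv"))),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })

  manifest <- stage("manifest", {
    fl <- unique(files[file.exists(files)])
    m <- list(
      package = "promstate",
      version = as.character(packageVersion("promstate")),
      seed = seed,
      parameters = list(min_probes = min_probes, fdr = pk_fdr,
                        n_permutations = n_perm,
                        cell_types = cell_types,
                        simulate = config$simulate),
      files = lapply(fl, function(f)
        list(path = f, md5 = unname(tools::md5sum(f)))))
    jsonlite::write_json(m, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    m
  })
  invisible(manifest)
}
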