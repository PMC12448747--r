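# Pipeline orchestration: a structured run configuration, schema validation
# before any computation, deterministic per-stage seeding, and a manifest of
# inputs, parameters and output checksums.

# allowed parameter names per stage type (schema; unknown keys rejected)
.stage_schema <- list(
  simulate_screen = c("n_genes", "guides_per_gene", "n_control_guides",
                      "frac_true_hits", "effect_size_sd_units",
                      "cells_per_guide", "sort_fraction", "reads_per_bin",
                      "recombination_rate"),
  score_screen = c("counts", "high", "low", "min_count", "alpha", "n_perm",
                   "screen_id"),
  simulate_meta = c("n_screens", "n_genes", "shared_hit_count",
                    "screen_specific_hit_count", "shared_effect",
                    "specific_effect", "screen_se"),
  meta = c("screens", "q_threshold", "lfc_threshold", "lfc_screens",
           "standardize", "p_floor"),
  silac = c("peptides", "min_intensity", "ratio_min", "ratio_max",
            "group_a", "group_b", "lfc_cut", "p_cut"),
  rnaseq = c("counts", "samples", "pedestal", "loess_iterations",
             "lfc_cut", "p_cut"),
  splice = c("psi", "samples", "dpsi_cut", "presence_low", "presence_high",
             "detection_floor"),
  polya = c("events", "cfc_cut", "fdr_cut"))

#' Validate a pipeline run configuration
#'
#' A run configuration is a list (or YAML file) with a `seed`, an `out_dir`,
#' and a named `stages` list; each stage has a `type` (`simulate_screen`,
#' `score_screen`, `simulate_meta`, `meta`, `silac`, `rnaseq`, `splice` or
#' `polya`) and a `params` block whose keys are schema-checked. Schema
#' violations and missing input files are reported before any computation
#' starts.
#'
#' @param config A list or path to a YAML file.
#' @return The validated config list, invisibly on error-free input.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed_top <- c("seed", "out_dir", "stages")
  extra <- setdiff(names(config), allowed_top)
  if (length(extra) > 0)
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (is.null(config$seed)) config$seed <- 1L
  stopifnot_scalar_number(config$seed, "seed")
  if (is.null(config$out_dir)) stop("`out_dir` is required", call. = FALSE)
  config$stages <- config$stages %||% list()
  for (nm in names(config$stages)) {
    st <- config$stages[[nm]]
    if (is.null(st$type) || !st$type %in% names(.stage_schema))
      stop(sprintf("stage `%s`: unknown or missing type", nm), call. = FALSE)
    bad <- setdiff(names(st$params %||% list()), .stage_schema[[st$type]])
    if (length(bad) > 0)
      stop(sprintf("stage `%s` (%s): unknown parameters: %s", nm, st$type,
                   paste(bad, collapse = ", ")), call. = FALSE)
    for (p in c("counts", "samples", "peptides", "psi", "events")) {
      v <- st$params[[p]]
      if (is.character(v) && !startsWith(v, "@") && !file.exists(v))
        stop(sprintf("stage `%s`: input file not found: %s", nm, v),
             call. = FALSE)
    }
  }
  invisible(config)
}

# one global seed fans out to per-stage child seeds: stage i gets
# (seed * 31 + i) mod (2^31 - 1), keeping every derived seed a valid
# 32-bit integer and stages decoupled
stage_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 31 + index) %% (2^31 - 1))
}

resolve_input <- function(x, registry, what) {
  if (is.character(x) && length(x) == 1L && startsWith(x, "@")) {
    key <- substring(x, 2L)
    val <- registry[[key]]
    if (is.null(val)) stop("no upstream output named ", key, call. = FALSE)
    return(val)
  }
  if (is.character(x)) return(read_tsv_strict(x))
  x
}

#' Run a configured pipeline
#'
#' Validates the configuration, then executes the selected stages in listed
#' order with deterministic per-stage seeds derived from the global seed.
#' Stage parameters referencing `"@stage.output"` consume an earlier stage's
#' in-memory output; plain strings are read as TSV files. Writes every
#' stage's tables under `out_dir/<stage>/` and a `manifest.json` recording
#' parameters, seeds and md5 checksums of all outputs; identical
#' config + inputs reproduce identical outputs.
#'
#' @param config A list or YAML path accepted by [validate_run_config()].
#' @param seed Optional override of the config's global seed.
#' @return A list with `status` (0 on success) and `manifest`.
#' @export
run_pipeline <- function(config, seed = NULL) {
  config <- validate_run_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  registry <- list()
  manifest <- list(seed = config$seed, stages = list())

  emit <- function(stage_dir, tables) {
    dir.create(stage_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    for (nm in names(tables)) {
      x <- tables[[nm]]
      if (is.matrix(x)) x <- data.frame(id = rownames(x), x,
                                        check.names = FALSE)
      p <- file.path(stage_dir, paste0(nm, ".tsv"))
      write_tsv(x, p)
      paths[nm] <- p
    }
    paths
  }

  for (i in seq_along(config$stages)) {
    nm <- names(config$stages)[i]
    st <- config$stages[[nm]]
    prm <- st$params %||% list()
    sseed <- stage_seed(config$seed, i)
    tables <- switch(st$type,
      simulate_screen = {
        cfg <- do.call(screen_sim_config, c(prm, list(seed = sseed)))
        sim <- simulate_sorting_screen(cfg)
        sim[c("counts", "library", "truth")]
      },
      score_screen = {
        counts <- resolve_input(prm$counts, registry, "counts")
        res <- score_screen(counts, high = prm$high %||% "high",
                            low = prm$low %||% "low",
                            min_count = prm$min_count %||% 10,
                            alpha = prm$alpha %||% 0.25,
                            n_perm = prm$n_perm %||% 1000L, seed = sseed,
                            screen_id = prm$screen_id %||% nm)
        res[c("guide_stats", "gene_neg", "gene_pos", "summary")]
      },
      simulate_meta = {
        cfg <- do.call(meta_sim_config, c(prm, list(seed = sseed)))
        sim <- simulate_screen_summaries(cfg)
        out <- sim$summaries
        names(out) <- paste0("summary_", seq_along(out))
        c(out, list(truth = sim$truth))
      },
      meta = {
        screens <- lapply(prm$screens, resolve_input, registry, "screens")
        names(screens) <- names(prm$screens) %||%
          paste0("screen", seq_along(screens))
        combos <- meta_all_combinations(
          screens, standardize = prm$standardize %||% TRUE,
          p_floor = prm$p_floor %||% 1e-300)
        full <- combos[[length(combos)]]
        full <- classify_novelty(full, screens,
                                 q_threshold = prm$q_threshold %||% 0.05,
                                 lfc_threshold = prm$lfc_threshold %||% 1,
                                 lfc_screens = prm$lfc_screens %||%
                                   character(0))
        combos[[length(combos)]] <- full
        setNames(combos, gsub("\\+", "_", names(combos)))
      },
      silac = {
        pep <- resolve_input(prm$peptides, registry, "peptides")
        filt <- filter_peptides(pep,
                                min_intensity = prm$min_intensity %||% 1000,
                                ratio_bounds = c(prm$ratio_min %||% 0.01,
                                                 prm$ratio_max %||% 100))
        turn <- protein_half_life(filt$kept)
        out <- list(protein_halflife = turn,
                    rejection_tally = data.frame(reason = names(filt$tally),
                                                 n = as.integer(filt$tally)))
        if (!is.null(prm$group_a) && !is.null(prm$group_b))
          out$halflife_contrast <- contrast_half_life(
            turn, prm$group_a, prm$group_b,
            lfc_cut = prm$lfc_cut %||% 0.5, p_cut = prm$p_cut %||% 0.05)
        out
      },
      rnaseq = {
        counts <- resolve_input(prm$counts, registry, "counts")
        samples <- resolve_input(prm$samples, registry, "samples")
        m <- as.matrix(counts[, -1, drop = FALSE])
        rownames(m) <- counts[[1L]]
        groups <- samples$group[match(colnames(m), samples$sample)]
        norm <- cyclic_loess_normalize(
          cpm_pedestal_log2(m, prm$pedestal %||% 2),
          iterations = prm$loess_iterations %||% 3L)
        nf <- noise_filter(norm, groups, pedestal = prm$pedestal %||% 2)
        de <- differential_expression(norm[nf$kept, , drop = FALSE], groups,
                                      lfc_cut = prm$lfc_cut %||% 1,
                                      p_cut = prm$p_cut %||% 0.05)
        list(kept_genes = data.frame(gene = rownames(m), kept = nf$kept),
             noise_thresholds = data.frame(group = names(nf$thresholds),
                                           threshold = nf$thresholds),
             de = de)
      },
      splice = {
        psi <- resolve_input(prm$psi, registry, "psi")
        samples <- resolve_input(prm$samples, registry, "samples")
        scol <- setdiff(names(psi), c("junction_id", "gene"))
        groups <- samples$group[match(scol, samples$sample)]
        list(junction_classes = classify_junctions(
          psi, groups, dpsi_cut = prm$dpsi_cut %||% 0.10,
          presence_low = prm$presence_low %||% 0.05,
          presence_high = prm$presence_high %||% 0.10,
          detection_floor = prm$detection_floor %||% 0.01))
      },
      polya = {
        events <- resolve_input(prm$events, registry, "events")
        list(polya_classes = filter_polya_events(
          events, cfc_cut = prm$cfc_cut %||% 0.25,
          fdr_cut = prm$fdr_cut %||% 0.05))
      })

    for (tn in names(tables)) registry[[paste0(nm, ".", tn)]] <- tables[[tn]]
    paths <- emit(file.path(config$out_dir, nm), tables)
    manifest$stages[[nm]] <- list(
      type = st$type, seed = sseed, params = prm,
      outputs = as.list(setNames(unname(tools::md5sum(paths)),
                                 basename(paths))))
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(status = 0L, manifest = manifest)
}
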