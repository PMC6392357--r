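# One-command orchestration of the full analysis on synthetic (or
# pre-simulated) inputs.

#' Pipeline configuration
#'
#' Bundles generator parameters and stage settings; every source of
#' randomness derives from the single `seed` by fixed offsets.
#'
#' @param params a [community_params()] object (regenerated with
#'   `seed` as its `rng_seed`).
#' @param seed root seed for the run.
#' @param otu_threshold OTU divergence threshold.
#' @param linkage clustering linkage.
#' @param min_identity diet identification identity floor.
#' @param radius near/far neighbour radius (m).
#' @param n_draws randomized subwebs for the null envelope.
#' @param n_restarts modularity restarts.
#' @param evenness_denominator passed to [interaction_evenness()].
#' @param level taxonomic level for webs and overlap.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(params = community_params(), seed = 1,
                            otu_threshold = 0.02, linkage = "average",
                            min_identity = 0.95, radius = 2,
                            n_draws = 1000, n_restarts = 5,
                            evenness_denominator = "cells",
                            level = "species") {
  params$rng_seed <- as.integer(seed)
  structure(list(params = params, seed = as.integer(seed),
                 otu_threshold = otu_threshold, linkage = linkage,
                 min_identity = min_identity, radius = radius,
                 n_draws = n_draws, n_restarts = n_restarts,
                 evenness_denominator = evenness_denominator,
                 level = level),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Simulates (or accepts) a dataset, delimits insect OTUs from COI,
#' identifies diets from gut markers, builds the observation and
#' molecular webs, computes node/link overlap, classifies and summarizes
#' diet mismatch, fits the detection model, computes the metric set on
#' both webs and the randomized-subweb null envelope, and optionally
#' writes the full report bundle.
#'
#' @param config a [pipeline_config()].
#' @param sim optional pre-built [simulate_dataset()] result (otherwise
#'   simulated from `config$params`).
#' @param outdir optional output directory for the report bundle.
#' @return List of class `pipeline_result` with all stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config(), sim = NULL,
                         outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  if (is.null(sim)) sim <- stage("simulate", simulate_dataset(config$params))

  # insect OTU delimitation from larval COI
  otus <- stage("otu", {
    dm <- p_distance_matrix(sim$seqs$coi)
    cluster_otus(dm, threshold = config$otu_threshold,
                 linkage = config$linkage)
  })
  larvae <- sim$larvae
  larvae$insect <- unname(otus[larvae$larva_id])

  resolved <- stage("diet", {
    resolve_diets(larvae, sim$seqs$gut, sim$seqs$ref, sim$reflib,
                  min_identity = config$min_identity)
  })
  n_identified <- sum(vapply(resolved, function(r) length(r$call$items) > 0,
                             logical(1)))
  recovery <- diet_recovery(n_identified, nrow(larvae))
  res_summary <- stage("resolution", resolution_summary(resolved, sim$reflib))

  # webs restricted to the matched larvae (non-empty diet call)
  matched <- vapply(larvae$larva_id, function(id) {
    length(resolved[[id]]$call$items) > 0
  }, logical(1))
  obs <- stage("webs", build_observation_web(larvae[matched, ], sim$reflib,
                                             level = config$level))
  mol <- stage("webs", build_molecular_web(larvae[matched, ], resolved,
                                           sim$reflib, level = config$level))
  overlap <- stage("overlap", overlap_tables(obs, mol, sim$reflib))

  classified <- stage("mismatch", {
    cl <- classify_diets(larvae, resolved, sim$reflib, sim$stems,
                         radius = config$radius)
    idx <- match(cl$larva_id, larvae$larva_id)
    cl$insect <- larvae$insect[idx]
    cl$host <- larvae$collection_taxon[idx]
    cl$body_size_mm <- larvae$body_size_mm[idx]
    cl
  })
  mismatch_summary <- stage("mismatch", summarize_mismatch(classified))
  accuracy <- stage("mismatch", accuracy_by_level(larvae, resolved, sim$reflib))

  fit <- stage("detect", {
    recs <- occurrence_counts(classified)
    if (length(unique(recs$y)) < 2) NULL else fit_logistic(recs)
  })

  metrics_obs <- stage("metrics", metric_set(
    obs, seed = derive_seed(config$seed, 31L), n_restarts = config$n_restarts,
    evenness_denominator = config$evenness_denominator))
  metrics_mol <- stage("metrics", metric_set(
    mol, seed = derive_seed(config$seed, 37L), n_restarts = config$n_restarts,
    evenness_denominator = config$evenness_denominator))

  envelope <- if (nrow(obs) <= nrow(mol) && ncol(obs) <= ncol(mol) &&
                  config$n_draws > 0) {
    # a very sparse molecular web may admit no induced subweb of the
    # observation web's exact size without empty rows/columns; report
    # that rather than aborting the run
    tryCatch(
      null_envelope(obs, mol, n_draws = config$n_draws,
                    seed = derive_seed(config$seed, 41L),
                    n_restarts = config$n_restarts),
      error = function(e) {
        warning(sprintf("null envelope skipped: %s", conditionMessage(e)))
        NULL
      }
    )
  } else NULL

  result <- structure(list(
    config = config, sim = sim, otus = otus, resolved = resolved,
    recovery_pct = recovery, resolution_summary = res_summary,
    obs_web = obs, mol_web = mol, overlap = overlap,
    classified = classified, mismatch_summary = mismatch_summary,
    accuracy = accuracy, fit = fit,
    metrics_obs = metrics_obs, metrics_mol = metrics_mol,
    envelope = envelope
  ), class = "pipeline_result")

  if (!is.null(outdir)) write_report(result, outdir)
  result
}

#' Write the pipeline report bundle
#'
#' @param result a [run_pipeline()] result.
#' @param outdir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  add <- function(p) files <<- c(files, p)

  otu_df <- data.frame(seq_id = names(result$otus),
                       otu_id = unname(result$otus))
  p <- file.path(outdir, "otus.tsv")
  utils::write.table(otu_df, p, sep = "\t", row.names = FALSE, quote = FALSE)
  add(p)

  add(write_diet_calls(result$resolved, file.path(outdir, "diet_calls.tsv")))
  p <- file.path(outdir, "resolution_summary.tsv")
  utils::write.table(result$resolution_summary, p, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  add(p)
  add(write_web(result$obs_web, file.path(outdir, "observation_web.csv")))
  add(write_web(result$mol_web, file.path(outdir, "molecular_web.csv")))
  p <- file.path(outdir, "overlap_table.tsv")
  utils::write.table(result$overlap, p, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  add(p)
  add(write_mismatch_summary(result$mismatch_summary,
                             file.path(outdir, "mismatch_summary.tsv")))
  p <- file.path(outdir, "metrics.json")
  jsonlite::write_json(list(observation = as.list(result$metrics_obs),
                            molecular = as.list(result$metrics_mol)),
                       p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  add(p)
  if (!is.null(result$envelope)) {
    add(write_envelope(result$envelope, file.path(outdir, "envelope.json")))
  }
  if (!is.null(result$fit)) {
    add(write_fit(result$fit, file.path(outdir, "fit.json")))
  }
  p <- file.path(outdir, "run_log.txt")
  writeLines(c(
    sprintf("barcoweb %s", as.character(utils::packageVersion("barcoweb"))),
    sprintf("R %s", getRversion()),
    sprintf("seed %d", result$config$seed),
    sprintf("larvae %d, identified %.1f%%", nrow(result$sim$larvae),
            result$recovery_pct),
    sprintf("observation web %d x %d; molecular web %d x %d",
            nrow(result$obs_web), ncol(result$obs_web),
            nrow(result$mol_web), ncol(result$mol_web))
  ), p)
  add(p)
  invisible(files)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("barcoweb pipeline result\n")
  cat(sprintf("  larvae: %d (diet identified for %.1f%%)\n",
              nrow(x$sim$larvae), x$recovery_pct))
  cat(sprintf("  insect OTUs: %d\n", length(unique(x$otus))))
  cat(sprintf("  observation web: %d insects x %d plants\n",
              nrow(x$obs_web), ncol(x$obs_web)))
  cat(sprintf("  molecular web:  %d insects x %d plants\n",
              nrow(x$mol_web), ncol(x$mol_web)))
  cat("  mismatch percentages:\n")
  print(x$mismatch_summary$percentages)
  invisible(x)
}
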