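#' Pipeline run configuration
#'
#' Exactly one of `synthetic` (a [synthetic_config()] or preset name) or
#' `paths` (named list of input files) must be supplied. `paths` entries:
#' `compounds` (catalogue TSV), `panel` (panel TSV), `ppi` (vector of edge
#' files), `known` (vector of symbol-list files), `gene_sets` (GMT),
#' and `fingerprint_length`.
#'
#' @param synthetic synthetic configuration or preset name, or `NULL`.
#' @param paths named list of input paths, or `NULL`.
#' @param top_k herb-profile size (default 100).
#' @param kernel a `proximity_kernel`.
#' @param ease EASE penalization flag for enrichment.
#' @param universe optional explicit enrichment background; default: all PPI
#'   nodes.
#' @param druggable optional symbol vector restricting the putative target
#'   space; by default every ranked protein is putative.
#' @param out_dir output directory, or `NULL` to skip writing artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(synthetic = NULL, paths = NULL, top_k = 100,
                       kernel = gaussian_kernel(), ease = FALSE,
                       universe = NULL, druggable = NULL, out_dir = NULL) {
  if (is.null(synthetic) == is.null(paths)) {
    stop("supply exactly one of `synthetic` or `paths`")
  }
  stopifnot(top_k >= 1)
  if (is.character(synthetic)) synthetic <- synthetic_config(preset = synthetic)
  structure(list(synthetic = synthetic, paths = paths, top_k = top_k,
                 kernel = kernel, ease = ease, universe = universe,
                 druggable = druggable, out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from a YAML or JSON file
#'
#' Recognized keys mirror the [run_config()] arguments; `synthetic` may be a
#' preset name or a mapping of [synthetic_config()] fields.
#'
#' @param path config file (`.yaml`/`.yml`/`.json`).
#' @param out_dir optional override of the configured output directory.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  syn <- raw$synthetic
  if (!is.null(syn) && is.list(syn)) {
    syn <- do.call(synthetic_config, syn)
  }
  run_config(synthetic = syn, paths = raw$paths,
             top_k = raw$top_k %||% 100,
             ease = isTRUE(raw$ease), universe = raw$universe,
             out_dir = out_dir %||% raw$out_dir)
}

#' Run the whole inference chain
#'
#' Stages, in order: obtain inputs (synthetic bundle or files); score every
#' compound against every protein and build herb top-k profiles; take the
#' union of the profiles as the putative target set and compare it with the
#' known disease targets; build the putative-union-known target network;
#' screen hubs, major hubs and candidate targets; run pathway enrichment of
#' the candidates. All artifacts are written under `config$out_dir` when set
#' (`summary.json`, `topology.tsv`, `profiles/`, `screen.json`,
#' `enrichment.tsv`, `hub_network.graphml`, `run.log`, `config.json`, and
#' the synthetic inputs when generated). The run is fully deterministic
#' given the configuration, and `summary.json` does not depend on
#' `out_dir`.
#'
#' @param config a `run_config`.
#' @return a `pipeline_summary`, invisibly carrying the stage objects in
#'   attribute `"stages"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  run_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE)
      }),
      message = function(m) {
        log_lines <<- c(log_lines, paste0("[", stage, "] ",
                                          trimws(conditionMessage(m))))
        invokeRestart("muffleMessage")
      })
  }

  inputs <- run_stage("input", {
    if (!is.null(config$synthetic)) {
      generate_bundle(config$synthetic)
    } else {
      p <- config$paths
      fl <- p$fingerprint_length %||% stop("paths need fingerprint_length")
      list(network = load_ppi(p$ppi),
           panel = load_drug_panel(p$panel, fl),
           catalogue = load_compound_catalogue(p$compounds, fl),
           known_targets = load_known_targets(p$known),
           gene_sets = read_gmt(p$gene_sets),
           truth = NULL)
    }
  })

  pred <- run_stage("predict", {
    predictions <- predict_targets(inputs$catalogue, inputs$panel,
                                   inputs$network, config$kernel)
    profiles <- herb_profiles(predictions, config$top_k)
    ## the putative target space is the full ranked proteome, optionally
    ## restricted to a supplied druggable list
    putative <- sort(rownames(predictions$scores))
    if (!is.null(config$druggable)) {
      putative <- intersect(putative, normalize_symbols(config$druggable))
    }
    list(predictions = predictions, profiles = profiles, putative = putative,
         overlap = overlap_with_drug_targets(putative,
                                             inputs$known_targets$members),
         overlap_matrix = profile_overlap_matrix(profiles),
         common = common_targets(profiles))
  })

  target_net <- run_stage("build-net", {
    build_target_network(pred$putative, inputs$known_targets, inputs$network)
  })

  screen <- run_stage("screen", screen_targets(target_net, pred$putative))

  enr <- run_stage("enrich", {
    uni <- config$universe %||% igraph::V(inputs$network)$name
    enrich(screen$candidates, inputs$gene_sets, universe = uni,
           ease = config$ease)
  })

  per_herb <- as.list(attr(inputs$catalogue, "per_herb"))
  summary <- structure(list(
    per_herb_compounds = per_herb,
    total_compounds = attr(inputs$catalogue, "total"),
    top_k = config$top_k,
    n_putative = length(pred$putative),
    known_targets = length(inputs$known_targets$members),
    overlap_with_known = list(n = pred$overlap$n_shared,
                              percentage = pred$overlap$percentage),
    n_common_all_herbs = length(pred$common),
    target_network = list(nodes = igraph::vcount(target_net),
                          edges = igraph::ecount(target_net)),
    hub_threshold = screen$hub_threshold,
    n_hubs = length(screen$hubs),
    feature_medians = as.list(screen$feature_medians),
    n_major_hubs = length(screen$major_hubs),
    n_candidates = length(screen$candidates),
    top_enriched = top_enrichment(enr, 10),
    dropped_records = sort(log_lines)),
    class = "pipeline_summary")

  if (!is.null(config$out_dir)) {
    run_stage("write", write_artifacts(config, inputs, pred, target_net,
                                       screen, enr, summary, log_lines))
  }
  attr(summary, "stages") <- list(inputs = inputs, predictions = pred,
                                  target_network = target_net,
                                  screen = screen, enrichment = enr)
  invisible(summary)
}

write_artifacts <- function(config, inputs, pred, target_net, screen, enr,
                            summary, log_lines) {
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$synthetic)) {
    write_bundle(inputs, file.path(dir, "inputs"))
  }
  write_summary_json(summary, file.path(dir, "summary.json"))
  utils::write.table(topology(target_net), file.path(dir, "topology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prof_dir <- file.path(dir, "profiles")
  dir.create(prof_dir, showWarnings = FALSE)
  for (h in names(pred$profiles)) {
    utils::write.table(pred$profiles[[h]], file.path(prof_dir, paste0(h, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(pred$overlap_matrix, file.path(dir, "profile_overlaps.tsv"),
                     sep = "\t", quote = FALSE)
  writeLines(pred$putative, file.path(dir, "putative_targets.txt"))
  jsonlite::write_json(list(hub_threshold = screen$hub_threshold,
                            median_degree = screen$median_degree,
                            feature_medians = as.list(screen$feature_medians),
                            hubs = screen$hubs,
                            major_hubs = screen$major_hubs,
                            candidates = screen$candidates),
                       file.path(dir, "screen.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_enrichment_tsv(enr, file.path(dir, "enrichment.tsv"))
  write_graphml(screen$hub_network, file.path(dir, "hub_network.graphml"))
  cfg_echo <- list(top_k = config$top_k, ease = config$ease,
                   kernel = config$kernel$kind, out_dir = dir,
                   synthetic = if (!is.null(config$synthetic))
                     unclass(config$synthetic),
                   paths = config$paths)
  jsonlite::write_json(cfg_echo, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}

write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("Pipeline run summary\n")
  cat(sprintf("  compounds: %d total (%s)\n", x$total_compounds,
              paste(sprintf("%s: %d", names(x$per_herb_compounds),
                            unlist(x$per_herb_compounds)), collapse = ", ")))
  cat(sprintf("  putative target space (ranked proteome): %d\n",
              x$n_putative))
  cat(sprintf("  overlap with %d known disease targets: %d (%.2f%%)\n",
              x$known_targets, x$overlap_with_known$n,
              x$overlap_with_known$percentage))
  cat(sprintf("  common to all herbs: %d\n", x$n_common_all_herbs))
  cat(sprintf("  target network: %d nodes, %d edges\n",
              x$target_network$nodes, x$target_network$edges))
  cat(sprintf("  hubs: %d (degree > %.2f); major hubs: %d; candidates: %d\n",
              x$n_hubs, x$hub_threshold, x$n_major_hubs, x$n_candidates))
  fm <- x$feature_medians
  if (!is.null(fm$degree) && !is.na(fm$degree)) {
    cat(sprintf("  hub-network feature medians: degree %.2f, betweenness %.4f, closeness %.2f, K value %.2f\n",
                fm$degree, fm$betweenness, fm$closeness, fm$kcore))
  }
  if (nrow(x$top_enriched)) {
    cat(sprintf("  top enriched set: %s (%s), p_bonf = %.3g\n",
                x$top_enriched$set_id[1], x$top_enriched$set_name[1],
                x$top_enriched$p_bonferroni[1]))
  }
  invisible(x)
}

#' Fixture-checked run report
#'
#' Prints the run's headline counts next to the packaged-fixture counts
#' (distinct drug-overlap targets in the transcribed published table, the
#' OMIM symbol-list size, and the compound total), so any input bundle can
#' be eyeballed against the published scale.
#'
#' @param summary a `pipeline_summary`.
#' @return data.frame of the fixture checks, invisibly.
#' @export
pipeline_report <- function(summary) {
  t2 <- load_table2_fixture()
  omim <- load_omim_fixture()
  checks <- data.frame(
    check = c("distinct targets shared with known anti-RA drugs (fixture)",
              "OMIM-derived RA targets (fixture)",
              "compounds in this run",
              "putative targets in this run",
              "candidate targets in this run"),
    value = c(t2$distinct_targets, length(omim$members),
              summary$total_compounds, summary$n_putative,
              summary$n_candidates),
    stringsAsFactors = FALSE)
  print(summary)
  cat("\nFixture checks\n")
  for (i in seq_len(nrow(checks))) {
    cat(sprintf("  %s: %d\n", checks$check[i], checks$value[i]))
  }
  invisible(checks)
}
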