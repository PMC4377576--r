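#' Configuration for the synthetic-data generator
#'
#' Builds the fully-seeded configuration from which every synthetic input
#' (interaction network, reference drug panel, herb compound catalogues,
#' disease targets, gene sets) is a pure function. The generator plants
#' ground truth: each drug's targets form a network-localized module, each
#' herb compound is a noisy copy of one panel drug's fingerprint, and the
#' disease-target set overlaps the planted modules.
#'
#' The `"paper_scale"` preset mirrors the scale of a five-herb formula study:
#' 5 herbs with 22/122/39/65/203 compounds (451 total), 1746 proteins,
#' 208 disease targets. The `"toy"` preset is a seconds-fast miniature.
#'
#' @param seed integer root seed; per-stage substreams are derived from it so
#'   that, e.g., changing `n_gene_sets` does not perturb the network.
#' @param preset `NULL`, `"toy"` or `"paper_scale"`; explicit arguments
#'   override preset values.
#' @param n_proteins number of network nodes.
#' @param ppi_model `"scale-free"` (Barabasi-Albert) or `"block-model"` (SBM).
#' @param pa_edges edges added per node in the scale-free model.
#' @param sbm_blocks,sbm_p_in,sbm_p_out block-model parameters.
#' @param n_panel_drugs,targets_per_drug reference panel size and per-drug
#'   target count.
#' @param target_module_size size of each drug's planted target module.
#' @param module_radius maximum pairwise shortest-path distance inside a
#'   planted module (default 2: module = a seed node plus neighbours).
#' @param n_herbs,compounds_per_herb herb count and per-herb compound counts
#'   (scalar or vector recycled to `n_herbs`).
#' @param fingerprint_length,fingerprint_density binary fingerprint length and
#'   expected on-bit fraction for panel drugs.
#' @param bit_flip_rate per-bit flip probability turning a parent drug
#'   fingerprint into a compound fingerprint.
#' @param n_disease_targets,disease_module_overlap disease-target count and
#'   the fraction of it drawn from the planted drug-target modules.
#' @param n_gene_sets,gene_set_size_range gene-set collection size and the
#'   (min, max) size of the random sets; the first set is always the planted
#'   disease module, id `"PLANTED_DISEASE"`.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, preset = NULL,
                             n_proteins = NULL, ppi_model = NULL,
                             pa_edges = NULL, sbm_blocks = NULL,
                             sbm_p_in = NULL, sbm_p_out = NULL,
                             n_panel_drugs = NULL, targets_per_drug = NULL,
                             target_module_size = NULL, module_radius = NULL,
                             n_herbs = NULL, compounds_per_herb = NULL,
                             fingerprint_length = NULL,
                             fingerprint_density = NULL,
                             bit_flip_rate = NULL,
                             n_disease_targets = NULL,
                             disease_module_overlap = NULL,
                             n_gene_sets = NULL, gene_set_size_range = NULL) {
  base <- list(
    n_proteins = 200L, ppi_model = "scale-free", pa_edges = 3L,
    sbm_blocks = 4L, sbm_p_in = 0.2, sbm_p_out = 0.01,
    n_panel_drugs = 20L, targets_per_drug = 3L, target_module_size = 6L,
    module_radius = 2L, n_herbs = 3L, compounds_per_herb = 10L,
    fingerprint_length = 128L, fingerprint_density = 0.1,
    bit_flip_rate = 0.05, n_disease_targets = 30L,
    disease_module_overlap = 0.5, n_gene_sets = 20L,
    gene_set_size_range = c(10L, 40L))
  presets <- list(
    toy = list(n_proteins = 50L, pa_edges = 2L, n_panel_drugs = 8L,
               targets_per_drug = 2L, target_module_size = 4L, n_herbs = 2L,
               compounds_per_herb = 5L, fingerprint_length = 64L,
               n_disease_targets = 10L, n_gene_sets = 10L,
               gene_set_size_range = c(5L, 15L)),
    paper_scale = list(n_proteins = 1746L, ppi_model = "block-model",
                       sbm_blocks = 16L,
                       sbm_p_in = exp(seq(log(0.02), log(0.35), length.out = 16)),
                       sbm_p_out = 0.004,
                       n_panel_drugs = 100L, targets_per_drug = 3L,
                       target_module_size = 8L, n_herbs = 5L,
                       compounds_per_herb = c(22L, 122L, 39L, 65L, 203L),
                       fingerprint_length = 256L, n_disease_targets = 208L,
                       n_gene_sets = 50L, gene_set_size_range = c(10L, 100L)))
  cfg <- base
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(presets))
    cfg[names(presets[[preset]])] <- presets[[preset]]
  }
  user <- list(n_proteins = n_proteins, ppi_model = ppi_model,
               pa_edges = pa_edges, sbm_blocks = sbm_blocks,
               sbm_p_in = sbm_p_in, sbm_p_out = sbm_p_out,
               n_panel_drugs = n_panel_drugs,
               targets_per_drug = targets_per_drug,
               target_module_size = target_module_size,
               module_radius = module_radius, n_herbs = n_herbs,
               compounds_per_herb = compounds_per_herb,
               fingerprint_length = fingerprint_length,
               fingerprint_density = fingerprint_density,
               bit_flip_rate = bit_flip_rate,
               n_disease_targets = n_disease_targets,
               disease_module_overlap = disease_module_overlap,
               n_gene_sets = n_gene_sets,
               gene_set_size_range = gene_set_size_range)
  user <- user[!vapply(user, is.null, logical(1))]
  cfg[names(user)] <- user
  cfg$seed <- as.integer(seed)

  with(cfg, {
    stopifnot(n_proteins >= 2, n_panel_drugs >= 2, targets_per_drug >= 1,
              target_module_size >= 1, module_radius >= 1, n_herbs >= 1,
              all(compounds_per_herb >= 1), fingerprint_length >= 1,
              fingerprint_density > 0, fingerprint_density <= 1,
              bit_flip_rate >= 0, bit_flip_rate <= 1,
              n_disease_targets >= 1, n_disease_targets <= n_proteins,
              disease_module_overlap >= 0, disease_module_overlap <= 1,
              targets_per_drug <= target_module_size,
              n_gene_sets >= 1, length(gene_set_size_range) == 2,
              gene_set_size_range[1] >= 1,
              gene_set_size_range[2] >= gene_set_size_range[1])
  })
  if (cfg$ppi_model == "scale-free" && cfg$pa_edges < 1) {
    stop("scale-free model needs at least 1 attachment edge per node")
  }
  if (cfg$target_module_size > cfg$n_proteins) {
    stop("target_module_size exceeds n_proteins")
  }
  cfg$compounds_per_herb <- rep_len(as.integer(cfg$compounds_per_herb),
                                    cfg$n_herbs)
  structure(cfg, class = "synthetic_config")
}

## Per-stage substream: the root seed plus a fixed stage offset.
stage_seed <- function(config, stage) {
  offsets <- c(ppi = 101L, panel = 211L, herbs = 307L,
               disease = 401L, gene_sets = 503L)
  set.seed(config$seed + offsets[[stage]])
}

#' Generate the synthetic interaction network
#'
#' Scale-free graphs come from preferential attachment (connected by
#' construction); block-model graphs are stitched into one component by
#' bridging edges between components if needed. Nodes are named
#' `G0001, G0002, ...`; edges are tagged with source `"synthetic"`.
#'
#' @param config a [synthetic_config()].
#' @return igraph network with `config$n_proteins` nodes.
#' @export
generate_ppi <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  stage_seed(config, "ppi")
  n <- config$n_proteins
  if (config$ppi_model == "scale-free") {
    g <- igraph::sample_pa(n, m = config$pa_edges, directed = FALSE)
  } else {
    sizes <- rep(n %/% config$sbm_blocks, config$sbm_blocks)
    sizes[1] <- sizes[1] + n - sum(sizes)
    pm <- matrix(config$sbm_p_out, config$sbm_blocks, config$sbm_blocks)
    ## per-block within-density (recycled), emulating functional modules of
    ## heterogeneous density as found in merged interaction databases
    diag(pm) <- rep_len(config$sbm_p_in, config$sbm_blocks)
    g <- igraph::sample_sbm(n, pref.matrix = pm, block.sizes = sizes)
    comp <- igraph::components(g)
    if (comp$no > 1) {
      reps <- vapply(seq_len(comp$no),
                     function(k) which(comp$membership == k)[1], integer(1))
      g <- igraph::add_edges(g, as.vector(rbind(reps[-length(reps)], reps[-1])))
    }
  }
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("G%04d", seq_len(n))
  igraph::E(g)$sources <- "synthetic"
  if (igraph::components(g)$no != 1) stop("generated network is not connected")
  g
}

#' Generate the reference drug panel with planted target modules
#'
#' Each drug receives a random binary fingerprint and a target set sampled
#' from one planted module: a seed node plus `target_module_size - 1` of its
#' neighbours, so every pair of module members is within shortest-path
#' distance `module_radius` (default 2). The seed — a well-connected
#' protein — is always among the drug's targets, reflecting the tendency of
#' drug targets to be network-central; the remaining targets are sampled
#' from the module.
#'
#' @param config a [synthetic_config()].
#' @param network the network from [generate_ppi()].
#' @return list with `panel` (a `drug_panel`) and `truth`
#'   (`list(modules, seeds, drug_targets)`, the planted per-drug module node
#'   sets, module seed nodes and target sets).
#' @export
generate_panel <- function(config, network) {
  stopifnot(inherits(config, "synthetic_config"))
  stage_seed(config, "panel")
  if (config$target_module_size > igraph::vcount(network)) {
    stop("target_module_size exceeds the number of network nodes")
  }
  deg <- igraph::degree(network)
  ## drug targets concentrate on well-connected proteins: module seeds come
  ## from the top-decile-degree nodes, sampled with probability
  ## proportional to degree
  eligible <- names(deg)[deg >= max(config$target_module_size - 1,
                                    stats::quantile(deg, 0.90))]
  if (length(eligible) < config$n_panel_drugs) {
    eligible <- names(deg)[deg >= config$target_module_size - 1]
  }
  if (length(eligible) < config$n_panel_drugs) {
    stop(sprintf(paste0("only %d nodes have enough neighbours to seed a ",
                        "module of size %d; reduce n_panel_drugs or ",
                        "target_module_size"),
                 length(eligible), config$target_module_size))
  }
  seeds <- sample(eligible, config$n_panel_drugs, prob = deg[eligible])
  L <- config$fingerprint_length
  ids <- sprintf("D%03d", seq_len(config$n_panel_drugs))
  fps <- vector("list", config$n_panel_drugs)
  targets <- vector("list", config$n_panel_drugs)
  modules <- vector("list", config$n_panel_drugs)
  for (i in seq_along(ids)) {
    fps[[i]] <- as_fingerprint(which(stats::runif(L) < config$fingerprint_density) - 1L)
    nb <- igraph::neighbors(network, seeds[i])$name
    satellites <- sample(nb, config$target_module_size - 1)
    modules[[i]] <- sort(c(seeds[i], satellites))
    targets[[i]] <- sort(c(seeds[i],
                           sample(satellites, config$targets_per_drug - 1)))
  }
  names(modules) <- ids
  panel <- new_drug_panel(ids, fps, targets, "synthetic", L)
  list(panel = panel,
       truth = list(modules = modules,
                    seeds = stats::setNames(seeds, ids),
                    drug_targets = stats::setNames(targets, ids)))
}

#' Generate herb compound catalogues as noisy drug copies
#'
#' Every compound is assigned one parent panel drug; its fingerprint is the
#' parent's fingerprint with each of the `fingerprint_length` bit positions
#' independently flipped with probability `bit_flip_rate`.
#'
#' @param config a [synthetic_config()].
#' @param panel the `drug_panel` from [generate_panel()].
#' @return list with `catalogue` (a `compound_catalogue`) and `truth`
#'   (`list(parents = ...)`, named compound -> parent drug id map).
#' @export
generate_herbs <- function(config, panel) {
  stopifnot(inherits(config, "synthetic_config"))
  stage_seed(config, "herbs")
  L <- config$fingerprint_length
  herbs <- rep(sprintf("herb_%d", seq_len(config$n_herbs)),
               times = config$compounds_per_herb)
  n <- length(herbs)
  ids <- sprintf("C%04d", seq_len(n))
  parent_idx <- sample(nrow(panel), n, replace = TRUE)
  fps <- vector("list", n)
  for (i in seq_len(n)) {
    flips <- which(stats::runif(L) < config$bit_flip_rate) - 1L
    parent_fp <- panel$fingerprint[[parent_idx[i]]]
    ## XOR: flipped positions toggle membership
    fps[[i]] <- as_fingerprint(c(setdiff(parent_fp, flips),
                                 setdiff(flips, parent_fp)))
  }
  catalogue <- new_catalogue(
    data.frame(compound_id = ids, herb = herbs, name = ids,
               stringsAsFactors = FALSE), fps, L)
  parents <- stats::setNames(panel$drug_id[parent_idx], ids)
  list(catalogue = catalogue, truth = list(parents = parents))
}

#' Generate the synthetic disease-target set
#'
#' A fraction `disease_module_overlap` of the targets is drawn from the
#' planted drug-target modules (specifically from the union of the planted
#' target sets, mirroring disease-target lists compiled from drug-target
#' databases), the remainder uniformly from the other network nodes.
#'
#' @param config a [synthetic_config()].
#' @param network the synthetic network.
#' @param truth ground truth containing `drug_targets` (or `modules`) from
#'   [generate_panel()].
#' @return a `known_targets` object (sources `"planted"` / `"background"`).
#' @export
generate_disease_targets <- function(config, network, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  stage_seed(config, "disease")
  nodes <- igraph::V(network)$name
  module_union <- sort(unique(unlist(truth$drug_targets %||% truth$modules)))
  k_planted <- round(config$disease_module_overlap * config$n_disease_targets)
  if (k_planted > length(module_union)) {
    stop(sprintf("disease_module_overlap infeasible: need %d module genes, have %d",
                 k_planted, length(module_union)))
  }
  planted <- if (k_planted > 0) sort(sample(module_union, k_planted)) else character(0)
  pool <- setdiff(nodes, planted)
  n_rest <- config$n_disease_targets - k_planted
  background <- if (n_rest > 0) sort(sample(pool, n_rest)) else character(0)
  tags <- c(stats::setNames(rep(list("planted"), length(planted)), planted),
            stats::setNames(rep(list("background"), length(background)), background))
  members <- sort(c(planted, background))
  structure(list(disease = "synthetic", members = members,
                 source_tags = tags[members],
                 per_source = c(planted = length(planted),
                                background = length(background))),
            class = "known_targets")
}

#' Generate the synthetic gene-set collection
#'
#' The first set, id `"PLANTED_DISEASE"`, equals the disease module (the
#' disease-target member set) and serves as the positive control for
#' enrichment; the remaining sets are uniform random draws from the node set
#' with sizes in `gene_set_size_range`.
#'
#' @param config a [synthetic_config()].
#' @param network the synthetic network.
#' @param truth ground truth containing `disease_module`.
#' @return a `gene_set_collection` with universe = all network nodes.
#' @export
generate_gene_sets <- function(config, network, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  stage_seed(config, "gene_sets")
  nodes <- igraph::V(network)$name
  sets <- list(list(id = "PLANTED_DISEASE", name = "Planted disease module",
                    members = sort(truth$disease_module)))
  rng <- config$gene_set_size_range
  for (i in seq_len(config$n_gene_sets - 1)) {
    size <- sample(seq(rng[1], rng[2]), 1)
    sets[[i + 1]] <- list(id = sprintf("GS%03d", i),
                          name = sprintf("Random set %d", i),
                          members = sort(sample(nodes, min(size, length(nodes)))))
  }
  gene_set_collection(sets, universe = nodes)
}

#' Generate the full synthetic input bundle
#'
#' Runs all generator stages in order and returns every pipeline input plus
#' the planted ground truth. The bundle is a pure function of the
#' configuration: identical configs give bit-identical bundles.
#'
#' @param config a [synthetic_config()] (or a preset name).
#' @return list with `network`, `panel`, `catalogue`, `known_targets`,
#'   `gene_sets`, `truth` (`parents`, `modules`, `disease_module`) and
#'   `config`.
#' @export
generate_bundle <- function(config) {
  if (is.character(config)) config <- synthetic_config(preset = config)
  network <- generate_ppi(config)
  pn <- generate_panel(config, network)
  hb <- generate_herbs(config, pn$panel)
  truth <- c(pn$truth, hb$truth)
  known <- generate_disease_targets(config, network, truth)
  truth$disease_module <- known$members
  gene_sets <- generate_gene_sets(config, network, truth)
  list(network = network, panel = pn$panel, catalogue = hb$catalogue,
       known_targets = known, gene_sets = gene_sets, truth = truth,
       config = config)
}

#' Write a synthetic bundle to disk in the formats the loaders read
#'
#' @param bundle result of [generate_bundle()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_compound_catalogue(bundle$catalogue, file.path(dir, "compounds.tsv"))
  write_drug_panel(bundle$panel, file.path(dir, "panel.tsv"))
  write_edge_tsv(bundle$network, file.path(dir, "ppi.tsv"))
  writeLines(bundle$known_targets$members, file.path(dir, "known_targets.txt"))
  write_gmt(bundle$gene_sets, file.path(dir, "gene_sets.gmt"))
  jsonlite::write_json(
    list(parents = as.list(bundle$truth$parents),
         modules = bundle$truth$modules,
         disease_module = bundle$truth$disease_module),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
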