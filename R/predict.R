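#' Tanimoto similarity of two binary fingerprints
#'
#' Jaccard coefficient on on-bit index sets: `|a & b| / |a | b|`. Two empty
#' fingerprints have similarity 0 (with a warning), not NaN.
#'
#' @param fp_a,fp_b integer vectors of 0-based on-bit indices.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  u <- length(union(fp_a, fp_b))
  if (u == 0) {
    warning("both fingerprints are empty; Tanimoto set to 0")
    return(0)
  }
  length(intersect(fp_a, fp_b)) / u
}

#' Gaussian-of-distance proximity kernel
#'
#' The functional-similarity transform: a target at shortest-path distance
#' `d` contributes `exp(-d^2)`. Any strictly decreasing kernel with value 1
#' at distance 0 and value 0 at infinite distance is admissible; this
#' constructor validates those properties so alternatives stay pluggable.
#'
#' @param fn kernel function of distance; default `exp(-d^2)`.
#' @param kind label.
#' @return a `proximity_kernel`.
#' @export
gaussian_kernel <- function(fn = function(d) exp(-d^2),
                            kind = "gaussian-of-distance") {
  v <- fn(c(0:4, Inf))
  if (abs(v[1] - 1) > 1e-12) stop("kernel must equal 1 at distance 0")
  if (any(diff(v[1:5]) >= 0)) stop("kernel must be strictly decreasing")
  if (v[6] != 0) stop("kernel must vanish at infinite distance")
  structure(list(kind = kind, fn = fn), class = "proximity_kernel")
}

#' Chemical-similarity vector of a query against the drug space
#'
#' @param query a compound record (list with `fingerprint`) or a raw on-bit
#'   index vector.
#' @param panel a `drug_panel`.
#' @return named numeric vector, one Tanimoto value per panel drug, in panel
#'   order.
#' @export
chem_similarity_vector <- function(query, panel) {
  if (nrow(panel) == 0) stop("empty drug panel")
  fp <- if (is.list(query)) query$fingerprint else query
  stats::setNames(
    vapply(panel$fingerprint, function(d) tanimoto(fp, d), numeric(1)),
    panel$drug_id)
}

#' Network proximity of a protein to one drug's target set
#'
#' Sums the kernel over the drug's targets: targets in another component
#' contribute 0 (kernel at infinite distance), targets absent from the
#' network contribute 0 and are reported via a message.
#'
#' @param protein gene symbol (must be a network node).
#' @param drug one row of a `drug_panel` (list with `targets`) or a symbol
#'   vector.
#' @param network igraph network.
#' @param kernel a `proximity_kernel`.
#' @return non-negative proximity value.
#' @export
proximity <- function(protein, drug, network, kernel = gaussian_kernel()) {
  protein <- normalize_symbols(protein)
  if (!protein %in% igraph::V(network)$name) {
    stop("protein not in network: ", protein)
  }
  targets <- if (is.list(drug)) drug$targets[[1]] %||% drug$targets else drug
  targets <- normalize_symbols(targets)
  present <- intersect(targets, igraph::V(network)$name)
  if (length(present) < length(targets)) {
    message(sprintf("%d drug target(s) absent from the network contribute 0",
                    length(targets) - length(present)))
  }
  if (!length(present)) return(0)
  d <- igraph::distances(network, v = protein, to = present, weights = NA)
  sum(kernel$fn(as.numeric(d)))
}

#' Functional-similarity vector of a protein against the target space
#'
#' @param protein gene symbol.
#' @param panel a `drug_panel`.
#' @param network igraph network.
#' @param kernel a `proximity_kernel`.
#' @return named non-negative vector aligned to the same panel order as
#'   [chem_similarity_vector()].
#' @export
functional_similarity_vector <- function(protein, panel, network,
                                         kernel = gaussian_kernel()) {
  fm <- functional_similarity_matrix(panel, network, kernel)
  protein <- normalize_symbols(protein)
  if (!protein %in% rownames(fm)) stop("protein not in network: ", protein)
  fm[protein, ]
}

## nodes x drugs proximity matrix, shared across all compounds of a run.
functional_similarity_matrix <- function(panel, network,
                                         kernel = gaussian_kernel()) {
  nodes <- igraph::V(network)$name
  all_targets <- sort(unique(unlist(panel$targets)))
  present <- intersect(all_targets, nodes)
  if (length(present) < length(all_targets)) {
    message(sprintf("%d panel target symbol(s) absent from the network contribute 0",
                    length(all_targets) - length(present)))
  }
  fm <- matrix(0, nrow = length(nodes), ncol = nrow(panel),
               dimnames = list(nodes, panel$drug_id))
  if (length(present)) {
    d <- igraph::distances(network, v = present, weights = NA)
    kd <- kernel$fn(d)  # targets x nodes
    for (j in seq_len(nrow(panel))) {
      tg <- intersect(panel$targets[[j]], present)
      if (length(tg)) {
        fm[, j] <- colSums(kd[tg, nodes, drop = FALSE])
      }
    }
  }
  fm
}

#' Concordance score between chemical and functional similarity vectors
#'
#' Pearson correlation between the two panel-aligned vectors; the
#' drug-target interaction likelihood. If either vector is constant the
#' correlation is undefined and `NA` is returned (such proteins rank last).
#'
#' @param chem_vec,func_vec equal-length numeric vectors (length >= 2).
#' @return correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
concordance_score <- function(chem_vec, func_vec) {
  if (length(chem_vec) != length(func_vec)) stop("vector lengths differ")
  if (length(chem_vec) < 2) stop("correlation needs a panel of >= 2 drugs")
  if (stats::sd(chem_vec) == 0 || stats::sd(func_vec) == 0) return(NA_real_)
  stats::cor(chem_vec, func_vec)
}

#' Rank all network proteins as putative targets of one compound
#'
#' The drugCIPHER-CS-style ranking: every node gets the correlation between
#' the compound's chemical-similarity vector and the node's
#' functional-similarity vector; nodes are sorted by score descending with
#' ties (and undefined scores, which sort last) broken by symbol.
#'
#' @param compound list with `compound_id` and `fingerprint`, or a raw
#'   fingerprint.
#' @param panel a `drug_panel` (>= 2 drugs).
#' @param network igraph network.
#' @param kernel a `proximity_kernel`.
#' @return data.frame with `compound_id`, `protein`, `score`, `rank`;
#'   `score` is `NA` where undefined.
#' @export
rank_targets <- function(compound, panel, network,
                         kernel = gaussian_kernel()) {
  if (nrow(panel) < 2) stop("correlation needs a panel of >= 2 drugs")
  fp <- if (is.list(compound)) compound$fingerprint else compound
  if (is.list(fp)) fp <- fp[[1]]
  id <- if (is.list(compound)) compound$compound_id %||% "query" else "query"
  chem <- chem_similarity_vector(fp, panel)
  fm <- functional_similarity_matrix(panel, network, kernel)
  scores <- score_against_matrix(chem, fm)
  ord <- score_order(scores)
  data.frame(compound_id = id, protein = names(scores)[ord],
             score = unname(scores[ord]), rank = seq_along(scores),
             stringsAsFactors = FALSE)
}

## deterministic ordering contract: score desc, symbol asc, undefined last;
## scores are snapped to 10 decimals first so that analytically tied values
## are not separated by floating-point noise
score_order <- function(scores) {
  snapped <- round(scores, 10)
  order(is.na(snapped), -ifelse(is.na(snapped), 0, snapped), names(scores))
}

score_against_matrix <- function(chem, fm) {
  if (stats::sd(chem) == 0) {
    return(stats::setNames(rep(NA_real_, nrow(fm)), rownames(fm)))
  }
  s <- suppressWarnings(as.numeric(stats::cor(chem, t(fm))))
  stats::setNames(s, rownames(fm))
}

#' Score every compound of a catalogue against every network protein
#'
#' Shares the functional-similarity matrix across compounds, so a full
#' catalogue is scored in one pass.
#'
#' @param catalogue a `compound_catalogue`.
#' @param panel a `drug_panel` (>= 2 drugs).
#' @param network igraph network.
#' @param kernel a `proximity_kernel`.
#' @return a `target_predictions` object: list with `scores`
#'   (proteins x compounds matrix, `NA` = undefined), `compounds`
#'   (data.frame `compound_id`, `herb`).
#' @export
predict_targets <- function(catalogue, panel, network,
                            kernel = gaussian_kernel()) {
  if (nrow(panel) < 2) stop("correlation needs a panel of >= 2 drugs")
  fm <- functional_similarity_matrix(panel, network, kernel)
  chem <- vapply(catalogue$fingerprint,
                 function(fp) chem_similarity_vector(fp, panel),
                 numeric(nrow(panel)))  # drugs x compounds
  colnames(chem) <- catalogue$compound_id
  const_chem <- apply(chem, 2, stats::sd) == 0
  const_func <- apply(fm, 1, stats::sd) == 0
  scores <- suppressWarnings(stats::cor(t(fm), chem))  # proteins x compounds
  scores[const_func, ] <- NA_real_
  scores[, const_chem] <- NA_real_
  structure(list(scores = scores,
                 compounds = data.frame(compound_id = catalogue$compound_id,
                                        herb = catalogue$herb,
                                        stringsAsFactors = FALSE)),
            class = "target_predictions")
}

#' @export
print.target_predictions <- function(x, ...) {
  cat("Target predictions:", ncol(x$scores), "compounds x",
      nrow(x$scores), "proteins;",
      sum(is.na(x$scores)), "undefined score(s)\n")
  invisible(x)
}

#' Ranking of one compound from a prediction set
#'
#' @param predictions a `target_predictions` object.
#' @param compound_id compound to extract.
#' @return ranked data.frame as in [rank_targets()].
#' @export
compound_ranking <- function(predictions, compound_id) {
  if (!compound_id %in% colnames(predictions$scores)) {
    stop("unknown compound: ", compound_id)
  }
  s <- predictions$scores[, compound_id]
  ord <- score_order(s)
  data.frame(compound_id = compound_id, protein = names(s)[ord],
             score = unname(s[ord]), rank = seq_along(s),
             stringsAsFactors = FALSE)
}

#' Herb-level target profile
#'
#' Aggregates compound-level scores to one score per protein and herb (the
#' maximum over the herb's compounds — the most permissive rule; see the
#' methods vignette) and keeps the top `k` proteins by (score desc, symbol
#' asc). Proteins whose scores are undefined for every compound of the herb
#' sort last and only enter if fewer than `k` defined proteins exist.
#'
#' @param predictions a `target_predictions` object.
#' @param herb herb label.
#' @param k profile size (default 100).
#' @return a `herb_profile` data.frame with `protein`, `score`.
#' @export
herb_profile <- function(predictions, herb, k = 100) {
  idx <- predictions$compounds$herb == herb
  if (!any(idx)) stop("herb has no compounds: ", herb)
  s <- predictions$scores[, idx, drop = FALSE]
  agg <- apply(s, 1, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  ord <- score_order(agg)
  top <- utils::head(ord, k)
  structure(data.frame(protein = names(agg)[top], score = unname(agg[top]),
                       stringsAsFactors = FALSE),
            herb = herb, k = k, class = c("herb_profile", "data.frame"))
}

#' All herb profiles of a prediction set
#'
#' @param predictions a `target_predictions` object.
#' @param k profile size.
#' @return named list of `herb_profile`s (herb label order of appearance).
#' @export
herb_profiles <- function(predictions, k = 100) {
  herbs <- unique(predictions$compounds$herb)
  stats::setNames(lapply(herbs, function(h) herb_profile(predictions, h, k)),
                  herbs)
}

#' Pairwise overlap counts between herb profiles
#'
#' @param profiles named list of `herb_profile`s (>= 2).
#' @return symmetric herb x herb integer matrix; diagonal = profile sizes.
#' @export
profile_overlap_matrix <- function(profiles) {
  if (length(profiles) < 2) stop("need at least two profiles")
  n <- length(profiles)
  m <- matrix(0L, n, n, dimnames = list(names(profiles), names(profiles)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- length(intersect(profiles[[i]]$protein, profiles[[j]]$protein))
  }
  m
}

#' Targets common to every herb profile
#'
#' @param profiles named list of `herb_profile`s.
#' @return sorted symbol vector present in all profiles.
#' @export
common_targets <- function(profiles) {
  sort(Reduce(intersect, lapply(profiles, `[[`, "protein")))
}

#' Overlap of a putative-target set with a reference symbol set
#'
#' @param putative symbol set (e.g. union of herb profiles).
#' @param reference symbol set (e.g. known disease targets or drug targets).
#' @return list with `shared` (sorted symbols), `n_shared`, `n_putative` and
#'   `percentage` (100 x shared / putative, rounded to 2 decimals).
#' @export
overlap_with_drug_targets <- function(putative, reference) {
  putative <- unique(normalize_symbols(putative))
  reference <- unique(normalize_symbols(reference))
  shared <- sort(intersect(putative, reference))
  pct <- if (length(putative)) {
    round_half_up(100 * length(shared) / length(putative), 2)
  } else 0
  list(shared = shared, n_shared = length(shared),
       n_putative = length(putative), percentage = pct)
}
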