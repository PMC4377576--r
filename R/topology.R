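#' Build the target interaction network
#'
#' Induced subgraph of the merged PPI network on the union of putative and
#' known disease targets. Union members absent from the PPI data are kept as
#' isolated (degree-0) nodes, which can never become hubs but stay visible
#' in reports.
#'
#' @param putative symbol set of putative targets.
#' @param known a `known_targets` object or symbol vector.
#' @param ppi igraph PPI network.
#' @return igraph network.
#' @export
build_target_network <- function(putative, known, ppi) {
  known_members <- if (inherits(known, "known_targets")) known$members else known
  members <- unique(normalize_symbols(c(putative, known_members)))
  if (!length(members)) stop("empty putative/known target union")
  induce_network(ppi, members, keep_missing = TRUE)
}

#' Four topological features of every node
#'
#' For each node: degree; shortest-path betweenness normalized by
#' `(nc-1)(nc-2)/2` where `nc` is the node's component size (0 when
#' `nc < 3`); closeness as reachable-count-minus-one over farness (the sum
#' of distances to reachable nodes), scaled x100 for reporting, 0 for
#' isolated nodes; and the k-core index ("K value"), the largest k such that
#' the node survives recursive deletion of vertices of degree < k.
#'
#' @param network simple undirected igraph network.
#' @return data.frame with `node`, `degree`, `betweenness`, `closeness`,
#'   `kcore`, one row per node in sorted symbol order.
#' @export
topology <- function(network) {
  n <- igraph::vcount(network)
  if (n == 0) {
    return(data.frame(node = character(0), degree = integer(0),
                      betweenness = numeric(0), closeness = numeric(0),
                      kcore = integer(0), stringsAsFactors = FALSE))
  }
  nodes <- igraph::V(network)$name
  deg <- igraph::degree(network)
  comp <- igraph::components(network)
  csize <- comp$csize[comp$membership]
  btw_raw <- igraph::betweenness(network, weights = NA)
  pairs <- (csize - 1) * (csize - 2) / 2
  btw <- ifelse(pairs > 0, btw_raw / pairs, 0)
  d <- igraph::distances(network, weights = NA)
  farness <- apply(d, 1, function(r) sum(r[is.finite(r)]))
  reach <- csize - 1
  clo <- ifelse(farness > 0, 100 * reach / farness, 0)
  kc <- igraph::coreness(network)
  out <- data.frame(node = nodes, degree = as.integer(deg),
                    betweenness = as.numeric(btw),
                    closeness = as.numeric(clo), kcore = as.integer(kc),
                    stringsAsFactors = FALSE)
  out <- out[order(out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select hub nodes
#'
#' A node is a hub if its degree strictly exceeds twice the median degree of
#' all nodes in the network. In a regular graph nothing qualifies; degree-0
#' nodes never qualify.
#'
#' @param network igraph network (non-empty).
#' @return list with `hubs` (sorted symbols), `median_degree`, `threshold`.
#' @export
select_hubs <- function(network) {
  if (igraph::vcount(network) == 0) stop("empty network")
  deg <- igraph::degree(network)
  med <- stats::median(deg)
  thr <- 2 * med
  list(hubs = sort(names(deg)[deg > thr]), median_degree = med,
       threshold = thr)
}

#' Induced subgraph on the hub set
#'
#' @param network igraph network.
#' @param hubs symbol subset of the network's nodes.
#' @return igraph network of direct interactions among hubs.
#' @export
hub_subnetwork <- function(network, hubs) {
  stopifnot(all(hubs %in% igraph::V(network)$name))
  igraph::induced_subgraph(network, hubs)
}

#' Screen major hubs in the hub subnetwork
#'
#' Recomputes the four topological features on the hub subnetwork, takes the
#' median of each feature over the hubs, and keeps the hubs that strictly
#' exceed all four medians. Because the thresholds are medians of the same
#' quantities, the selection is invariant under any strictly increasing
#' rescaling of a feature.
#'
#' @param hub_net hub subnetwork (non-empty).
#' @return list with `feature_medians` (named: degree, betweenness,
#'   closeness, kcore), `major_hubs` (sorted symbols) and `topology` (the
#'   hub-network feature table).
#' @export
screen_major_hubs <- function(hub_net) {
  if (igraph::vcount(hub_net) == 0) stop("empty hub network")
  tp <- topology(hub_net)
  med <- c(degree = stats::median(tp$degree),
           betweenness = stats::median(tp$betweenness),
           closeness = stats::median(tp$closeness),
           kcore = stats::median(tp$kcore))
  keep <- tp$degree > med[["degree"]] &
    tp$betweenness > med[["betweenness"]] &
    tp$closeness > med[["closeness"]] &
    tp$kcore > med[["kcore"]]
  list(feature_medians = med, major_hubs = sort(tp$node[keep]),
       topology = tp)
}

#' Candidate targets: major hubs that are also putative targets
#'
#' @param major_hubs symbol set.
#' @param putative symbol set.
#' @return sorted intersection.
#' @export
candidate_targets <- function(major_hubs, putative) {
  sort(intersect(normalize_symbols(major_hubs), normalize_symbols(putative)))
}

#' Full topological screen: hubs, major hubs, candidates
#'
#' Runs [select_hubs()], [hub_subnetwork()], [screen_major_hubs()] and
#' [candidate_targets()] on a target network.
#'
#' @param network target interaction network.
#' @param putative putative-target symbol set.
#' @return a `screen_result`: list with `hub_threshold`, `median_degree`,
#'   `hubs`, `feature_medians`, `major_hubs`, `candidates`, `hub_network`,
#'   `hub_topology`.
#' @export
screen_targets <- function(network, putative) {
  hs <- select_hubs(network)
  if (!length(hs$hubs)) {
    res <- list(hub_threshold = hs$threshold, median_degree = hs$median_degree,
                hubs = character(0),
                feature_medians = c(degree = NA_real_, betweenness = NA_real_,
                                    closeness = NA_real_, kcore = NA_real_),
                major_hubs = character(0), candidates = character(0),
                hub_network = igraph::make_empty_graph(0, directed = FALSE),
                hub_topology = topology(igraph::make_empty_graph(0, directed = FALSE)))
    return(structure(res, class = "screen_result"))
  }
  hnet <- hub_subnetwork(network, hs$hubs)
  sc <- screen_major_hubs(hnet)
  structure(list(hub_threshold = hs$threshold,
                 median_degree = hs$median_degree, hubs = hs$hubs,
                 feature_medians = sc$feature_medians,
                 major_hubs = sc$major_hubs,
                 candidates = candidate_targets(sc$major_hubs, putative),
                 hub_network = hnet, hub_topology = sc$topology),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Topological screen\n")
  cat(sprintf("  hub rule: degree > %.2f (2 x median degree %.2f)\n",
              x$hub_threshold, x$median_degree))
  cat(sprintf("  hubs: %d\n", length(x$hubs)))
  if (length(x$hubs)) {
    m <- x$feature_medians
    cat(sprintf("  major-hub thresholds (hub-network medians): degree > %.2f, betweenness > %.4f, closeness > %.2f, K value > %.2f\n",
                m[["degree"]], m[["betweenness"]], m[["closeness"]], m[["kcore"]]))
  }
  cat(sprintf("  major hubs: %d\n  candidate targets: %d\n",
              length(x$major_hubs), length(x$candidates)))
  invisible(x)
}
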