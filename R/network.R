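#' Build an interaction network from an edge table
#'
#' Constructs the undirected simple protein-protein interaction graph used
#' throughout the pipeline. Symbols are case-normalized, self-loops are
#' dropped (with a message reporting how many), and duplicate edges are
#' merged into a single edge whose `sources` attribute is the sorted union of
#' the provenance labels of all merged copies (labels are stored
#' `"|"`-separated).
#'
#' @param edges data.frame with columns `from`, `to` and optionally `source`.
#' @param default_source provenance label used where `source` is absent.
#' @return an [igraph::igraph] object; vertices carry gene symbols in `name`,
#'   edges carry a `sources` attribute.
#' @export
interaction_network <- function(edges, default_source = "unknown") {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  from <- normalize_symbols(edges$from)
  to <- normalize_symbols(edges$to)
  if (any(!nzchar(from)) || any(!nzchar(to))) {
    stop("empty gene symbol in edge table")
  }
  src <- if ("source" %in% names(edges)) as.character(edges$source) else
    rep(default_source, length(from))
  src[is.na(src) | !nzchar(src)] <- default_source

  loops <- from == to
  if (any(loops)) {
    message(sprintf("dropped %d self-loop(s)", sum(loops)))
    from <- from[!loops]; to <- to[!loops]; src <- src[!loops]
  }
  ## canonical unordered key
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  merged <- split(src, key)
  keys <- sort(names(merged))
  pairs <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  sources <- vapply(merged[keys], function(s)
    paste(sort(unique(unlist(strsplit(s, "|", fixed = TRUE)))), collapse = "|"),
    character(1))
  if (is.null(pairs)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = pairs[, 1], to = pairs[, 2], sources = unname(sources),
                 stringsAsFactors = FALSE),
      directed = FALSE)
    ## deterministic vertex order
    g <- igraph::permute(g, match(igraph::V(g)$name, sort(igraph::V(g)$name)))
  }
  g
}

#' Load and merge protein-protein interaction files
#'
#' Reads one or more edge-list files and merges them into a single undirected
#' simple graph. Plain 2-3 column TSV (`from`, `to`[, `source`], no header) and
#' SIF (`A relation B`, whitespace-separated) are accepted; files ending in
#' `.sif` are parsed as SIF. Provenance defaults to the supplied label or the
#' file name; an edge present in several files appears once, tagged with the
#' union of its sources.
#'
#' @param paths character vector of file paths.
#' @param sources optional character vector of provenance labels, recycled
#'   against `paths`; defaults to the file base names.
#' @return an [igraph::igraph] as produced by [interaction_network()].
#' @export
load_ppi <- function(paths, sources = NULL) {
  stopifnot(length(paths) >= 1)
  if (is.null(sources)) sources <- basename(paths)
  sources <- rep_len(sources, length(paths))
  tabs <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    tabs[[i]] <- read_edge_file(paths[[i]], sources[[i]])
  }
  interaction_network(do.call(rbind, tabs))
}

read_edge_file <- function(path, source_label) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  sif <- grepl("\\.sif$", path, ignore.case = TRUE)
  out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    ln <- lines[idx[j]]
    fields <- strsplit(trimws(ln), if (sif) "[\t ]+" else "\t")[[1]]
    fields <- fields[nzchar(fields)]
    if (sif) {
      if (length(fields) != 3) {
        stop(sprintf("%s line %d: expected 'A relation B', got %d field(s)",
                     path, idx[j], length(fields)))
      }
      out[[j]] <- data.frame(from = fields[1], to = fields[3],
                             source = source_label, stringsAsFactors = FALSE)
    } else {
      if (length(fields) < 2 || length(fields) > 3) {
        stop(sprintf("%s line %d: expected 2-3 tab-separated fields, got %d",
                     path, idx[j], length(fields)))
      }
      out[[j]] <- data.frame(
        from = fields[1], to = fields[2],
        source = if (length(fields) == 3) fields[3] else source_label,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(from = character(0), to = character(0),
                      source = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Edge table of an interaction network
#'
#' @param network igraph network.
#' @return data.frame with columns `from`, `to`, `source`.
#' @export
network_edges <- function(network) {
  el <- igraph::as_edgelist(network)
  src <- if ("sources" %in% igraph::edge_attr_names(network))
    igraph::E(network)$sources else rep(NA_character_, nrow(el))
  if (!nrow(el)) {
    return(data.frame(from = character(0), to = character(0),
                      source = character(0), stringsAsFactors = FALSE))
  }
  data.frame(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2]),
             source = src, stringsAsFactors = FALSE)
}

#' Write / read a network as GraphML
#'
#' GraphML export replaces interactive viewers: the hub subnetwork and other
#' artifacts can be opened in Cytoscape/Gephi. Round trip preserves node
#' names, the edge set and the `sources` provenance attribute.
#'
#' @param network igraph network.
#' @param path output file.
#' @return `path`, invisibly (writer); an igraph (reader).
#' @export
write_graphml <- function(network, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  ## igraph stores a numeric "id" attribute on round trip; drop bookkeeping
  for (a in setdiff(igraph::vertex_attr_names(g), "name")) {
    g <- igraph::delete_vertex_attr(g, a)
  }
  g
}

#' Write an edge table as 3-column TSV
#'
#' @param network igraph network.
#' @param path output file.
#' @export
write_edge_tsv <- function(network, path) {
  utils::write.table(network_edges(network), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Induced subgraph on a symbol set, keeping requested members as isolates
#'
#' @param network igraph network.
#' @param symbols gene symbols to induce on (normalized).
#' @param keep_missing if TRUE, symbols absent from the network are added as
#'   degree-0 nodes (with a message); if FALSE they are ignored.
#' @return igraph network.
#' @export
induce_network <- function(network, symbols, keep_missing = FALSE) {
  symbols <- unique(normalize_symbols(symbols))
  present <- intersect(symbols, igraph::V(network)$name)
  g <- igraph::induced_subgraph(network, present)
  missing <- setdiff(symbols, present)
  if (keep_missing && length(missing)) {
    message(sprintf("%d member(s) absent from the interaction data kept as isolated nodes",
                    length(missing)))
    g <- igraph::add_vertices(g, length(missing), name = missing)
  }
  g
}
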