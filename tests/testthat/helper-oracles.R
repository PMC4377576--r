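## Brute-force oracles, written independently of the package internals and of
## igraph: BFS/path enumeration on adjacency matrices, exhaustive k-core
## peeling, direct pmf summation, correlation by the definition formula.

rand_adj <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
  a <- a + t(a)
  dimnames(a) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
  a
}

adj_to_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

bf_dist <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] == 1))))
      nxt <- nxt[!is.finite(D[s, nxt])]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

bf_components <- function(adj) {
  D <- bf_dist(adj)
  n <- nrow(adj)
  id <- integer(n)
  next_id <- 0
  for (v in seq_len(n)) {
    if (id[v] == 0) {
      next_id <- next_id + 1
      id[is.finite(D[v, ])] <- next_id
    }
  }
  id
}

## all shortest paths between s and t by exhaustive simple-path enumeration
bf_shortest_paths <- function(adj, s, t) {
  best <- Inf
  acc <- list()
  rec <- function(path) {
    v <- path[length(path)]
    if (length(path) - 1 > best) return(invisible())
    if (v == t) {
      len <- length(path) - 1
      if (len < best) {
        best <<- len
        acc <<- list(path)
      } else if (len == best) {
        acc[[length(acc) + 1]] <<- path
      }
      return(invisible())
    }
    for (w in which(adj[v, ] == 1)) {
      if (!(w %in% path)) rec(c(path, w))
    }
  }
  rec(s)
  acc
}

bf_betweenness <- function(adj) {
  n <- nrow(adj)
  b <- numeric(n)
  D <- bf_dist(adj)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (!is.finite(D[s, t])) next
      paths <- bf_shortest_paths(adj, s, t)
      total <- length(paths)
      inner <- setdiff(seq_len(n), c(s, t))
      for (v in inner) {
        through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
        b[v] <- b[v] + through / total
      }
    }
  }
  comp <- bf_components(adj)
  csize <- as.integer(table(comp)[as.character(comp)])
  pairs <- (csize - 1) * (csize - 2) / 2
  ifelse(pairs > 0, b / pairs, 0)
}

bf_closeness <- function(adj) {
  D <- bf_dist(adj)
  comp <- bf_components(adj)
  csize <- as.integer(table(comp)[as.character(comp)])
  vapply(seq_len(nrow(adj)), function(v) {
    far <- sum(D[v, is.finite(D[v, ])])
    if (far > 0) 100 * (csize[v] - 1) / far else 0
  }, numeric(1))
}

bf_kcore <- function(adj) {
  n <- nrow(adj)
  core <- integer(n)
  for (k in 0:n) {
    alive <- rep(TRUE, n)
    repeat {
      degs <- vapply(seq_len(n), function(v)
        if (alive[v]) sum(adj[v, alive]) else Inf, numeric(1))
      drop <- alive & degs < k
      if (!any(drop)) break
      alive[drop] <- FALSE
    }
    core[alive] <- k
  }
  core
}

bf_topology <- function(adj) {
  data.frame(node = rownames(adj), degree = as.integer(rowSums(adj)),
             betweenness = bf_betweenness(adj),
             closeness = bf_closeness(adj), kcore = bf_kcore(adj),
             stringsAsFactors = FALSE)
}

## middle element / mean of the two middle elements
bf_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

bf_major_hubs <- function(features) {
  keep <- rep(TRUE, nrow(features))
  for (f in c("degree", "betweenness", "closeness", "kcore")) {
    keep <- keep & features[[f]] > bf_median(features[[f]])
  }
  sort(features$node[keep])
}

bf_hyper_upper <- function(k, K, n, N) {
  i <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

bf_pearson <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(NA_real_)
  sum(dx * dy) / den
}

bf_tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) 0 else length(intersect(a, b)) / u
}

## full brute-force compound ranking: chem vector, proximity by BFS
## distances, correlation by definition, tie-break (NA last, score desc,
## symbol asc)
bf_rank_targets <- function(fp, panel_fps, panel_targets, adj) {
  nodes <- rownames(adj)
  D <- bf_dist(adj)
  chem <- vapply(panel_fps, function(d) bf_tanimoto(fp, d), numeric(1))
  scores <- vapply(seq_along(nodes), function(vi) {
    fun <- vapply(panel_targets, function(tg) {
      tg <- intersect(tg, nodes)
      if (!length(tg)) return(0)
      sum(exp(-D[vi, match(tg, nodes)]^2))
    }, numeric(1))
    bf_pearson(chem, fun)
  }, numeric(1))
  snapped <- round(scores, 10)
  ord <- order(is.na(snapped), -ifelse(is.na(snapped), 0, snapped), nodes)
  data.frame(protein = nodes[ord], score = scores[ord],
             stringsAsFactors = FALSE)
}

## small crafted hub network: a K4 core with five pendants on one node; the
## core gateway strictly dominates all four features
hub_toy_graph <- function() {
  edges <- rbind(c("A", "B"), c("A", "C"), c("A", "D"), c("B", "C"),
                 c("B", "D"), c("C", "D"),
                 cbind("A", paste0("P", 1:5)))
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE)
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  adj <- adj[order(rownames(adj)), order(colnames(adj))]
  list(graph = g, adj = adj)
}

## 4-node path with a 2-drug panel: the hand-computable worked example
toy_prediction_case <- function() {
  net <- interaction_network(data.frame(
    from = c("A", "B", "C"), to = c("B", "C", "D"), source = "toy"))
  panel <- drug_panel(
    c("D1", "D2"),
    fingerprints = list(c(0L, 1L, 2L), c(5L, 6L, 7L)),
    targets = list("A", "D"),
    fingerprint_length = 16)
  list(network = net, panel = panel, query = c(0L, 1L, 2L))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
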