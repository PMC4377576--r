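#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn without replacement
#' from a universe of `N` genes of which `K` are annotated. Evaluated
#' through the stable log-space tail routine of [stats::phyper()].
#'
#' @param k overlap count.
#' @param K annotated genes in the universe (set size).
#' @param n query size.
#' @param N universe size.
#' @return probability in `(0, 1]`.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k < 0 || k > min(K, n)) stop("k must satisfy 0 <= k <= min(K, n)")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a query gene set
#'
#' Hypergeometric test of each gene set against the query, Bonferroni
#' corrected over the number of sets with a non-empty intersection with the
#' universe. Sets and query are intersected with the universe first; query
#' symbols outside the universe are dropped with a message.
#'
#' @param query symbol set (e.g. candidate targets).
#' @param sets a `gene_set_collection`.
#' @param universe background symbol set; defaults to the collection's
#'   universe, which must then be present.
#' @param ease if TRUE, apply the EASE penalization (test `k - 1` instead of
#'   `k`).
#' @return an `enrichment_result` data.frame sorted by
#'   (`p_bonferroni`, `set_id`), with columns `set_id`, `set_name`,
#'   `overlap_genes` (list), `k`, `K`, `n`, `N`, `p_raw`, `p_bonferroni`.
#' @export
enrich <- function(query, sets, universe = NULL, ease = FALSE) {
  universe <- universe %||% sets$universe
  if (is.null(universe) || !length(universe)) stop("empty universe")
  universe <- unique(normalize_symbols(universe))
  query <- unique(normalize_symbols(query))
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    message(sprintf("%d query symbol(s) outside the universe dropped",
                    length(dropped)))
  }
  query <- intersect(query, universe)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(sets$sets, function(s) {
    members_u <- intersect(s$members, universe)
    ov <- sort(intersect(members_u, query))
    k <- length(ov)
    p <- if (ease) hypergeom_upper(max(k - 1, 0), length(members_u), n, N)
         else hypergeom_upper(k, length(members_u), n, N)
    list(set_id = s$id, set_name = s$name, overlap_genes = ov, k = k,
         K = length(members_u), p_raw = p)
  })
  K <- vapply(rows, `[[`, integer(1), "K")
  m <- sum(K > 0)
  out <- data.frame(set_id = vapply(rows, `[[`, character(1), "set_id"),
                    set_name = vapply(rows, `[[`, character(1), "set_name"),
                    k = vapply(rows, `[[`, integer(1), "k"), K = K,
                    n = n, N = N,
                    p_raw = vapply(rows, `[[`, numeric(1), "p_raw"),
                    stringsAsFactors = FALSE)
  out$p_bonferroni <- pmin(1, m * out$p_raw)
  out$overlap_genes <- lapply(rows, `[[`, "overlap_genes")
  out <- out[order(out$p_bonferroni, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_tested = m, class = c("enrichment_result", "data.frame"))
}

#' Top rows of an enrichment result, report-table style
#'
#' @param result an `enrichment_result`.
#' @param top number of rows.
#' @return data.frame with `set_id`, `set_name`, slash-joined overlap genes
#'   and the Bonferroni-corrected p-value.
#' @export
top_enrichment <- function(result, top = 10) {
  head_rows <- utils::head(result, top)
  data.frame(set_id = head_rows$set_id, set_name = head_rows$set_name,
             genes = vapply(head_rows$overlap_genes, paste, character(1),
                            collapse = "/"),
             p_bonferroni = head_rows$p_bonferroni,
             stringsAsFactors = FALSE)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Enrichment:", nrow(x), "gene sets,", attr(x, "n_tested"),
      "tested (non-empty in universe); query size", x$n[1],
      "of universe", x$N[1], "\n")
  top <- top_enrichment(x, 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %s %s: k=%d, p_bonf=%.3g\n", top$set_id[i],
                top$set_name[i], x$k[i], top$p_bonferroni[i]))
  }
  invisible(x)
}

#' Write an enrichment result as TSV
#'
#' @param result an `enrichment_result`.
#' @param path output file.
#' @export
write_enrichment_tsv <- function(result, path) {
  out <- data.frame(set_id = result$set_id, set_name = result$set_name,
                    genes = vapply(result$overlap_genes, paste, character(1),
                                   collapse = "/"),
                    k = result$k, K = result$K, n = result$n, N = result$N,
                    p_raw = result$p_raw, p_bonferroni = result$p_bonferroni,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
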