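#' Load a herb compound catalogue
#'
#' Reads the tabular catalogue of compounds for each herb of a formula. The
#' file is tab-separated with a header and must contain columns `compound_id`
#' and `herb`, plus either a `fingerprint` column (comma-separated 0-based
#' on-bit indices) or a `smiles` column (converted through
#' [fingerprint_from_smiles()]). An optional `name` column is carried along.
#'
#' @param path catalogue file.
#' @param fingerprint_length declared fingerprint length; every bit index must
#'   be `< fingerprint_length`.
#' @return a `compound_catalogue`: data.frame with columns `compound_id`,
#'   `herb`, `name` and a `fingerprint` list-column, with attributes
#'   `fingerprint_length`, `per_herb` (named counts) and `total`.
#' @export
load_compound_catalogue <- function(path, fingerprint_length) {
  stopifnot(is.numeric(fingerprint_length), fingerprint_length >= 1)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("compound_id", "herb") %in% names(tab))) {
    stop("catalogue must have columns compound_id and herb")
  }
  if (!nrow(tab)) {
    return(new_catalogue(data.frame(compound_id = character(0),
                                    herb = character(0), name = character(0),
                                    stringsAsFactors = FALSE),
                         list(), fingerprint_length))
  }
  dup <- tab$compound_id[duplicated(tab$compound_id)]
  if (length(dup)) {
    stop("duplicate compound_id: ", paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(trimws(tab$herb)))) stop("empty herb label in catalogue")

  if ("fingerprint" %in% names(tab)) {
    fps <- lapply(tab$fingerprint, parse_bits)
  } else if ("smiles" %in% names(tab)) {
    fps <- fingerprint_from_smiles(tab$smiles, fingerprint_length)
  } else {
    stop("catalogue needs a fingerprint or smiles column")
  }
  for (i in seq_along(fps)) {
    if (length(fps[[i]]) && max(fps[[i]]) >= fingerprint_length) {
      stop(sprintf("row %d (compound_id %s): bit index %d >= fingerprint length %d",
                   i, tab$compound_id[i], max(fps[[i]]), fingerprint_length))
    }
  }
  df <- data.frame(compound_id = tab$compound_id, herb = tab$herb,
                   name = if ("name" %in% names(tab)) tab$name else tab$compound_id,
                   stringsAsFactors = FALSE)
  new_catalogue(df, fps, fingerprint_length)
}

new_catalogue <- function(df, fingerprints, fingerprint_length) {
  df$fingerprint <- fingerprints
  per_herb <- if (nrow(df)) table(df$herb) else table(character(0))
  structure(df,
            fingerprint_length = as.integer(fingerprint_length),
            per_herb = c(per_herb),
            total = nrow(df),
            class = c("compound_catalogue", "data.frame"))
}

#' @export
print.compound_catalogue <- function(x, ...) {
  cat("Compound catalogue:", attr(x, "total"), "compounds,",
      length(attr(x, "per_herb")), "herb(s);",
      "fingerprint length", attr(x, "fingerprint_length"), "\n")
  ph <- attr(x, "per_herb")
  for (h in names(ph)) cat(sprintf("  %s: %d\n", h, ph[[h]]))
  invisible(x)
}

#' Write a compound catalogue as TSV
#' @param catalogue a `compound_catalogue`.
#' @param path output file.
#' @export
write_compound_catalogue <- function(catalogue, path) {
  out <- data.frame(compound_id = catalogue$compound_id,
                    herb = catalogue$herb, name = catalogue$name,
                    fingerprint = vapply(catalogue$fingerprint, format_bits,
                                         character(1)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert SMILES strings to folded binary fingerprints
#'
#' Isolated chemistry entry point: the rest of the pipeline only ever sees
#' abstract on-bit index sets. Uses ChemmineR atom-pair descriptors folded to
#' the requested length; requires the ChemmineR package.
#'
#' @param smiles character vector of SMILES strings.
#' @param fingerprint_length folded fingerprint length (e.g. 512).
#' @return list of 0-based on-bit index vectors.
#' @export
fingerprint_from_smiles <- function(smiles, fingerprint_length) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("fingerprint_from_smiles requires the ChemmineR package")
  }
  names(smiles) <- sprintf("s%d", seq_along(smiles))
  sdf <- ChemmineR::smiles2sdf(smiles)
  ap <- ChemmineR::sdf2ap(sdf)
  ## fold onto the most common atom-pair descriptors
  e <- new.env()
  utils::data("apfp", package = "ChemmineR", envir = e)
  if (fingerprint_length > nrow(e$apfp)) {
    stop("fingerprint_length exceeds the available descriptor set (",
         nrow(e$apfp), ")")
  }
  descnames <- as.character(e$apfp$AP)[seq_len(fingerprint_length)]
  fp <- ChemmineR::desc2fp(ap, descnames = descnames, type = "matrix")
  lapply(seq_len(nrow(fp)), function(i) as_fingerprint(which(fp[i, ] != 0) - 1L))
}

#' Load a reference drug panel
#'
#' The panel spans the "drug space" (fingerprints) and the "target space"
#' (known target sets) against which query compounds and candidate proteins
#' are profiled. TSV with header columns `drug_id`, `fingerprint`
#' (comma-separated on-bit indices), `targets` (comma-separated symbols) and
#' optional `indication`.
#'
#' @param path panel file.
#' @param fingerprint_length declared fingerprint length.
#' @return a `drug_panel` data.frame with list-columns `fingerprint`,
#'   `targets`.
#' @export
load_drug_panel <- function(path, fingerprint_length) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("drug_id", "fingerprint", "targets") %in% names(tab))) {
    stop("panel must have columns drug_id, fingerprint, targets")
  }
  dup <- tab$drug_id[duplicated(tab$drug_id)]
  if (length(dup)) stop("duplicate drug_id: ", paste(unique(dup), collapse = ", "))
  fps <- lapply(tab$fingerprint, parse_bits)
  tg <- lapply(tab$targets, function(s) sort(unique(normalize_symbols(
    strsplit(s, "[,;]")[[1]]))))
  if (any(vapply(tg, length, integer(1)) == 0)) {
    stop("every panel drug needs a non-empty target set")
  }
  new_drug_panel(tab$drug_id, fps, tg,
                 if ("indication" %in% names(tab)) tab$indication else NA,
                 fingerprint_length)
}

#' Construct a reference drug panel in memory
#'
#' @param drug_id unique drug identifiers.
#' @param fingerprints list of 0-based on-bit index vectors.
#' @param targets list of non-empty gene-symbol vectors.
#' @param indication optional free-text indications.
#' @param fingerprint_length declared fingerprint length.
#' @return a `drug_panel`.
#' @export
drug_panel <- function(drug_id, fingerprints, targets, indication = NA,
                       fingerprint_length) {
  stopifnot(length(drug_id) == length(fingerprints),
            length(drug_id) == length(targets))
  if (anyDuplicated(drug_id)) stop("duplicate drug_id")
  if (any(vapply(targets, length, integer(1)) == 0)) {
    stop("every panel drug needs a non-empty target set")
  }
  fingerprints <- lapply(fingerprints, as_fingerprint)
  targets <- lapply(targets, function(t) sort(unique(normalize_symbols(t))))
  new_drug_panel(drug_id, fingerprints, targets, indication,
                 fingerprint_length)
}

new_drug_panel <- function(drug_id, fingerprints, targets, indication,
                           fingerprint_length) {
  df <- data.frame(drug_id = drug_id,
                   indication = rep_len(indication, length(drug_id)),
                   stringsAsFactors = FALSE)
  df$fingerprint <- fingerprints
  df$targets <- targets
  structure(df, fingerprint_length = as.integer(fingerprint_length),
            class = c("drug_panel", "data.frame"))
}

#' @export
print.drug_panel <- function(x, ...) {
  cat("Reference drug panel:", nrow(x), "drugs;",
      length(unique(unlist(x$targets))), "distinct target symbols;",
      "fingerprint length", attr(x, "fingerprint_length"), "\n")
  invisible(x)
}

#' Write a drug panel as TSV
#' @param panel a `drug_panel`.
#' @param path output file.
#' @export
write_drug_panel <- function(panel, path) {
  out <- data.frame(drug_id = panel$drug_id,
                    fingerprint = vapply(panel$fingerprint, format_bits, character(1)),
                    targets = vapply(panel$targets, paste, character(1), collapse = ","),
                    indication = panel$indication,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load known disease-target symbol lists
#'
#' Each file is a plain list of gene symbols (one per line); the union is
#' case-normalized and deduplicated, and every symbol keeps the set of source
#' labels it came from.
#'
#' @param paths character vector of symbol-list files.
#' @param sources provenance labels, recycled against `paths`; default file
#'   base names.
#' @param disease free-text disease label.
#' @return a `known_targets` object: list with `disease`, `members` (sorted
#'   unique symbols), `source_tags` (named list of label sets) and
#'   `per_source` counts.
#' @export
load_known_targets <- function(paths, sources = NULL, disease = "disease") {
  if (is.null(sources)) sources <- basename(paths)
  sources <- rep_len(sources, length(paths))
  tags <- list()
  by_source <- list()
  for (i in seq_along(paths)) {
    syms <- readLines(paths[[i]], warn = FALSE)
    syms <- unique(normalize_symbols(syms[nzchar(trimws(syms))]))
    by_source[[sources[[i]]]] <- union(by_source[[sources[[i]]]], syms)
    for (s in syms) tags[[s]] <- sort(unique(c(tags[[s]], sources[[i]])))
  }
  per_source <- vapply(by_source, length, integer(1))
  members <- sort(names(tags))
  if (!length(members)) warning("known-target union is empty")
  structure(list(disease = disease, members = members,
                 source_tags = tags[members], per_source = per_source),
            class = "known_targets")
}

#' @export
print.known_targets <- function(x, ...) {
  cat(sprintf("Known targets for %s: %d symbols after deduplication\n",
              x$disease, length(x$members)))
  for (s in names(x$per_source)) cat(sprintf("  %s: %d\n", s, x$per_source[[s]]))
  invisible(x)
}

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, tab-separated `set_id`, description, then
#' member symbols.
#'
#' @param path GMT file.
#' @return a `gene_set_collection`: list with `sets` (named list of
#'   `list(id, name, members)`) and optional `universe`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("%s line %d: GMT needs id, description and >=1 member", path, i))
    }
    id <- fields[1]
    if (id %in% names(sets)) stop("duplicate set_id: ", id)
    sets[[id]] <- list(id = id, name = fields[2],
                       members = sort(unique(normalize_symbols(fields[-(1:2)]))))
  }
  gene_set_collection(sets)
}

#' @rdname read_gmt
#' @param collection a `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  lines <- vapply(collection$sets, function(s)
    paste(c(s$id, s$name, s$members), collapse = "\t"), character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

#' @rdname read_gmt
#' @param sets named list of `list(id, name, members)`.
#' @param universe optional explicit background symbol set.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  ids <- vapply(sets, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate set_id in collection")
  if (any(vapply(sets, function(s) length(s$members) == 0, logical(1)))) {
    stop("gene sets must be non-empty")
  }
  names(sets) <- ids
  structure(list(sets = sets,
                 universe = if (is.null(universe)) NULL else
                   sort(unique(normalize_symbols(universe)))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- vapply(x$sets, function(s) length(s$members), integer(1))
  cat("Gene-set collection:", length(x$sets), "sets; sizes",
      if (length(sz)) paste0(min(sz), "-", max(sz)) else "-", "\n")
  invisible(x)
}

#' Packaged fixture: printed drug-target overlap table
#'
#' Loads the transcribed published table of putative targets that the five
#' herbs share with known anti-rheumatic drugs, and counts distinct target
#' symbols.
#'
#' @param target_class optional filter on the target classification column
#'   (exact string match, e.g. `"Successful target"`).
#' @return list with `rows` (data.frame: `herbs` list-column, `target_name`,
#'   `target_symbol`, `known_drug`, `indication`, `target_class`) and
#'   `distinct_targets` count.
#' @export
load_table2_fixture <- function(target_class = NULL) {
  path <- system.file("extdata", "table2_anti_ra_overlap.tsv",
                      package = "herbnet")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged anti-RA overlap fixture not found")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!is.null(target_class)) tab <- tab[tab$target_class == target_class, ]
  rows <- data.frame(target_name = tab$target_name,
                     target_symbol = normalize_symbols(tab$target_symbol),
                     known_drug = tab$known_drug, indication = tab$indication,
                     target_class = tab$target_class, stringsAsFactors = FALSE)
  rows$herbs <- strsplit(tab$herbs, "/", fixed = TRUE)
  if (any(!nzchar(rows$target_symbol))) stop("fixture row with empty target symbol")
  list(rows = rows, distinct_targets = length(unique(rows$target_symbol)))
}

#' Packaged fixture: OMIM-derived disease targets
#'
#' @return `known_targets` object for the packaged OMIM symbol list.
#' @export
load_omim_fixture <- function() {
  path <- system.file("extdata", "omim_ra_targets.txt", package = "herbnet")
  if (!nzchar(path) || !file.exists(path)) stop("packaged OMIM fixture not found")
  load_known_targets(path, sources = "OMIM", disease = "rheumatoid arthritis")
}
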