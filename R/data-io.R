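#' Load a gene-expression matrix from TSV
#'
#' Reads a tab-separated matrix whose first row holds cell-line labels and
#' whose first column holds gene symbols. Duplicate gene rows (e.g. multiple
#' probes mapping to one gene) are collapsed by their mean, which is reported
#' via `message()`. Values must be numeric and finite.
#'
#' @param path path to the TSV file.
#' @return an [ExpressionMatrix-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tc1\tc2\tc3", "TP53\t1\t2\t3", "EGFR\t4\t5\t6"), tf)
#' loadExpressionMatrix(tf)
#' @export
loadExpressionMatrix <- function(path) {
  m <- .readIdMatrix(path)
  rownames(m) <- .normSymbol(rownames(m))
  if (anyDuplicated(rownames(m))) {
    ndup <- sum(duplicated(rownames(m)))
    .msg("collapsing %d duplicate gene row(s) by mean", ndup)
    m <- do.call(rbind, lapply(split(seq_len(nrow(m)), rownames(m)),
                               function(i) colMeans(m[i, , drop = FALSE])))
  }
  new("ExpressionMatrix", m[order(rownames(m)), , drop = FALSE])
}

#' Load a drug-activity matrix from TSV
#'
#' Same layout as [loadExpressionMatrix()]: first row cell-line labels,
#' first column drug names, values lgGI50. Entries equal to any of
#' `missingTokens` (or empty) are flagged as missing (`NA`), never coerced
#' to zero. All-missing drugs are retained at load; filtering by
#' missingness is a separate step ([filterDrugsByMissingness()]).
#'
#' @param path path to the TSV file.
#' @param missingTokens character vector of tokens marking missing values.
#' @param cellOrder optional character vector; when given, columns are
#'   aligned (subset + reorder) to this reference order, with a message for
#'   any cells absent from the file.
#' @return an [ActivityMatrix-class].
#' @export
loadActivityMatrix <- function(path, missingTokens = c("NaN", "NA", ""),
                               cellOrder = NULL) {
  m <- .readIdMatrix(path, missingTokens = missingTokens)
  rownames(m) <- .normSymbol(rownames(m))
  if (anyDuplicated(rownames(m)))
    stop("duplicate drug identifiers: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (all(rowSums(!is.na(m)) == 0))
    stop("no drug has any usable activity value")
  if (!is.null(cellOrder)) {
    keep <- intersect(cellOrder, colnames(m))
    if (length(keep) < length(cellOrder))
      .msg("%d reference cell line(s) absent from activity file",
           length(cellOrder) - length(keep))
    if (length(keep) < 3) stop("fewer than 3 cell lines after alignment")
    m <- m[, keep, drop = FALSE]
  }
  new("ActivityMatrix", m)
}

#' Load an undirected protein-interaction network from an edge list
#'
#' Reads a two-or-more-column TSV of gene-symbol pairs (extra columns
#' ignored, `#` comment lines skipped), drops self-loops, merges duplicate
#' and reversed edges, and returns a simple undirected [igraph][igraph::graph]
#' over normalized symbols. Counts of dropped records are messaged.
#'
#' @param path path to the edge-list TSV.
#' @param header logical; does the file start with a header line?
#' @return an undirected simple `igraph` graph.
#' @export
loadNetwork <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    read.delim(path, header = header, sep = "\t", check.names = FALSE,
               colClasses = "character", quote = "", comment.char = "#"),
    error = function(e) stop("empty or unreadable edge list: ", path))
  if (nrow(raw) == 0 || ncol(raw) < 2)
    stop("edge list needs at least two columns and one edge: ", path)
  a <- .normSymbol(raw[[1]]); b <- .normSymbol(raw[[2]])
  ok <- nzchar(a) & nzchar(b)
  loops <- ok & a == b
  ed <- cbind(pmin(a[ok & !loops], b[ok & !loops]),
              pmax(a[ok & !loops], b[ok & !loops]))
  dups <- duplicated(paste(ed[, 1], ed[, 2], sep = "\r"))
  if (sum(loops) || sum(dups) || sum(!ok))
    .msg("dropped %d self-loop(s), %d duplicate edge(s), %d malformed row(s)",
         sum(loops), sum(dups), sum(!ok))
  ed <- ed[!dups, , drop = FALSE]
  if (nrow(ed) == 0) stop("empty network after cleaning: ", path)
  igraph::graph_from_edgelist(ed, directed = FALSE)
}

#' Load gene sets from a GMT file
#'
#' GMT dialect: one term per line, `term_id TAB description TAB gene1 TAB
#' gene2 ...`. Gene symbols are trimmed and uppercased; duplicates within a
#' term are collapsed. Lines with fewer than three fields are skipped with
#' a warning; repeated term ids are unioned with a warning.
#'
#' @param path path to the GMT file.
#' @param namespaces optional named character mapping term id -> namespace
#'   (BP/MF/CC); unknown terms get `""`.
#' @return a [GeneAnnotation-class].
#' @export
loadGeneSets <- function(path, namespaces = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short))
    warning(sum(short), " GMT line(s) with fewer than 3 fields skipped")
  fields <- fields[!short]
  if (length(fields) == 0) stop("no usable gene-set lines in ", path)
  ids <- vapply(fields, function(f) trimws(f[1]), "")
  descs <- vapply(fields, function(f) trimws(f[2]), "")
  sets <- lapply(fields, function(f) unique(.normSymbol(f[-(1:2)])))
  sets <- lapply(sets, function(s) s[nzchar(s)])
  if (anyDuplicated(ids)) {
    warning("duplicate term id(s) in GMT merged by union: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    sets <- lapply(split(sets, ids), function(g) unique(unlist(g)))
    descs <- vapply(split(descs, ids), `[`, "", 1)
    ids <- names(sets)
  } else {
    names(sets) <- ids
    names(descs) <- ids
  }
  ns <- setNames(rep("", length(ids)), ids)
  if (!is.null(namespaces)) {
    hit <- intersect(ids, names(namespaces))
    ns[hit] <- namespaces[hit]
  }
  new("GeneAnnotation", sets = sets, termNames = descs, namespaces = ns)
}

# Build an OntologyDAG from child->parent links, checking acyclicity and
# reachability of a root from every term, and precomputing depths by BFS
# downward from the roots.
.makeDAG <- function(child, parent, allTerms = NULL) {
  terms <- unique(c(child, parent, allTerms))
  parents <- split(parent, factor(child, levels = terms))
  parents <- lapply(parents, unique)
  roots <- terms[lengths(parents) == 0]
  if (length(roots) == 0)
    stop("cycle detected in ontology links: no parentless root term; ",
         "term '", terms[1], "' is inside a cycle")
  # cycle check via Kahn's algorithm on child->parent edges
  indeg <- lengths(parents)
  children <- split(child, factor(parent, levels = terms))
  queue <- roots; seen <- 0L
  indeg2 <- indeg
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[t]]) {
      indeg2[[ch]] <- indeg2[[ch]] - 1L
      if (indeg2[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(terms)) {
    bad <- terms[indeg2 > 0][1]
    stop("cycle detected in ontology links involving term '", bad, "'")
  }
  depths <- setNames(rep(NA_integer_, length(terms)), terms)
  depths[roots] <- 0L
  frontier <- roots; d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- nxt[is.na(depths[nxt])]
    depths[nxt] <- d
    frontier <- nxt
  }
  dag <- new("OntologyDAG", parents = parents, roots = roots,
             depths = depths)
  dag
}

#' Load an ontology parent-child DAG
#'
#' Accepts either a two-column child-parent TSV or a minimal OBO 1.2 subset
#' (`[Term]` stanzas with `id:`, `is_a:` and `relationship: part_of` lines;
#' `is_obsolete` stanzas skipped). Roots are auto-detected as parentless
#' terms and each term's depth (shortest path from a root) is precomputed.
#'
#' @param path path to the file.
#' @param format `"auto"` (by extension/content), `"tsv"` or `"obo"`.
#' @return an [OntologyDAG-class].
#' @export
loadOntologyGraph <- function(path, format = c("auto", "tsv", "obo")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto")
    format <- if (any(grepl("^\\[Term\\]", lines))) "obo" else "tsv"
  if (format == "obo") {
    lines <- trimws(lines)
    starts <- which(lines == "[Term]")
    if (length(starts) == 0) stop("no [Term] stanzas in ", path)
    bounds <- c(starts, length(lines) + 1L)
    child <- character(); parent <- character(); ids <- character()
    for (s in seq_along(starts)) {
      stanza <- lines[seq(bounds[s] + 1L, bounds[s + 1L] - 1L)]
      brk <- which(startsWith(stanza, "["))  # e.g. a [Typedef] block
      if (length(brk)) stanza <- stanza[seq_len(brk[1] - 1L)]
      if (any(startsWith(stanza, "is_obsolete: true"))) next
      id <- sub("^id: ", "", stanza[startsWith(stanza, "id: ")][1])
      if (is.na(id)) next
      ids <- c(ids, id)
      pa <- c(sub("\\s*!.*$", "",
                  sub("^is_a: ", "", stanza[startsWith(stanza, "is_a: ")])),
              sub("\\s*!.*$", "",
                  sub("^relationship: part_of ",  "",
                      stanza[startsWith(stanza, "relationship: part_of ")])))
      pa <- trimws(pa[nzchar(pa)])
      child <- c(child, rep(id, length(pa)))
      parent <- c(parent, pa)
    }
    return(.makeDAG(child, parent, allTerms = union(ids, parent)))
  }
  tab <- read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                    colClasses = "character", quote = "")
  if (ncol(tab) < 2) stop("child-parent TSV needs two columns: ", path)
  .makeDAG(trimws(tab[[1]]), trimws(tab[[2]]))
}

#' Load the curated drug-gene compendium
#'
#' Reads a TSV with (at least) a drug column and a gene column; optional
#' cell-line, PMID and description columns are carried along. Names are
#' whitespace/case normalized and rows are deduplicated on the
#' (drug, gene) pair. Rows with an empty drug or gene are rejected with a
#' warning.
#'
#' @param path path to the TSV file.
#' @param drugCol,geneCol column names holding the drug and gene.
#' @return a [Compendium-class].
#' @export
loadCompendium <- function(path, drugCol = "drug", geneCol = "gene") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "", comment.char = "")
  if (!drugCol %in% names(tab)) stop("missing drug column '", drugCol, "'")
  if (!geneCol %in% names(tab)) stop("missing gene column '", geneCol, "'")
  df <- data.frame(drug = .normSymbol(tab[[drugCol]]),
                   gene = .normSymbol(tab[[geneCol]]),
                   stringsAsFactors = FALSE)
  opt <- c(cell_line = "cell_line", pmid = "pmid",
           description = "description")
  for (nm in names(opt))
    df[[nm]] <- if (opt[[nm]] %in% names(tab)) trimws(tab[[opt[[nm]]]])
                else NA_character_
  bad <- !nzchar(df$drug) | !nzchar(df$gene)
  if (any(bad)) {
    warning(sum(bad), " compendium row(s) with empty drug or gene rejected")
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no usable compendium rows in ", path)
  dup <- duplicated(.pairKey(df$drug, df$gene))
  if (any(dup)) .msg("deduplicated %d repeated compendium pair(s)", sum(dup))
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  new("Compendium", pairs = df)
}

#' Summarize a compendium
#'
#' @param compendium a [Compendium-class].
#' @return named integer vector: `n_pairs` (distinct drug-gene pairs),
#'   `n_drugs`, `n_genes` (distinct normalized names).
#' @export
compendiumSummary <- function(compendium) {
  p <- compendiumPairs(compendium)
  c(n_pairs = nrow(p),
    n_drugs = length(unique(p$drug)),
    n_genes = length(unique(p$gene)))
}

#' Write a prediction table to TSV
#'
#' Deterministic row order (drug ascending, then q_score ascending, then
#' gene ascending) so identical runs produce byte-identical files. Numeric
#' columns are formatted at 10 significant digits.
#'
#' @param table a [PredictionTable-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePredictions <- function(table, path) {
  df <- predictions(table)
  if (nrow(df))
    df <- df[order(df$drug, df$q_score, df$gene), , drop = FALSE]
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.logical, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 10,
                                                trim = TRUE,
                                                scientific = FALSE))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Writers for the synthetic bundle (and round-trip tests).
.writeIdMatrix <- function(m, path, idName = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idName
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.writeEdgeList <- function(g, path) {
  ed <- igraph::as_edgelist(g)
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  ed <- ed[order(ed[, 1], ed[, 2]), , drop = FALSE]
  write.table(ed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.writeGMT <- function(annotation, path) {
  sets <- geneSets(annotation)
  lines <- vapply(names(sets), function(id)
    paste(c(id, annotation@termNames[[id]], sets[[id]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}

.writeOntologyTSV <- function(dag, path) {
  child <- rep(names(dag@parents), lengths(dag@parents))
  parent <- unlist(dag@parents, use.names = FALSE)
  write.table(data.frame(child, parent)[order(child, parent), ],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
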