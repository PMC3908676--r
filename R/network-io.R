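#' Read a PPI network from an edge-list or SIF file
#'
#' Builds an undirected simple graph of proteins. Self-interactions (loops)
#' and duplicate pairs (in either order) are discarded, matching the usual
#' simple-graph model of a PPI network. Lines starting with `#` and blank
#' lines are skipped.
#'
#' @param path Path to the network file.
#' @param format `"edgelist"` (two whitespace/tab-delimited protein IDs per
#'   line) or `"sif"` (three tokens: `A interaction_type B`; the middle token
#'   is ignored).
#' @return An undirected simple [igraph::igraph] with named vertices. An
#'   empty file yields an empty graph.
#' @examples
#' f <- tempfile()
#' writeLines(c("A B", "B A", "A A", "B C"), f)
#' net <- read_network(f)
#' igraph::vcount(net) # 3
#' igraph::ecount(net) # 2
#' @export
read_network <- function(path, format = c("edgelist", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_noncall("network file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  min_tok <- if (format == "edgelist") 2L else 3L
  from <- character(0)
  to <- character(0)
  for (i in idx) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tok) < min_tok) {
      stop_noncall("malformed ", format, " line ", i, " in ", path,
                   ": expected at least ", min_tok, " fields")
    }
    from <- c(from, tok[[1]])
    to <- c(to, tok[[if (format == "edgelist") 2L else 3L]])
  }
  nodes <- lex_sort(unique(c(from, to)))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  loop <- from == to
  if (any(!loop)) {
    keys <- pair_key(from[!loop], to[!loop])
    first <- !duplicated(keys)
    em <- cbind(from[!loop][first], to[!loop][first])
    g <- igraph::add_edges(g, t(em))
  }
  g
}

#' Write a PPI network as a two-column edge list
#'
#' Output is canonical: within each line the two endpoints are in
#' lexicographic order, and lines are sorted, so identical graphs always
#' produce byte-identical files. Isolated vertices cannot be represented in
#' an edge list and are dropped.
#'
#' @param net An undirected [igraph::igraph] with named vertices.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::ecount(net) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  em <- igraph::as_edgelist(net)
  swap <- em[, 1] > em[, 2]
  em[swap, ] <- em[swap, 2:1]
  lines <- paste(em[, 1], em[, 2], sep = "\t")
  writeLines(lex_sort(lines), path)
  invisible(path)
}

#' Construct a complex set
#'
#' A complex set is an ordered collection of protein complexes, each a set
#' of at least one protein identifier. It holds both predicted sets and
#' reference (benchmark) sets.
#'
#' @param complexes List of character vectors of protein IDs. Duplicate IDs
#'   within a complex are collapsed.
#' @return An object of class `complex_set` (a list of character vectors).
#' @export
complex_set <- function(complexes = list()) {
  stopifnot(is.list(complexes))
  complexes <- lapply(complexes, function(m) {
    m <- unique(as.character(m))
    if (length(m) == 0) stop_noncall("complexes must be non-empty")
    m
  })
  structure(complexes, class = "complex_set")
}

#' @export
print.complex_set <- function(x, ...) {
  cat("complex_set with", length(x), "complexes\n")
  sizes <- lengths(x)
  if (length(x) > 0) {
    cat("  sizes:", paste(utils::head(sizes, 20), collapse = " "),
        if (length(x) > 20) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
`[.complex_set` <- function(x, i) {
  complex_set(unclass(x)[i])
}

#' Canonicalize a complex set
#'
#' Sorts members lexicographically within each complex and orders complexes
#' by decreasing size, breaking ties by the lexicographically smallest first
#' member. This is the order used by [write_complexes()].
#'
#' @param cs A [complex_set()].
#' @return A canonically ordered `complex_set`.
#' @export
canonicalize_complexes <- function(cs) {
  cs <- complex_set(cs)
  members <- lapply(unclass(cs), lex_sort)
  if (length(members) > 1) {
    first <- vapply(members, `[`, character(1), 1L)
    ord <- order(-lengths(members), first, method = "radix")
    members <- members[ord]
  }
  complex_set(members)
}

#' Read a complex set file
#'
#' One complex per line, whitespace-separated protein IDs (the MCL output
#' convention). Blank lines are skipped; duplicate IDs within a line are
#' collapsed.
#'
#' @param path Path to the complex file.
#' @return A [complex_set()]; empty if the file has no non-blank lines.
#' @export
read_complexes <- function(path) {
  if (!file.exists(path)) {
    stop_noncall("complex file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  complex_set(lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]]))
}

#' Write a complex set file
#'
#' Writes in canonical form (see [canonicalize_complexes()]): one complex
#' per line, members sorted lexicographically, complexes ordered by size
#' descending then first member, so equal sets give byte-identical files.
#'
#' @param cs A [complex_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_complexes <- function(cs, path) {
  cs <- canonicalize_complexes(cs)
  writeLines(vapply(unclass(cs), paste, character(1), collapse = " "), path)
  invisible(path)
}

#' Read a protein localization table
#'
#' Two-column TSV: protein ID, then a comma-separated list of sub-cellular
#' location labels (possibly empty). Repeated rows for the same protein
#' union their label sets. Proteins absent from the file are treated as
#' unannotated.
#'
#' @param path Path to the TSV file.
#' @return A named list mapping protein ID to a character vector of
#'   location labels.
#' @export
read_localization <- function(path) {
  if (!file.exists(path)) {
    stop_noncall("localization file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  tab <- list()
  for (i in seq_along(lines)) {
    if (grepl("^\\s*$", lines[[i]])) next
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    prot <- trimws(fields[[1]])
    if (!nzchar(prot)) {
      stop_noncall("localization line ", i, " in ", path, ": missing protein ID")
    }
    locs <- character(0)
    if (length(fields) >= 2 && nzchar(trimws(fields[[2]]))) {
      locs <- trimws(strsplit(fields[[2]], ",", fixed = TRUE)[[1]])
      locs <- locs[nzchar(locs)]
    }
    tab[[prot]] <- unique(c(tab[[prot]], locs))
  }
  tab
}
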