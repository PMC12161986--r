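#' Interaction network over protein symbols
#'
#' Undirected, optionally score-weighted graph over uppercase protein
#' symbols: the protein-protein interaction (PPI) modality of the pipeline.
#' Edges are stored canonically with `from < to` (lexicographic), no
#' self-loops and no duplicates; scores, when present, lie in `[0, 1]`.
#'
#' @param edges data.frame with columns `from`, `to` and optionally `score`.
#' @param nodes character vector of node symbols; defaults to the union of
#'   edge endpoints. Symbols are uppercased and whitespace-trimmed.
#' @return An object of class `InteractionNetwork`: a list with elements
#'   `nodes` (sorted character), `edges` (data.frame `from`, `to`, and
#'   `score` when scores are present).
#' @export
interaction_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  from <- toupper(trimws(as.character(edges$from)))
  to <- toupper(trimws(as.character(edges$to)))
  has_score <- "score" %in% names(edges)
  score <- if (has_score) as.numeric(edges$score) else NULL

  keep <- from != to
  from <- from[keep]; to <- to[keep]
  if (has_score) score <- score[keep]

  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp

  key <- paste(from, to, sep = "\t")
  if (length(key) == 0L) {
    ed <- if (has_score) {
      data.frame(from = character(), to = character(), score = numeric(),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
    }
  } else if (has_score) {
    # duplicate edges collapse to the maximum score (keep strongest evidence)
    agg <- tapply(score, key, max)
    key <- names(agg)
    parts <- strsplit(key, "\t", fixed = TRUE)
    from <- vapply(parts, `[`, "", 1L)
    to <- vapply(parts, `[`, "", 2L)
    score <- as.numeric(agg)
    o <- order(from, to)
    ed <- data.frame(from = from[o], to = to[o], score = score[o],
                     stringsAsFactors = FALSE)
  } else {
    dup <- duplicated(key)
    o <- order(from[!dup], to[!dup])
    ed <- data.frame(from = from[!dup][o], to = to[!dup][o],
                     stringsAsFactors = FALSE)
  }

  if (is.null(nodes)) nodes <- union(ed$from, ed$to)
  nodes <- sort(unique(toupper(trimws(nodes))))
  cm_assert(all(ed$from %in% nodes) && all(ed$to %in% nodes),
            "edge endpoints must be members of `nodes`")
  if (has_score) {
    cm_assert(all(is.finite(ed$score)) && all(ed$score >= 0) && all(ed$score <= 1),
              "edge scores must be finite and in [0, 1]")
  }
  structure(list(nodes = nodes, edges = ed), class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork: %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if ("score" %in% names(x$edges)) " (scored)" else ""))
  invisible(x)
}

n_edges <- function(net) nrow(net$edges)

has_scores <- function(net) "score" %in% names(net$edges)

#' Convert an InteractionNetwork to an igraph graph
#'
#' @param net an `InteractionNetwork`.
#' @return An undirected `igraph` graph; edge scores become the `weight`
#'   edge attribute when present.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  if (has_scores(net)) igraph::E(g)$weight <- net$edges$score
  g
}

#' Read a tab-separated protein interaction edge list
#'
#' Parses a two- or three-column TSV (`geneA`, `geneB`, optional numeric
#' `score`). A header line is detected when the third field of the first
#' row is non-numeric. Symbols are uppercased and trimmed, self-loops are
#' dropped, duplicate edges collapse keeping the maximum score, and --
#' when scores are present -- edges below `min_score` are removed
#' (high-confidence filtering, e.g. STRING score >= 0.7).
#'
#' @param path file path.
#' @param score_column_present `NA` (autodetect from column count), `TRUE`
#'   or `FALSE`.
#' @param min_score minimum retained score; ignored for unscored input.
#' @return An [interaction_network()] object.
#' @export
read_edge_list <- function(path, score_column_present = NA, min_score = 0) {
  if (!file.exists(path))
    cm_stop(sprintf("edge list file not found: %s", path), "cm_parse_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    cm_stop(sprintf("empty edge list file: %s", path), "cm_empty_error")

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  start <- 1L
  if (nf[1] >= 3L && is.na(suppressWarnings(as.numeric(fields[[1]][3])))) {
    start <- 2L  # header row
  }
  if (start > length(fields))
    cm_stop(sprintf("edge list %s contains only a header", path), "cm_empty_error")
  fields <- fields[start:length(fields)]
  nf <- nf[start:length(nf)]

  want <- if (isTRUE(score_column_present)) 3L
          else if (isFALSE(score_column_present)) 2L
          else max(2L, min(nf[1], 3L))
  bad <- which(nf < want)
  if (length(bad) > 0L)
    cm_stop(sprintf("malformed edge list row at line %d of %s: expected >= %d columns, found %d",
                    bad[1] + start - 1L, path, want, nf[bad[1]]), "cm_parse_error")

  from <- vapply(fields, `[`, "", 1L)
  to <- vapply(fields, `[`, "", 2L)
  if (want >= 3L) {
    score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    if (anyNA(score))
      cm_stop(sprintf("non-numeric score at line %d of %s",
                      which(is.na(score))[1] + start - 1L, path), "cm_parse_error")
    ed <- data.frame(from = from, to = to, score = score, stringsAsFactors = FALSE)
  } else {
    ed <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  }

  net <- interaction_network(ed)
  if (has_scores(net) && min_score > 0) {
    keep <- net$edges$score >= min_score
    net$edges <- net$edges[keep, , drop = FALSE]
    rownames(net$edges) <- NULL
    net$nodes <- sort(union(net$edges$from, net$edges$to))
  }
  if (n_edges(net) == 0L)
    cm_stop("no edges remain after self-loop removal and score filtering",
            "cm_empty_error")
  net
}

#' Write an edge list TSV (inverse of [read_edge_list()])
#'
#' @param net an `InteractionNetwork`.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  ed <- net$edges
  lines <- if (has_scores(net)) {
    paste(ed$from, ed$to, sprintf("%.17g", ed$score), sep = "\t")
  } else {
    paste(ed$from, ed$to, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text protein list (one symbol per line)
#'
#' @param path file path.
#' @return Sorted unique uppercase symbols.
#' @export
read_protein_list <- function(path) {
  x <- toupper(trimws(readLines(path, warn = FALSE)))
  x <- x[nzchar(x)]
  if (length(x) == 0L) cm_stop("empty protein list", "cm_empty_error")
  sort(unique(x))
}
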