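#' Per-protein embedding set
#'
#' A fixed-dimension real vector per protein, tagged with the modality it
#' came from (`"ppi"`, `"image"` or `"coembedding"`).
#'
#' @param ids character vector of unique protein symbols.
#' @param vectors numeric matrix with `length(ids)` rows; all finite.
#' @param modality modality tag.
#' @return Object of class `EmbeddingSet` with fields `ids`, `vectors`
#'   (rownames set to ids), `modality`, `d`.
#' @export
embedding_set <- function(ids, vectors, modality = "ppi") {
  ids <- as.character(ids)
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  cm_assert(!anyDuplicated(ids), "embedding ids must be unique")
  cm_assert(nrow(vectors) == length(ids),
            "vector row count must equal the number of ids")
  cm_assert(all(is.finite(vectors)), "embedding vectors must be finite")
  rownames(vectors) <- ids
  structure(list(ids = ids, vectors = vectors, modality = modality,
                 d = ncol(vectors)),
            class = "EmbeddingSet")
}

#' @export
print.EmbeddingSet <- function(x, ...) {
  cat(sprintf("EmbeddingSet[%s]: %d proteins x %d dims\n",
              x$modality, length(x$ids), x$d))
  invisible(x)
}

#' Write an embedding TSV (`id` + one column per dimension, header row)
#'
#' Values are serialized with 17 significant digits so that
#' `read_embedding_tsv(write_embedding_tsv(E))` reproduces `E` exactly.
#'
#' @param emb an `EmbeddingSet`.
#' @param path output path.
#' @export
write_embedding_tsv <- function(emb, path) {
  header <- paste(c("id", paste0("v", seq_len(emb$d))), collapse = "\t")
  body <- vapply(seq_along(emb$ids), function(i) {
    paste(c(emb$ids[i], sprintf("%.17g", emb$vectors[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an embedding TSV written by [write_embedding_tsv()]
#'
#' @param path file path.
#' @param modality modality tag to attach.
#' @return An `EmbeddingSet`.
#' @export
read_embedding_tsv <- function(path, modality = "ppi") {
  if (!file.exists(path))
    cm_stop(sprintf("embedding file not found: %s", path), "cm_parse_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    cm_stop(sprintf("empty embedding file: %s", path), "cm_empty_error")
  if (length(lines) == 1L)
    cm_stop(sprintf("embedding file %s has a header but no rows", path),
            "cm_empty_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(fields[[1]])
  if (ncols < 2L)
    cm_stop(sprintf("embedding file %s needs an id column plus >= 1 numeric column", path),
            "cm_parse_error")
  ragged <- which(lengths(fields[-1]) != ncols)
  if (length(ragged) > 0L)
    cm_stop(sprintf("ragged row at line %d of %s", ragged[1] + 1L, path),
            "cm_parse_error")
  ids <- vapply(fields[-1], `[`, "", 1L)
  if (anyDuplicated(ids))
    cm_stop(sprintf("duplicate id '%s' in %s", ids[duplicated(ids)][1], path),
            "cm_parse_error")
  vals <- suppressWarnings(
    vapply(fields[-1], function(f) as.numeric(f[-1]), numeric(ncols - 1L)))
  vals <- if (ncols == 2L) matrix(vals, nrow = 1L) else vals
  if (anyNA(vals))
    cm_stop(sprintf("non-numeric cell in %s (row %d)", path,
                    which(apply(is.na(vals), 2, any))[1] + 1L), "cm_parse_error")
  embedding_set(ids, t(vals), modality = modality)
}

#' Reference assembly sets (CORUM / GO-CC style)
#'
#' @param term_id,term_name character vectors.
#' @param members list of character vectors (non-empty, uppercased).
#' @return Object of class `ReferenceSets`: data.frame-backed list with
#'   `terms` (data.frame `term_id`, `term_name`, `size`) and `members`
#'   (named list of character sets).
#' @export
reference_sets <- function(term_id, term_name, members) {
  term_id <- as.character(term_id)
  cm_assert(!anyDuplicated(term_id), "term_ids must be unique")
  members <- lapply(members, function(m) sort(unique(toupper(trimws(m)))))
  cm_assert(all(lengths(members) > 0L), "member sets must be non-empty")
  names(members) <- term_id
  structure(list(terms = data.frame(term_id = term_id,
                                    term_name = as.character(term_name),
                                    size = lengths(members),
                                    stringsAsFactors = FALSE),
                 members = members),
            class = "ReferenceSets")
}

#' @export
print.ReferenceSets <- function(x, ...) {
  cat(sprintf("ReferenceSets: %d terms, %d distinct proteins\n",
              nrow(x$terms), length(unique(unlist(x$members)))))
  invisible(x)
}

#' Read reference assembly sets from TSV
#'
#' Format: `term_id <TAB> term_name <TAB> members`, where members are
#' separated by commas and/or semicolons. Member symbols are uppercased.
#'
#' @param path file path.
#' @return A [reference_sets()] object.
#' @export
read_reference_sets <- function(path) {
  if (!file.exists(path))
    cm_stop(sprintf("reference set file not found: %s", path), "cm_parse_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    cm_stop(sprintf("empty reference set file: %s", path), "cm_empty_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad) > 0L)
    cm_stop(sprintf("malformed reference row at line %d of %s: expected 3 columns",
                    bad[1], path), "cm_parse_error")
  term_id <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(term_id))
    cm_stop(sprintf("duplicate term_id '%s' in %s",
                    term_id[duplicated(term_id)][1], path), "cm_parse_error")
  members <- lapply(fields, function(f) {
    m <- trimws(strsplit(f[3], "[,;]")[[1]])
    m[nzchar(m)]
  })
  empty <- which(lengths(members) == 0L)
  if (length(empty) > 0L)
    cm_stop(sprintf("term '%s' (line %d of %s) has no members",
                    term_id[empty[1]], empty[1], path), "cm_parse_error")
  reference_sets(term_id, vapply(fields, `[`, "", 2L), members)
}

#' Write reference sets TSV (inverse of [read_reference_sets()])
#' @param ref a `ReferenceSets` object.
#' @param path output path.
#' @export
write_reference_sets <- function(ref, path) {
  lines <- vapply(seq_len(nrow(ref$terms)), function(i) {
    paste(ref$terms$term_id[i], ref$terms$term_name[i],
          paste(ref$members[[i]], collapse = ","), sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
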