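#' Per-image feature table
#'
#' One row per image: an image identifier, the protein the image stains,
#' and a fixed-length numeric feature vector (e.g. the penultimate layer
#' of an image-localization classifier, computed upstream).
#'
#' @param image_id character vector, unique.
#' @param protein character vector of protein symbols (uppercased).
#' @param features numeric matrix, one row per image.
#' @return An `ImageFeatureTable` list with `image_id`, `protein`,
#'   `features`.
#' @export
image_feature_table <- function(image_id, protein, features) {
  image_id <- as.character(image_id)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  cm_assert(!anyDuplicated(image_id), "image_ids must be unique")
  cm_assert(nrow(features) == length(image_id) &&
              length(protein) == length(image_id),
            "image_id, protein and feature rows must align")
  cm_assert(all(is.finite(features)), "image features must be finite")
  structure(list(image_id = image_id,
                 protein = toupper(trimws(as.character(protein))),
                 features = features),
            class = "ImageFeatureTable")
}

#' Read an image feature TSV: `image_id <TAB> protein <TAB> f1..fd`
#' (header row required).
#' @param path file path.
#' @return An [image_feature_table()].
#' @export
read_image_features <- function(path) {
  if (!file.exists(path))
    cm_stop(sprintf("image feature file not found: %s", path), "cm_parse_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    cm_stop(sprintf("image feature file %s is empty", path), "cm_empty_error")
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncols <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  if (ncols < 3L)
    cm_stop("image feature table needs image_id, protein and >= 1 feature column",
            "cm_parse_error")
  ragged <- which(lengths(fields) != ncols)
  if (length(ragged) > 0L)
    cm_stop(sprintf("ragged row at line %d of %s", ragged[1] + 1L, path),
            "cm_parse_error")
  feats <- t(vapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f[-(1:2)]))
    v
  }, numeric(ncols - 2L)))
  if (ncols == 3L) feats <- matrix(feats, ncol = 1L)
  if (anyNA(feats)) cm_stop(sprintf("non-numeric feature cell in %s", path),
                            "cm_parse_error")
  image_feature_table(vapply(fields, `[`, "", 1L),
                      vapply(fields, `[`, "", 2L), feats)
}

#' Write an image feature TSV (inverse of [read_image_features()])
#' @param table an `ImageFeatureTable`.
#' @param path output path.
#' @export
write_image_features <- function(table, path) {
  d <- ncol(table$features)
  header <- paste(c("image_id", "protein", paste0("f", seq_len(d))), collapse = "\t")
  body <- vapply(seq_along(table$image_id), function(i) {
    paste(c(table$image_id[i], table$protein[i],
            sprintf("%.17g", table$features[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Aggregate per-image features into one vector per protein
#'
#' Componentwise median (default; robust to off-target staining outliers)
#' or mean across a protein's images. A protein with a single image gets
#' that image's vector verbatim. Aggregation is invariant to image order.
#'
#' @param table an `ImageFeatureTable`.
#' @param method `"median"` or `"mean"`.
#' @return An `EmbeddingSet` with `modality = "image"`, proteins in
#'   sorted order.
#' @export
aggregate_per_protein <- function(table, method = c("median", "mean")) {
  method <- match.arg(method)
  cm_assert(length(table$image_id) > 0, "image feature table is empty")
  proteins <- sort(unique(table$protein))
  agg <- if (method == "mean") colMeans else function(m) apply(m, 2, stats::median)
  vec <- t(vapply(proteins, function(p) {
    rows <- table$features[table$protein == p, , drop = FALSE]
    if (nrow(rows) == 1L) rows[1, ] else agg(rows)
  }, numeric(ncol(table$features))))
  embedding_set(proteins, vec, modality = "image")
}

#' L2-normalize every row of an embedding
#'
#' @param emb an `EmbeddingSet`.
#' @return An `EmbeddingSet` whose rows have unit Euclidean norm.
#' @export
l2_normalize <- function(emb) {
  norms <- sqrt(rowSums(emb$vectors^2))
  zero <- norms == 0
  if (any(zero))
    cm_stop(sprintf("zero vector for protein %s cannot be normalized",
                    emb$ids[zero][1]), "cm_contract_error")
  embedding_set(emb$ids, emb$vectors / norms, modality = emb$modality)
}

#' Image embedding stage: aggregate image features, write stage directory
#'
#' @param table an `ImageFeatureTable` or path to its TSV.
#' @param outdir stage directory.
#' @param agg aggregation method, see [aggregate_per_protein()].
#' @param inputs provenance inputs.
#' @return The `EmbeddingSet`, invisibly.
#' @export
image_embed <- function(table, outdir, agg = "median", inputs = character()) {
  if (is.character(table)) {
    inputs <- unique(c(inputs, table))
    table <- read_image_features(table)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  emb <- aggregate_per_protein(table, method = agg)
  write_embedding_tsv(emb, file.path(outdir, "image_emb.tsv"))
  stage_log(outdir, "image_embedding",
            sprintf("images=%d proteins=%d d=%d agg=%s",
                    length(table$image_id), length(emb$ids), emb$d, agg))
  register_stage(outdir, inputs = inputs, params = list(agg = agg),
                 stage_name = "image_embedding")
  invisible(emb)
}
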