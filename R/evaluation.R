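#' Exact upper-tail hypergeometric probability
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, t, s)`: drawing `s` proteins
#' from a background of `N` of which `t` belong to the term. Computed by
#' direct summation of log-binomial terms (no distribution-function
#' shortcut), so it can be cross-checked against subset enumeration.
#'
#' @param k observed overlap.
#' @param s node (sample) size.
#' @param t term size.
#' @param N background size.
#' @return The tail probability in `(0, 1]`.
#' @export
hypergeom_tail <- function(k, s, t, N) {
  cm_assert(k >= 0 && s >= 0 && t >= 0 && N >= 1, "negative arguments")
  cm_assert(k <= min(s, t), "overlap k cannot exceed min(s, t)")
  cm_assert(s <= N && t <= N, "s and t cannot exceed the background N")
  if (k == 0) return(1)
  i <- seq(k, min(s, t))
  i <- i[s - i <= N - t]   # infeasible terms have zero probability
  if (length(i) == 0L) return(0)
  terms <- lchoose(t, i) + lchoose(N - t, s - i) - lchoose(N, s)
  p <- sum(exp(terms))
  min(max(p, 0), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure: `q_(i) = min_{j >= i} m * p_(j) / j`, returned in
#' the original input order.
#'
#' @param p_list p-values in `(0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_list) {
  m <- length(p_list)
  if (m == 0L) return(numeric(0))
  cm_assert(all(p_list > 0 & p_list <= 1), "p-values must lie in (0, 1]")
  o <- order(p_list)
  q <- p_list[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Annotate hierarchy nodes by reference-set enrichment
#'
#' For every non-root node and reference term, computes the overlap
#' against the co-embedding universe (the DAG root) as background, an
#' exact one-sided hypergeometric p-value, BH q-values across all
#' node-term tests, and the Jaccard between node and term. Each node's
#' best term is the significant term with smallest `(q, -jaccard)`;
#' nodes with no term at `q <= fdr` are labeled `"unannotated"`.
#'
#' @param dag a `HierarchyDAG`.
#' @param reference a `ReferenceSets`.
#' @param fdr significance threshold on BH q-values.
#' @return List with `records` (data.frame of `EnrichmentRecord`s) and
#'   `annotations` (per-node best term).
#' @export
annotate_nodes <- function(dag, reference, fdr = 0.05) {
  cm_assert(nrow(reference$terms) > 0, "reference is empty")
  background <- dag$nodes[[dag$root]]$members
  N <- length(background)
  term_members <- lapply(reference$members, intersect, background)
  if (all(lengths(term_members) == 0L))
    cm_stop("no reference member overlaps the hierarchy background",
            "cm_contract_error")
  node_names <- setdiff(names(dag$nodes), dag$root)
  recs <- list()
  for (nn in node_names) {
    mem <- intersect(dag$nodes[[nn]]$members, background)
    s <- length(mem)
    for (ti in seq_along(term_members)) {
      tm <- term_members[[ti]]
      t_sz <- length(tm)
      if (t_sz == 0L) next
      k <- length(intersect(mem, tm))
      recs[[length(recs) + 1L]] <- data.frame(
        node = nn, term_id = reference$terms$term_id[ti],
        term_name = reference$terms$term_name[ti],
        overlap = k, node_size = s, term_size = t_sz, background = N,
        p_value = hypergeom_tail(k, s, t_sz, N),
        jaccard = k / (s + t_sz - k),
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  records$q_value <- bh_adjust(records$p_value)
  records <- records[, c("node", "term_id", "term_name", "overlap",
                         "node_size", "term_size", "background",
                         "p_value", "q_value", "jaccard")]
  annotations <- do.call(rbind, lapply(node_names, function(nn) {
    sub <- records[records$node == nn & records$q_value <= fdr, ]
    if (nrow(sub) == 0L)
      return(data.frame(node = nn, term_id = "unannotated",
                        term_name = "unannotated", q_value = NA_real_,
                        jaccard = NA_real_, stringsAsFactors = FALSE))
    sub <- sub[order(sub$q_value, -sub$jaccard, sub$term_id), ]
    data.frame(node = nn, term_id = sub$term_id[1],
               term_name = sub$term_name[1], q_value = sub$q_value[1],
               jaccard = sub$jaccard[1], stringsAsFactors = FALSE)
  }))
  list(records = records, annotations = annotations)
}

#' Jackknife robustness of hierarchy nodes
#'
#' Repeatedly drops a fraction of proteins from the co-embedding
#' universe, regenerates the hierarchy with identical parameters and
#' seed, and scores every non-root node of the base DAG by the maximum
#' Jaccard between the node (restricted to retained proteins) and any
#' node of the resampled DAG. A node's robustness is the mean of that
#' score over resamples. With `drop_fraction = 0` the rerun is
#' deterministic and every score is exactly 1.
#'
#' @param emb the co-embedding `EmbeddingSet` the base DAG was built from.
#' @param base_dag the `HierarchyDAG` to score.
#' @param params the [hierarchy_params()] used for the base DAG.
#' @param n_resamples number of jackknife resamples.
#' @param drop_fraction fraction of proteins removed per resample.
#' @param seed base seed; resample `j` drops proteins using `seed + j`
#'   while hierarchy generation reuses the base `seed`.
#' @return A `RobustnessReport`: list with `scores` (data.frame `node`,
#'   `score`) and the resampling parameters.
#' @export
jackknife_robustness <- function(emb, base_dag, params = hierarchy_params(),
                                 n_resamples = 10, drop_fraction = 0.1,
                                 seed = 1) {
  n <- length(emb$ids)
  n_drop <- floor(drop_fraction * n)
  min_viable <- 3 * params$min_size
  if (n - n_drop < min_viable)
    cm_stop(sprintf("resample would retain %d proteins (< %d viable minimum)",
                    n - n_drop, min_viable), "cm_contract_error")
  node_names <- setdiff(names(base_dag$nodes), base_dag$root)
  acc <- matrix(NA_real_, length(node_names), n_resamples,
                dimnames = list(node_names, NULL))
  for (j in seq_len(n_resamples)) {
    set.seed((seed + j) %% .Machine$integer.max)
    retained <- if (n_drop > 0) sort(sample(emb$ids, n - n_drop)) else emb$ids
    sub <- embedding_set(retained, emb$vectors[retained, , drop = FALSE],
                         emb$modality)
    rdag <- hierarchy_from_embedding(sub, params, seed = seed)
    rsets <- lapply(rdag$nodes, `[[`, "members")
    for (nn in node_names) {
      restricted <- intersect(base_dag$nodes[[nn]]$members, retained)
      acc[nn, j] <- if (length(restricted) == 0L) 0 else
        max(vapply(rsets, jaccard, 0.0, b = restricted))
    }
  }
  structure(list(scores = data.frame(node = node_names,
                                     score = rowMeans(acc),
                                     stringsAsFactors = FALSE),
                 n_resamples = n_resamples, drop_fraction = drop_fraction,
                 seed = seed),
            class = "RobustnessReport")
}

#' Export LLM naming requests for hierarchy nodes
#'
#' Writes one JSON record per non-root node (node id, member list, and an
#' empty prompt slot) for an external language-model naming service. No
#' network calls are made here.
#'
#' @param dag a `HierarchyDAG`.
#' @param outpath output JSON path.
#' @return `outpath`, invisibly.
#' @export
export_naming_requests <- function(dag, outpath) {
  node_names <- setdiff(names(dag$nodes), dag$root)
  reqs <- lapply(node_names, function(nn) {
    list(node = nn, members = dag$nodes[[nn]]$members,
         prompt = "", name = NULL, confidence = NULL)
  })
  jsonlite::write_json(reqs, outpath, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(outpath)
}

#' Hierarchy evaluation stage
#'
#' Annotates a hierarchy against reference assemblies and writes
#' `enrichment.tsv`, `node_annotations.tsv` and `naming_requests.json`
#' plus a provenance record.
#'
#' @param hierarchy a `HierarchyDAG` or a stage directory from
#'   [generate_hierarchy()].
#' @param reference a `ReferenceSets` or TSV path.
#' @param outdir stage directory.
#' @param fdr BH significance threshold.
#' @param inputs extra provenance inputs.
#' @return The [annotate_nodes()] result, invisibly.
#' @export
hierarchy_eval <- function(hierarchy, reference, outdir, fdr = 0.05,
                           inputs = character()) {
  if (!inherits(hierarchy, "HierarchyDAG")) {
    inputs <- unique(c(inputs, hierarchy))
    hierarchy <- read_hierarchy(hierarchy)
  }
  if (is.character(reference)) {
    inputs <- unique(c(inputs, reference))
    reference <- read_reference_sets(reference)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- annotate_nodes(hierarchy, reference, fdr = fdr)
  utils::write.table(res$records, file.path(outdir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$annotations, file.path(outdir, "node_annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_naming_requests(hierarchy, file.path(outdir, "naming_requests.json"))
  stage_log(outdir, "hierarchyeval",
            sprintf("nodes=%d terms=%d annotated=%d",
                    length(hierarchy$nodes) - 1L, nrow(reference$terms),
                    sum(res$annotations$term_id != "unannotated")))
  register_stage(outdir, inputs = inputs, params = list(fdr = fdr),
                 stage_name = "hierarchyeval")
  invisible(res)
}
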