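#' Cosine similarity matrix of an embedding
#'
#' @param emb an `EmbeddingSet` (no zero vectors).
#' @return A `SimilarityMatrix`: list with `ids` and the symmetric n x n
#'   `matrix` (entries clamped to `[-1, 1]`, unit diagonal).
#' @export
cosine_matrix <- function(emb) {
  S <- cosine_all_pairs(emb)
  S[S > 1] <- 1; S[S < -1] <- -1
  diag(S) <- 1
  dimnames(S) <- list(emb$ids, emb$ids)
  structure(list(ids = emb$ids, matrix = S), class = "SimilarityMatrix")
}

#' Build a nested stack of thresholded similarity graphs
#'
#' For each edge fraction `f` the graph keeps the top
#' `ceiling(f * n(n-1)/2)` protein pairs by similarity (ties broken by
#' lexicographic id pair), so a stricter cutoff's edge set is contained in
#' every looser one by construction.
#'
#' @param M a `SimilarityMatrix`.
#' @param edge_fractions strictly increasing fractions in `(0, 1]`.
#' @return A `GraphStack`: list with `ids`, `edge_fractions`, `edges`
#'   (one data.frame `from`,`to`,`sim` per fraction) and `cutoffs`
#'   (similarity of the weakest retained edge per level).
#' @export
build_graph_stack <- function(M, edge_fractions = default_edge_fractions()) {
  n <- length(M$ids)
  if (n < 3) cm_stop("similarity matrix must cover at least 3 proteins",
                     "cm_contract_error")
  cm_assert(all(diff(edge_fractions) > 0) && all(edge_fractions > 0) &&
              all(edge_fractions <= 1),
            "edge_fractions must be strictly increasing within (0, 1]")
  ut <- which(upper.tri(M$matrix), arr.ind = TRUE)
  from <- M$ids[ut[, 1]]; to <- M$ids[ut[, 2]]
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  sim <- M$matrix[ut]
  o <- order(-sim, from, to)
  from <- from[o]; to <- to[o]; sim <- sim[o]
  total <- length(sim)
  edges <- lapply(edge_fractions, function(f) {
    k <- min(total, ceiling(f * total))
    data.frame(from = from[seq_len(k)], to = to[seq_len(k)],
               sim = sim[seq_len(k)], stringsAsFactors = FALSE)
  })
  structure(list(ids = M$ids, edge_fractions = edge_fractions, edges = edges,
                 cutoffs = vapply(edges, function(e) min(e$sim), 0.0)),
            class = "GraphStack")
}

#' Default edge-density ladder for the similarity graph stack
#' @return Increasing edge fractions spanning sparse-to-moderate regimes.
#' @export
default_edge_fractions <- function() c(0.002, 0.005, 0.01, 0.02, 0.04, 0.07, 0.10)

#' Default CPM resolution sweep
#' @param n number of log-spaced resolutions in `[1e-3, 10]`.
#' @return Positive numeric vector of length `n`.
#' @export
default_resolutions <- function(n = 20) exp(seq(log(1e-3), log(10), length.out = n))

cpm_quality <- function(g, membership, gamma) {
  el <- igraph::as_edgelist(g, names = FALSE)
  e_in <- sum(membership[el[, 1]] == membership[el[, 2]])
  sizes <- tabulate(membership)
  e_in - gamma * sum(sizes * (sizes - 1) / 2)
}

# Seeded CPM-Leiden with restarts; returns the best membership by CPM
# quality (deterministic: restart seeds derive from `seed`).
leiden_cpm <- function(g, gamma, seed = 1, n_restarts = 3, n_iterations = 5) {
  best <- NULL; best_q <- -Inf
  for (s in seq_len(n_restarts)) {
    set.seed((seed * 97 + s * 1009) %% .Machine$integer.max)
    memb <- igraph::membership(igraph::cluster_leiden(
      g, objective_function = "CPM", resolution = gamma,
      n_iterations = n_iterations))
    q <- cpm_quality(g, memb, gamma)
    if (q > best_q) { best_q <- q; best <- memb }
  }
  structure(as.integer(best), names = igraph::V(g)$name, quality = best_q)
}

#' Pan-resolution community detection over a graph stack
#'
#' Runs resolution-parameterized partitioning (Leiden, constant Potts
#' model objective) at every (threshold graph, resolution) sweep cell and
#' pools every detected member set of size >= `min_size`, tagged with the
#' cell it came from. Cells are ordered resolution-major within each
#' threshold, then across thresholds. Empty graphs are skipped with a
#' message.
#'
#' @param stack a `GraphStack`.
#' @param resolutions positive (log-spaced) resolution sequence.
#' @param min_size minimum community size retained.
#' @param seed integer seed (restart seeds derive from it).
#' @param n_restarts Leiden restarts per cell (best CPM quality kept).
#' @return A `CommunityPool`: list with `pool` (list of entries
#'   `members`, `cell`, `threshold_index`, `resolution`), `n_cells`, and
#'   the sweep layout.
#' @export
detect_communities <- function(stack, resolutions = default_resolutions(),
                               min_size = 4, seed = 1, n_restarts = 3) {
  cm_assert(all(resolutions > 0), "resolutions must be positive")
  pool <- list()
  cell <- 0L
  nr <- length(resolutions)
  for (ti in seq_along(stack$edges)) {
    ed <- stack$edges[[ti]]
    if (nrow(ed) == 0L) {
      message(sprintf("graph at edge fraction %g is empty; skipping %d cells",
                      stack$edge_fractions[ti], nr))
      cell <- cell + nr
      next
    }
    g <- igraph::graph_from_data_frame(ed[, c("from", "to")], directed = FALSE,
                                       vertices = data.frame(name = stack$ids))
    for (ri in seq_along(resolutions)) {
      cell <- cell + 1L
      memb <- leiden_cpm(g, resolutions[ri],
                         seed = (seed * 131 + cell) %% .Machine$integer.max,
                         n_restarts = n_restarts)
      for (cid in unique(memb)) {
        members <- sort(names(memb)[memb == cid])
        if (length(members) < min_size) next
        pool[[length(pool) + 1L]] <- list(members = members, cell = cell,
                                          threshold_index = ti,
                                          resolution = resolutions[ri])
      }
    }
  }
  structure(list(pool = pool,
                 n_cells = length(stack$edges) * nr,
                 edge_fractions = stack$edge_fractions,
                 resolutions = resolutions, min_size = min_size),
            class = "CommunityPool")
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Chain communities across sweep cells and score persistence
#'
#' Communities in consecutive sweep cells are re-identified when their
#' Jaccard overlap is at least `jaccard_tau` (greedy one-to-one matching
#' in decreasing-Jaccard order). A chain's persistence is the number of
#' cells it spans; its representative member set is the largest set in
#' the chain (ties: lexicographically smallest member list). Only chains
#' with persistence >= `rho_min` survive.
#'
#' @param pool a `CommunityPool` from [detect_communities()].
#' @param jaccard_tau re-identification threshold.
#' @param rho_min minimum persistence.
#' @return List of `Community` objects: `members`, `persistence`,
#'   `origin` (`threshold_index`, `resolution` of first detection).
#' @export
compute_persistence <- function(pool, jaccard_tau = 0.75, rho_min = 3) {
  entries <- pool$pool
  if (length(entries) == 0L) return(list())
  cells <- sort(unique(vapply(entries, function(e) e$cell, 0L)))
  chains <- list()   # each: sets (list), cells (int vec), origin
  active <- integer(0)  # indices of chains extendable from the previous cell
  prev_cell <- -1L
  for (cc in cells) {
    cur <- entries[vapply(entries, function(e) e$cell, 0L) == cc]
    eligible <- if (cc == prev_cell + 1L) active else integer(0)
    matched_chain <- integer(0); matched_comm <- integer(0)
    if (length(eligible) > 0L && length(cur) > 0L) {
      jac <- outer(seq_along(eligible), seq_along(cur),
                   Vectorize(function(i, j) {
                     jaccard(chains[[eligible[i]]]$last, cur[[j]]$members)
                   }))
      repeat {
        best <- which(jac == max(jac), arr.ind = TRUE)
        if (length(best) == 0L || max(jac) < jaccard_tau) break
        i <- best[1, 1]; j <- best[1, 2]
        ci <- eligible[i]
        chains[[ci]]$sets[[length(chains[[ci]]$sets) + 1L]] <- cur[[j]]$members
        chains[[ci]]$cells <- c(chains[[ci]]$cells, cc)
        chains[[ci]]$last <- cur[[j]]$members
        matched_chain <- c(matched_chain, ci)
        matched_comm <- c(matched_comm, j)
        jac[i, ] <- -1; jac[, j] <- -1
      }
    }
    for (j in setdiff(seq_along(cur), matched_comm)) {
      chains[[length(chains) + 1L]] <- list(
        sets = list(cur[[j]]$members), cells = cc, last = cur[[j]]$members,
        origin = list(threshold_index = cur[[j]]$threshold_index,
                      resolution = cur[[j]]$resolution))
      matched_chain <- c(matched_chain, length(chains))
    }
    active <- matched_chain
    prev_cell <- cc
  }
  out <- list()
  for (ch in chains) {
    if (length(ch$cells) < rho_min) next
    sizes <- lengths(ch$sets)
    cand <- which(sizes == max(sizes))
    if (length(cand) > 1L) {
      keys <- vapply(ch$sets[cand], function(s) paste(s, collapse = " "), "")
      cand <- cand[order(keys)][1]
    }
    out[[length(out) + 1L]] <- structure(
      list(members = ch$sets[[cand[1]]], persistence = length(ch$cells),
           origin = ch$origin),
      class = "Community")
  }
  out
}

#' Containment index of a child set within a parent set
#'
#' `|child intersect parent| / |child|`: 1 when the child is fully inside
#' the parent, 0 when disjoint.
#'
#' @param child,parent non-empty character vectors.
#' @return A single real in `[0, 1]`.
#' @export
containment_index <- function(child, parent) {
  cm_assert(length(child) > 0 && length(parent) > 0,
            "containment_index requires non-empty sets")
  length(intersect(child, parent)) / length(unique(child))
}

#' Deduplicate near-identical communities
#'
#' Greedy: communities ordered by persistence (desc), then size (desc),
#' then lexicographic members; a community is kept only if its Jaccard
#' with every already-kept community is below `dedupe_tau`.
#'
#' @param communities list of `Community`.
#' @param dedupe_tau Jaccard threshold.
#' @return Filtered list.
#' @export
dedupe_communities <- function(communities, dedupe_tau = 0.9) {
  if (length(communities) == 0L) return(communities)
  pers <- vapply(communities, function(c) as.numeric(c$persistence), 0.0)
  sz <- vapply(communities, function(c) length(c$members), 0L)
  keys <- vapply(communities, function(c) paste(c$members, collapse = " "), "")
  o <- order(-pers, -sz, keys)
  kept <- list()
  for (i in o) {
    dup <- any(vapply(kept, function(k) {
      jaccard(k$members, communities[[i]]$members) >= dedupe_tau
    }, TRUE))
    if (!dup) kept[[length(kept) + 1L]] <- communities[[i]]
  }
  kept
}

#' Assemble communities into a containment DAG
#'
#' Parent candidates of a community are the strictly larger communities
#' containing at least `theta_c` of its members; only minimal candidates
#' are kept as parents (no grandparent shortcut edges). Communities with
#' no parent attach to a synthetic root holding the full protein
#' universe.
#'
#' @param communities deduplicated list of `Community`.
#' @param theta_c containment threshold for parent links.
#' @param universe protein universe for the root (defaults to the union
#'   of all community members).
#' @return A `HierarchyDAG`: list with `nodes` (named list: `members`,
#'   `size`, `persistence`), `edges` (data.frame `parent`, `child`),
#'   `root` (= `"ROOT"`).
#' @export
build_dag <- function(communities, theta_c = 0.75, universe = NULL) {
  universe <- sort(unique(c(universe, unlist(lapply(communities, `[[`, "members")))))
  sz <- vapply(communities, function(c) length(c$members), 0L)
  keys <- vapply(communities, function(c) paste(c$members, collapse = " "), "")
  o <- order(-sz, keys)
  communities <- communities[o]; sz <- sz[o]
  nms <- if (length(communities)) paste0("C", seq_along(communities)) else character(0)

  nodes <- list(ROOT = list(members = universe, size = length(universe),
                            persistence = NA_integer_))
  for (i in seq_along(communities))
    nodes[[nms[i]]] <- list(members = communities[[i]]$members,
                            size = sz[i],
                            persistence = communities[[i]]$persistence)

  parent_edges <- list()
  for (i in seq_along(communities)) {
    cand <- which(sz > sz[i])
    cand <- cand[vapply(cand, function(j) {
      containment_index(communities[[i]]$members, communities[[j]]$members) >= theta_c
    }, TRUE)]
    # minimal parents: drop any candidate that contains another candidate
    if (length(cand) > 1L) {
      minimal <- vapply(cand, function(j) {
        !any(vapply(cand, function(k) {
          k != j && sz[k] < sz[j] &&
            containment_index(communities[[k]]$members,
                              communities[[j]]$members) >= theta_c
        }, TRUE))
      }, TRUE)
      cand <- cand[minimal]
    }
    parents <- if (length(cand) == 0L) "ROOT" else nms[cand]
    for (p in parents)
      parent_edges[[length(parent_edges) + 1L]] <- c(p, nms[i])
  }
  edges <- if (length(parent_edges)) {
    m <- do.call(rbind, parent_edges)
    data.frame(parent = m[, 1], child = m[, 2], stringsAsFactors = FALSE)
  } else data.frame(parent = character(), child = character(),
                    stringsAsFactors = FALSE)
  dag <- structure(list(nodes = nodes, edges = edges, root = "ROOT"),
                   class = "HierarchyDAG")
  cm_assert(dag_is_acyclic(dag), "internal error: containment DAG has a cycle")
  dag
}

dag_is_acyclic <- function(dag) {
  if (nrow(dag$edges) == 0L) return(TRUE)
  g <- igraph::graph_from_data_frame(dag$edges, directed = TRUE)
  igraph::is_dag(g)
}

#' @export
print.HierarchyDAG <- function(x, ...) {
  cat(sprintf("HierarchyDAG: %d assemblies under root (%d proteins), %d edges\n",
              length(x$nodes) - 1L, x$nodes$ROOT$size, nrow(x$edges)))
  invisible(x)
}

dag_children <- function(dag, node) dag$edges$child[dag$edges$parent == node]

# Unroll the DAG to a tree. A node reachable through several parents is
# emitted once per parent; occurrences after the first are flagged
# `duplicate` and not expanded further (global visited set).
dag_to_tree <- function(dag, node = dag$root, visited = new.env()) {
  dup <- isTRUE(visited[[node]])
  rec <- list(name = node, size = dag$nodes[[node]]$size,
              persistence = dag$nodes[[node]]$persistence)
  if (dup) {
    rec$duplicate <- TRUE
  } else {
    visited[[node]] <- TRUE
    kids <- sort(dag_children(dag, node))
    if (length(kids) > 0)
      rec$children <- lapply(kids, function(k) dag_to_tree(dag, k, visited))
  }
  rec
}

#' Write a hierarchy DAG to a stage directory
#'
#' Writes `hierarchy_edges.tsv` (`parent`, `child`, `relation`),
#' `hierarchy_nodes.tsv` (`name`, `size`, `persistence`,
#' space-separated `members`) and `hierarchy.json` (the DAG unrolled to a
#' tree; a node reachable through several parents appears once per
#' parent, flagged `"duplicate": true` after its first occurrence).
#'
#' @param dag a `HierarchyDAG`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_hierarchy <- function(dag, outdir) {
  cm_assert(dag_is_acyclic(dag), "refusing to serialize a cyclic hierarchy")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ed <- dag$edges
  writeLines(c("parent\tchild\trelation",
               if (nrow(ed)) paste(ed$parent, ed$child, "contains", sep = "\t")),
             file.path(outdir, "hierarchy_edges.tsv"))
  nms <- names(dag$nodes)
  writeLines(c("name\tsize\tpersistence\tmembers",
               vapply(nms, function(nm) {
                 nd <- dag$nodes[[nm]]
                 paste(nm, nd$size,
                       ifelse(is.na(nd$persistence), 0L, nd$persistence),
                       paste(nd$members, collapse = " "), sep = "\t")
               }, "")),
             file.path(outdir, "hierarchy_nodes.tsv"))
  jsonlite::write_json(dag_to_tree(dag), file.path(outdir, "hierarchy.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Read a hierarchy back from [write_hierarchy()] output
#' @param dir directory holding `hierarchy_nodes.tsv` / `hierarchy_edges.tsv`.
#' @return A `HierarchyDAG`.
#' @export
read_hierarchy <- function(dir) {
  nl <- readLines(file.path(dir, "hierarchy_nodes.tsv"))[-1]
  nodes <- list()
  for (ln in nl) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    nodes[[f[1]]] <- list(members = sort(strsplit(f[4], " ", fixed = TRUE)[[1]]),
                          size = as.integer(f[2]),
                          persistence = as.integer(f[3]))
  }
  el <- readLines(file.path(dir, "hierarchy_edges.tsv"))[-1]
  edges <- if (length(el)) {
    m <- do.call(rbind, strsplit(el, "\t", fixed = TRUE))
    data.frame(parent = m[, 1], child = m[, 2], stringsAsFactors = FALSE)
  } else data.frame(parent = character(), child = character())
  structure(list(nodes = nodes, edges = edges, root = "ROOT"),
            class = "HierarchyDAG")
}

#' Default hierarchy-generation parameters
#'
#' @param edge_fractions density ladder, see [build_graph_stack()].
#' @param n_resolutions number of log-spaced CPM resolutions.
#' @param min_size minimum community size.
#' @param jaccard_tau persistence re-identification threshold.
#' @param rho_min minimum persistence.
#' @param dedupe_tau near-duplicate Jaccard threshold.
#' @param theta_c containment threshold for DAG parent links.
#' @param n_restarts Leiden restarts per sweep cell.
#' @return A parameter list consumed by [generate_hierarchy()].
#' @export
hierarchy_params <- function(edge_fractions = default_edge_fractions(),
                             n_resolutions = 20, min_size = 4,
                             jaccard_tau = 0.75, rho_min = 3,
                             dedupe_tau = 0.9, theta_c = 0.75,
                             n_restarts = 3) {
  list(edge_fractions = edge_fractions,
       resolutions = default_resolutions(n_resolutions),
       min_size = min_size, jaccard_tau = jaccard_tau, rho_min = rho_min,
       dedupe_tau = dedupe_tau, theta_c = theta_c, n_restarts = n_restarts)
}

# Core hierarchy computation from an embedding (no I/O): similarity ->
# graph stack -> community pool -> persistence -> containment DAG.
hierarchy_from_embedding <- function(emb, params = hierarchy_params(), seed = 1) {
  M <- cosine_matrix(emb)
  stack <- build_graph_stack(M, params$edge_fractions)
  pool <- detect_communities(stack, params$resolutions,
                             min_size = params$min_size, seed = seed,
                             n_restarts = params$n_restarts)
  comms <- compute_persistence(pool, params$jaccard_tau, params$rho_min)
  comms <- dedupe_communities(comms, params$dedupe_tau)
  build_dag(comms, theta_c = params$theta_c, universe = emb$ids)
}

#' Hierarchy generation stage
#'
#' @param input an `EmbeddingSet`, a co-embedding TSV path, or a stage
#'   directory containing one.
#' @param outdir stage directory.
#' @param params a [hierarchy_params()] list.
#' @param seed integer seed.
#' @param inputs extra provenance inputs.
#' @return The `HierarchyDAG`, invisibly.
#' @export
generate_hierarchy <- function(input, outdir, params = hierarchy_params(),
                               seed = 1, inputs = character()) {
  if (!inherits(input, "EmbeddingSet")) {
    f <- find_embedding_file(input, "coembedding")
    inputs <- unique(c(inputs, if (dir.exists(input)) input else f))
    input <- read_embedding_tsv(f, "coembedding")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dag <- hierarchy_from_embedding(input, params, seed)
  write_hierarchy(dag, outdir)
  stage_log(outdir, "hierarchy",
            sprintf("proteins=%d assemblies=%d edges=%d",
                    length(input$ids), length(dag$nodes) - 1L, nrow(dag$edges)))
  flat <- params; flat$edge_fractions <- paste(flat$edge_fractions, collapse = ",")
  flat$resolutions <- sprintf("%d log-spaced in [%g, %g]",
                              length(params$resolutions),
                              min(params$resolutions), max(params$resolutions))
  register_stage(outdir, inputs = inputs, params = c(flat, seed = seed),
                 stage_name = "hierarchy")
  invisible(dag)
}
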