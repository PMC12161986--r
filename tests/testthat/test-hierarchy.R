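test_that("cosine matrix closed forms", {
  emb <- embedding_set(c("A", "B", "C", "D"),
                       rbind(c(1, 1), c(2, 2), c(1, 0), c(0, 3)))
  M <- cosine_matrix(emb)$matrix
  expect_equal(M["A", "B"], 1)
  expect_equal(M["C", "D"], 0)
  expect_equal(M["A", "C"], 1 / sqrt(2), tolerance = 1e-8)
  expect_true(isSymmetric(M))
  expect_equal(unname(diag(M)), rep(1, 4))
  expect_error(cosine_matrix(embedding_set("A", matrix(0, 1, 2))),
               class = "cm_contract_error")
})

test_that("graph stack keeps top pairs and nests across fractions", {
  emb <- rand_embedding(4, 3, 1)
  M <- cosine_matrix(emb)
  st <- build_graph_stack(M, 1.0)
  expect_equal(nrow(st$edges[[1]]), 6L)

  # a clear top pair survives the tightest cut
  M2 <- cosine_matrix(embedding_set(c("A", "B", "C", "D"),
                                    rbind(c(1, 0), c(1, 0.01),
                                          c(0, 1), c(0.6, 0.6))))
  st2 <- build_graph_stack(M2, 1 / 6)
  expect_equal(nrow(st2$edges[[1]]), 1L)
  expect_equal(st2$edges[[1]]$from, "A")
  expect_equal(st2$edges[[1]]$to, "B")

  # nesting on a random matrix
  M3 <- cosine_matrix(rand_embedding(20, 5, 3))
  st3 <- build_graph_stack(M3, c(0.05, 0.10, 0.25))
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(st3$edges[[1]]) %in% key(st3$edges[[2]])))
  expect_true(all(key(st3$edges[[2]]) %in% key(st3$edges[[3]])))

  expect_error(build_graph_stack(cosine_matrix(rand_embedding(2, 3, 1))),
               class = "cm_contract_error")
  expect_error(build_graph_stack(M3, c(0.2, 0.1)), class = "cm_contract_error")
})

test_that("community detection finds planted cliques and obeys min_size", {
  net <- two_clique_net(5, bridge = TRUE)
  emb_ids <- net$nodes
  # build the graph stack directly from the clique structure via similarity 1/0
  S <- matrix(0, 10, 10, dimnames = list(emb_ids, emb_ids))
  S[cbind(net$edges$from, net$edges$to)] <- 1
  S <- pmax(S, t(S)); diag(S) <- 1
  M <- structure(list(ids = emb_ids, matrix = S), class = "SimilarityMatrix")
  st <- build_graph_stack(M, 21 / 45)   # keep exactly the 21 true edges
  pool <- detect_communities(st, resolutions = 0.5, min_size = 4, seed = 1)
  sets <- lapply(pool$pool, `[[`, "members")
  expect_true(any(vapply(sets, identical, TRUE, sort(paste0("X", 1:5)))))
  expect_true(any(vapply(sets, identical, TRUE, sort(paste0("Y", 1:5)))))

  # complete graph at the lowest resolution: one all-node community
  Mc <- structure(list(ids = emb_ids,
                       matrix = matrix(1, 10, 10,
                                       dimnames = list(emb_ids, emb_ids))),
                  class = "SimilarityMatrix")
  stc <- build_graph_stack(Mc, 1)
  poolc <- detect_communities(stc, resolutions = 1e-3, min_size = 4, seed = 1)
  expect_length(poolc$pool, 1L)
  expect_length(poolc$pool[[1]]$members, 10L)

  # a triangle community is suppressed by min_size = 4
  tri <- interaction_network(data.frame(from = c("A", "A", "B"),
                                        to = c("B", "C", "C")))
  St <- matrix(0, 3, 3, dimnames = list(tri$nodes, tri$nodes))
  St[cbind(tri$edges$from, tri$edges$to)] <- 1
  St <- pmax(St, t(St)); diag(St) <- 1
  Mt <- structure(list(ids = tri$nodes, matrix = St), class = "SimilarityMatrix")
  poolt <- detect_communities(build_graph_stack(Mt, 1), resolutions = 0.5,
                              min_size = 4, seed = 1)
  expect_length(poolt$pool, 0L)
})

test_that("persistence chains follow the Jaccard rule", {
  s <- sort(c("A", "B", "C", "D", "E"))
  pool5 <- pool_from_cells(rep(list(list(s)), 5))
  out <- compute_persistence(pool5, jaccard_tau = 0.75, rho_min = 1)
  expect_length(out, 1L)
  expect_equal(out[[1]]$persistence, 5L)
  expect_equal(out[[1]]$members, s)

  # {A..J} vs {A..I,K}: Jaccard 9/11 >= 0.75 -> same chain
  s1 <- LETTERS[1:10]; s2 <- c(LETTERS[1:9], "K")
  out2 <- compute_persistence(pool_from_cells(list(list(s1), list(s2))),
                              jaccard_tau = 0.75, rho_min = 1)
  expect_length(out2, 1L)
  expect_equal(out2[[1]]$persistence, 2L)

  # short chain dropped by rho_min
  out3 <- compute_persistence(pool_from_cells(list(list(s1), list(s1))),
                              jaccard_tau = 0.75, rho_min = 3)
  expect_length(out3, 0L)

  # dissimilar sets stay separate chains
  out4 <- compute_persistence(pool_from_cells(list(list(s1), list(LETTERS[11:20]))),
                              jaccard_tau = 0.75, rho_min = 1)
  expect_length(out4, 2L)
})

test_that("containment index closed forms", {
  expect_equal(containment_index(c("A", "B"), LETTERS[1:5]), 1.0)
  expect_equal(containment_index(c("A", "B"), c("X", "Y")), 0.0)
  expect_equal(containment_index(c("A", "B", "C", "D"),
                                 c("A", "B", "C", "X")), 0.75)
  expect_error(containment_index(character(), "A"),
               class = "cm_contract_error")
})

test_that("DAG assembly: chains, disjoint roots, minimal parents", {
  d1 <- dag_from_sets(list(LETTERS[1:8], LETTERS[1:4], c("A", "B")))
  expect_equal(sort(d1$edges$parent), c("C1", "C2", "ROOT"))
  expect_equal(d1$edges$child[d1$edges$parent == "C1"], "C2")
  expect_equal(d1$edges$child[d1$edges$parent == "C2"], "C3")

  d2 <- dag_from_sets(list(LETTERS[1:4], LETTERS[5:8]))
  expect_equal(d2$edges$parent, c("ROOT", "ROOT"))

  # {A,B,C} under both {A..F} and {A,B,C,D}: only the minimal parent kept
  d3 <- dag_from_sets(list(LETTERS[1:6], LETTERS[1:4], LETTERS[1:3]))
  expect_equal(d3$edges$parent[d3$edges$child == "C3"], "C2")

  # multi-parent: child contained >= theta in two incomparable parents
  d4 <- dag_from_sets(list(c("A", "B", "C", "D", "E"),
                           c("A", "B", "C", "D", "F"),
                           c("A", "B", "C", "D")))
  expect_equal(sort(d4$edges$parent[d4$edges$child == "C3"]), c("C1", "C2"))
  expect_true(cellmapr:::dag_is_acyclic(d4))
})

test_that("near-duplicate communities are deduplicated", {
  mk <- function(members, pers) structure(
    list(members = sort(members), persistence = pers,
         origin = list(threshold_index = 1L, resolution = 1)),
    class = "Community")
  comms <- list(mk(LETTERS[1:10], 5), mk(LETTERS[1:9], 2), mk(LETTERS[15:20], 3))
  kept <- dedupe_communities(comms, dedupe_tau = 0.9)
  expect_length(kept, 2L)
  expect_equal(kept[[1]]$persistence, 5L)   # higher persistence wins
})

test_that("hierarchy serialization round trips and flags multi-parent nodes", {
  d <- withr::local_tempdir()
  dag <- dag_from_sets(list(LETTERS[1:8], LETTERS[1:4], c("A", "B")))
  write_hierarchy(dag, d)
  edges <- read.delim(file.path(d, "hierarchy_edges.tsv"))
  expect_equal(nrow(edges), 3L)
  back <- read_hierarchy(d)
  expect_identical(lapply(back$nodes, `[[`, "members"),
                   lapply(dag$nodes, `[[`, "members"))

  dag4 <- dag_from_sets(list(c("A", "B", "C", "D", "E"),
                             c("A", "B", "C", "D", "F"),
                             c("A", "B", "C", "D")))
  write_hierarchy(dag4, d)
  js <- jsonlite::read_json(file.path(d, "hierarchy.json"))
  txt <- jsonlite::toJSON(js)
  expect_equal(length(gregexpr("\"C3\"", txt)[[1]]), 2L)
  expect_true(grepl("duplicate", txt))
})

test_that("hierarchy generation is deterministic under a fixed seed", {
  set.seed(31)
  X <- matrix(rnorm(40 * 8), 40, 8) +
    kronecker(diag(4)[rep(1:4, each = 10), ] * 4, matrix(1, 1, 2))
  emb <- embedding_set(sprintf("P%02d", 1:40), X, "coembedding")
  hp <- hierarchy_params(edge_fractions = c(0.05, 0.1, 0.2), n_resolutions = 6)
  d1 <- cellmapr:::hierarchy_from_embedding(emb, hp, seed = 7)
  d2 <- cellmapr:::hierarchy_from_embedding(emb, hp, seed = 7)
  expect_identical(lapply(d1$nodes, `[[`, "members"),
                   lapply(d2$nodes, `[[`, "members"))
  expect_identical(d1$edges, d2$edges)
  # all communities live inside the universe; root covers everything
  expect_true(all(unlist(lapply(d1$nodes, `[[`, "members")) %in% emb$ids))
  expect_setequal(d1$nodes$ROOT$members, emb$ids)
})
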