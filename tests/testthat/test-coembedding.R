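test_that("align_universes intersects, sorts and errors on disjoint ids", {
  ea <- rand_embedding(3, 4, 1)            # P001..P003
  eb <- embedding_set(c("P002", "P003", "P004"), matrix(rnorm(9), 3, 3))
  al <- align_universes(ea, eb)
  expect_identical(al[[1]]$ids, c("P002", "P003"))
  expect_identical(al[[2]]$ids, c("P002", "P003"))

  same <- align_universes(ea, ea)
  expect_identical(same[[1]]$ids, sort(ea$ids))

  ec <- rand_embedding(3, 4, 2, prefix = "Q")
  expect_error(align_universes(ea, ec), "3", class = "cm_contract_error")
})

test_that("identity task with linear capacity drives the loss down", {
  set.seed(11)
  X <- matrix(rnorm(30 * 6), 30, 6)
  emb <- embedding_set(sprintf("P%02d", 1:30), X)
  res <- fit_coembedding(emb, embedding_set(emb$ids, X, "image"),
                         coembed_config(latent_dim = 6, hidden_dim = 32,
                                        epochs = 120, alignment_weight = 0,
                                        seed = 4))
  expect_lt(tail(res$loss, 1), res$loss[1])
  expect_true(all(is.finite(res$loss)))
  expect_equal(res$embedding$d, 6L)
  # loss non-increasing on a 5-epoch smoothed window
  sm <- stats::filter(res$loss, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 1e-3))
})

test_that("two proteins with k = 2 degenerate to pure reconstruction", {
  emb <- rand_embedding(2, 5, 3)
  expect_no_error({
    res <- fit_coembedding(emb, rand_embedding(2, 4, 4),
                           coembed_config(latent_dim = 2, hidden_dim = 8,
                                          epochs = 20, pseudo_label_k = 2,
                                          seed = 1))
  })
  expect_true(all(res$loss_parts$triplet == 0))
})

test_that("co-embedding is deterministic given the seed", {
  ea <- rand_embedding(20, 6, 5)
  eb <- rand_embedding(20, 4, 6)
  cfg <- coembed_config(latent_dim = 4, hidden_dim = 16, epochs = 30, seed = 9)
  r1 <- fit_coembedding(ea, eb, cfg)
  r2 <- fit_coembedding(ea, eb, cfg)
  expect_identical(r1$embedding$vectors, r2$embedding$vectors)
  expect_identical(r1$loss, r2$loss)
})

test_that("duplicated modality with no alignment preserves the 5-NN graph", {
  set.seed(5)
  X <- matrix(rnorm(60 * 16), 60, 16) +
    kronecker(matrix(rnorm(3 * 16, sd = 3), 3, 16), matrix(1, 20, 1))
  ids <- sprintf("P%02d", 1:60)
  emb <- embedding_set(ids, X)
  res <- fit_coembedding(emb, embedding_set(ids, X, "image"),
                         coembed_config(latent_dim = 16, hidden_dim = 128,
                                        epochs = 600, alignment_weight = 0,
                                        patience = 1000, seed = 2))
  knn <- function(V) {
    S <- cosine_matrix(embedding_set(ids, V))$matrix
    diag(S) <- -2
    apply(S, 1, function(r) order(r, decreasing = TRUE)[1:5])
  }
  k_in <- knn(cellmapr:::zscore_columns(X))
  k_out <- knn(res$embedding$vectors)
  agreement <- mean(vapply(seq_along(ids), function(i)
    length(intersect(k_in[, i], k_out[, i])) / 5, 0.0))
  expect_gte(agreement, 0.8)
})

test_that("unified space recovers assembly structure beyond the compartment modality", {
  cfg <- planted_config("demo150", complementary = TRUE)
  pl <- sample_planted(cfg, seed = 10)
  net <- sample_ppi(pl, seed = 11)
  tf <- withr::local_tempfile(); write_edge_list(net, tf)
  net <- read_edge_list(tf, min_score = 0.7)
  imgs <- sample_image_features(pl, seed = 12)
  corp <- generate_walks(net, r = 10, l = 40, seed = 1)
  eppi <- suppressMessages(
    train_skipgram(corp, skipgram_config(dimension = 64, epochs = 3, seed = 1)))
  eimg <- aggregate_per_protein(imgs)
  al <- align_universes(eppi, eimg)
  res <- fit_coembedding(al[[1]], al[[2]],
                         coembed_config(latent_dim = 64, hidden_dim = 256,
                                        epochs = 250, seed = 1))
  ids <- res$ids
  a <- pl$assembly_of[ids]
  within_assembly_mean <- function(V) {
    S <- cosine_matrix(embedding_set(ids, V))$matrix
    ut <- upper.tri(S)
    mean(S[ut][outer(a, a, "==")[ut]])
  }
  # modality A = image features (compartment signal only), z-scored as trained
  expect_gt(within_assembly_mean(res$embedding$vectors),
            within_assembly_mean(cellmapr:::zscore_columns(al[[2]]$vectors)))
})

test_that("pair-similarity evaluation matches closed-form cases", {
  # block embedding: within-term pairs at cosine 1, across at 0
  ids <- c("A", "B", "C", "D")
  V <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  emb <- embedding_set(ids, V)
  ref <- reference_sets(c("T1", "T2"), c("t", "t"),
                        list(c("A", "B"), c("C", "D")))
  ev <- evaluate_pair_similarity(emb, ref)
  expect_equal(ev$deciles$co_complex_fraction[10], 1.0)
  expect_equal(ev$n_within, 2L)

  # single 2-member term: exactly that one within pair
  ref1 <- reference_sets("T1", "t", list(c("A", "C")))
  ev1 <- evaluate_pair_similarity(emb, ref1)
  expect_equal(ev1$n_within, 1L)
  expect_equal(unname(ev1$within_pairs[1, ]), c("A", "C"))

  expect_error(evaluate_pair_similarity(emb, reference_sets("T", "t",
                                                            list("Z"))),
               class = "cm_contract_error")
})

test_that("random embeddings show no decile enrichment (3 sigma)", {
  set.seed(12)
  emb <- rand_embedding(120, 20, 12, prefix = "R")
  terms <- lapply(1:12, function(i) sample(emb$ids, 10))
  ref <- reference_sets(paste0("T", 1:12), paste0("T", 1:12), terms)
  ev <- evaluate_pair_similarity(emb, ref)
  p0 <- ev$n_within / ev$n_pairs
  tol3 <- 3 * sqrt(p0 * (1 - p0) / ev$deciles$n_pairs)
  expect_true(all(abs(ev$deciles$co_complex_fraction - p0) <= tol3))
  expect_lt(abs(ev$rank_sum_z), 3)
})

test_that("2-D projection separates clusters, is deterministic, needs n >= 10", {
  set.seed(8)
  centers <- matrix(rnorm(3 * 12, sd = 6), 3, 12)
  X <- centers[rep(1:3, each = 50), ] + matrix(rnorm(150 * 12), 150, 12)
  emb <- embedding_set(sprintf("G%03d", 1:150), X)
  xy <- project_2d(emb, seed = 1)
  expect_true(all(is.finite(xy)))
  cl <- rep(1:3, each = 50)
  cents <- rbind(colMeans(xy[cl == 1, ]), colMeans(xy[cl == 2, ]),
                 colMeans(xy[cl == 3, ]))
  intra <- mean(sqrt(rowSums((xy - cents[cl, ])^2)))
  inter <- mean(dist(cents))
  expect_gt(inter, intra)
  expect_identical(xy, project_2d(emb, seed = 1))
  expect_error(project_2d(rand_embedding(5, 4, 1)), class = "cm_contract_error")
})

test_that("coembed stage integrates two stage directories", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  ea <- rand_embedding(15, 6, 21); eb <- rand_embedding(15, 5, 22)
  write_embedding_tsv(ea, file.path(d1, "ppi_emb.tsv"))
  write_embedding_tsv(eb, file.path(d2, "image_emb.tsv"))
  res <- coembed(d1, d2, d3, coembed_config(latent_dim = 4, hidden_dim = 16,
                                            epochs = 25, seed = 2))
  expect_true(validate_stage(d3)$valid)
  out <- read_embedding_tsv(file.path(d3, "coembedding.tsv"), "coembedding")
  expect_equal(out$d, 4L)
  expect_equal(unname(sqrt(rowSums(out$vectors^2))), rep(1, 15),
               tolerance = 1e-12)
})
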