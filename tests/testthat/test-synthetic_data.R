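test_that("demo600 plants 3 compartments of 200 and refines cleanly", {
  pl <- sample_planted(planted_config("demo600"), seed = 1)
  expect_length(pl$proteins, 600L)
  expect_equal(unname(lengths(pl$compartments)), rep(200L, 3))
  expect_length(pl$assemblies, 24L)
  expect_true(all(lengths(pl$assemblies) >= 15 & lengths(pl$assemblies) <= 35))
  # refinement: every assembly sits inside exactly one compartment
  for (an in names(pl$assemblies)) {
    comps <- unique(pl$compartment_of[pl$assemblies[[an]]])
    expect_length(comps, 1L)
  }
  # every protein belongs to exactly one deepest unit
  expect_false(anyNA(pl$assembly_of))
  expect_identical(sample_planted(planted_config("demo600"), seed = 1)[
    c("compartments", "assemblies")],
    pl[c("compartments", "assemblies")])
})

test_that("planted refinement holds for custom and subcomplex configs", {
  cfg <- planted_config("custom", n = 30, n_compartments = 3,
                        assemblies_per_compartment = 1,
                        assembly_size = c(10, 10), image_dim = 8)
  pl <- sample_planted(cfg, seed = 2)
  expect_equal(unname(lengths(pl$assemblies)), rep(10L, 3))

  cfgs <- planted_config("custom", n = 60, n_compartments = 2,
                         assemblies_per_compartment = 2,
                         assembly_size = c(12, 18), subcomplexes = TRUE,
                         image_dim = 8)
  pls <- sample_planted(cfgs, seed = 3)
  expect_gt(length(pls$subcomplexes), 0L)
  for (sn in names(pls$subcomplexes)) {
    assy <- unique(pls$assembly_of[pls$subcomplexes[[sn]]])
    expect_length(assy, 1L)
  }

  expect_error(sample_planted(planted_config("custom", n = 20,
                                             assemblies_per_compartment = 8,
                                             image_dim = 8), seed = 1),
               class = "cm_contract_error")
})

test_that("planted PPI edges respect depth probabilities and score bands", {
  cfg <- planted_config("demo150")
  pl <- sample_planted(cfg, seed = 5)
  net <- sample_ppi(pl, seed = 6)
  samecomp <- pl$compartment_of[net$edges$from] == pl$compartment_of[net$edges$to]
  expect_true(all(net$edges$score[samecomp] >= 0.7))
  expect_true(all(net$edges$score[!samecomp] < 0.7))

  # p_bg = 0: no cross-compartment edges at all
  net0 <- sample_ppi(pl, p_bg = 0, p_comp = 0.01, seed = 7)
  same0 <- pl$compartment_of[net0$edges$from] == pl$compartment_of[net0$edges$to]
  expect_true(all(same0))

  # p_sub = 1 with subcomplexes: subcomplexes become cliques
  cfgs <- planted_config("custom", n = 48, n_compartments = 2,
                         assemblies_per_compartment = 2,
                         assembly_size = c(12, 12), subcomplexes = TRUE,
                         image_dim = 8)
  pls <- sample_planted(cfgs, seed = 8)
  nets <- sample_ppi(pls, p_sub = 1, seed = 9)
  keys <- paste(nets$edges$from, nets$edges$to)
  for (sn in names(pls$subcomplexes)) {
    m <- pls$subcomplexes[[sn]]
    prs <- t(utils::combn(sort(m), 2))
    expect_true(all(paste(prs[, 1], prs[, 2]) %in% keys))
  }
})

test_that("within-assembly edge counts match the binomial expectation (3 sigma)", {
  cfg <- planted_config("demo150")
  pl <- sample_planted(cfg, seed = 11)
  trials <- sum(vapply(pl$assemblies, function(a) choose(length(a), 2), 0.0))
  tot <- 0
  nseeds <- 20
  for (s in 1:nseeds) {
    net <- sample_ppi(pl, seed = 100 + s)
    sameassy <- pl$assembly_of[net$edges$from] == pl$assembly_of[net$edges$to]
    tot <- tot + sum(sameassy)
  }
  expct <- nseeds * trials * cfg$p_assy
  tol3 <- 3 * sqrt(nseeds * trials * cfg$p_assy * (1 - cfg$p_assy))
  expect_lt(abs(tot - expct), tol3)
})

test_that("image features encode compartments with controllable noise", {
  cfg <- planted_config("demo150")
  pl <- sample_planted(cfg, seed = 3)
  # zero noise: all of a protein's images identical
  im0 <- sample_image_features(pl, noise_sd = 0, seed = 4)
  p1 <- im0$features[im0$protein == pl$proteins[1], , drop = FALSE]
  expect_equal(p1[1, ], p1[2, ])
  # nearest-centroid on noiseless means is perfect; accuracy decays with noise
  centroid_acc <- function(noise_sd) {
    im <- sample_image_features(pl, noise_sd = noise_sd, seed = 4)
    e <- aggregate_per_protein(im, "mean")
    C <- cfg$n_compartments; half <- cfg$image_dim %/% 2; bc <- half %/% C
    cents <- matrix(0, C, cfg$image_dim)
    for (k in seq_len(C)) cents[k, ((k - 1) * bc + 1):(k * bc)] <- cfg$comp_scale
    pred <- apply(e$vectors, 1, function(v) which.min(colSums((t(cents) - v)^2)))
    truth <- as.integer(factor(pl$compartment_of[e$ids],
                               levels = names(pl$compartments)))
    mean(pred == truth)
  }
  expect_equal(centroid_acc(0), 1.0)
  accs <- vapply(c(0.1, 1, 5), centroid_acc, 0.0)
  expect_true(all(diff(accs) <= 0))
  expect_lt(accs[3], accs[1])
})

test_that("truth sets and recovery scoring behave at the extremes", {
  cfg <- planted_config("custom", n = 45, n_compartments = 3,
                        assemblies_per_compartment = 1,
                        assembly_size = c(15, 15), image_dim = 8)
  pl <- sample_planted(cfg, seed = 2)
  truth <- truth_sets(pl)
  expect_equal(nrow(truth$terms), 6L)   # 3 compartments + 3 assemblies

  # a DAG holding every planted set exactly scores 1 everywhere
  dag <- dag_from_sets(unname(c(pl$compartments, pl$assemblies)),
                       universe = pl$proteins)
  rs <- recovery_score(dag, pl, "assembly")
  expect_equal(unname(rs$per_unit), rep(1, 3))
  expect_equal(rs$fraction_recovered, 1)

  # root-only DAG: score is the unit-vs-universe Jaccard
  root_only <- dag_from_sets(list(), universe = pl$proteins)
  rs0 <- recovery_score(root_only, pl, "assembly")
  expect_equal(unname(rs0$per_unit), rep(15 / 45, 3))

  # shuffled memberships score near the size/n baseline, never >= 0.5
  set.seed(7)
  shuffled <- dag_from_sets(lapply(1:3, function(i) sample(pl$proteins, 15)),
                            universe = pl$proteins)
  rs_sh <- recovery_score(shuffled, pl, "assembly")
  expect_lt(rs_sh$mean, 0.5)
})

test_that("synth_write emits a consistent, pipeline-ready bundle", {
  d <- withr::local_tempdir()
  out <- synth_write(d, tiny_planted_config(), seed = 4)
  expect_true(all(file.exists(unlist(out$paths))))
  net <- read_edge_list(out$paths$edge_list, min_score = 0)
  expect_setequal(union(net$edges$from, net$edges$to),
                  intersect(out$planted$proteins,
                            union(net$edges$from, net$edges$to)))
  ref <- read_reference_sets(out$paths$truth)
  expect_equal(nrow(ref$terms), 3 + 6)
  expect_identical(read_protein_list(out$paths$protein_list),
                   out$planted$proteins)
})
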