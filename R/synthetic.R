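#' Planted-hierarchy generator configuration
#'
#' The default `demo600` preset mirrors the shape of a proof-of-concept
#' cell map: 600 proteins, 3 compartments of 200, 8 assemblies per
#' compartment with sizes 15-35, background / compartment / assembly
#' edge probabilities 0.002 / 0.01 / 0.25, 64-dimensional image features
#' with 3 images per protein at noise SD 0.5. The `demo150` preset is a
#' quarter-scale version for fast tests. `complementary = TRUE` puts the
#' generator in the regime where the PPI modality carries assembly signal
#' only (`p_comp = p_bg`) and the image modality carries compartment
#' signal only (`assembly_scale = 0`) -- the setting where co-embedding
#' must beat either single modality.
#'
#' @param preset `"demo600"`, `"demo150"` or `"custom"`.
#' @param complementary force the complementary-modality regime.
#' @param ... overrides of individual fields (`n`, `n_compartments`,
#'   `assemblies_per_compartment`, `assembly_size`, `p_bg`, `p_comp`,
#'   `p_assy`, `p_sub`, `image_dim`, `images_per_protein`, `noise_sd`,
#'   `comp_scale`, `assembly_scale`, `min_plant`, `subcomplexes`).
#' @return A `PlantedConfig` list.
#' @export
planted_config <- function(preset = c("demo600", "demo150", "custom"),
                           complementary = FALSE, ...) {
  preset <- match.arg(preset)
  cfg <- list(n = 600, n_compartments = 3, assemblies_per_compartment = 8,
              assembly_size = c(15, 35), p_bg = 0.002, p_comp = 0.01,
              p_assy = 0.25, p_sub = 0.6, image_dim = 64,
              images_per_protein = 3, noise_sd = 0.5, comp_scale = 2,
              assembly_scale = 1, min_plant = 6, subcomplexes = FALSE)
  if (preset == "demo150")
    cfg <- utils::modifyList(cfg, list(n = 150, assemblies_per_compartment = 4,
                                       assembly_size = c(9, 16),
                                       image_dim = 32))
  cfg <- utils::modifyList(cfg, list(...))
  if (complementary)
    cfg <- utils::modifyList(cfg, list(p_comp = cfg$p_bg, assembly_scale = 0))
  cfg$preset <- preset
  cm_assert(cfg$p_bg <= cfg$p_comp && cfg$p_comp < cfg$p_assy &&
              cfg$p_assy < cfg$p_sub && cfg$p_sub <= 1 && cfg$p_bg >= 0,
            "edge probabilities must satisfy p_bg <= p_comp < p_assy < p_sub <= 1")
  cm_assert(cfg$image_dim >= 2 * cfg$n_compartments,
            "image_dim must be at least twice the number of compartments")
  structure(cfg, class = "PlantedConfig")
}

# sizes of `k` units in [lo, hi] summing exactly to `total` (seeded caller)
partition_sizes <- function(total, k, lo, hi) {
  cm_assert(k * lo <= total && total <= k * hi,
            sprintf("cannot split %d proteins into %d units of size %d-%d",
                    total, k, lo, hi))
  sizes <- sample(lo:hi, k, replace = TRUE)
  guard <- 0L
  while (sum(sizes) != total) {
    d <- sign(total - sum(sizes))
    adjustable <- if (d > 0) which(sizes < hi) else which(sizes > lo)
    i <- adjustable[sample.int(length(adjustable), 1L)]
    sizes[i] <- sizes[i] + d
    guard <- guard + 1L
    cm_assert(guard < 10000L, "size partitioning failed to converge")
  }
  sizes
}

#' Sample a planted nested assembly structure
#'
#' Proteins are partitioned into compartments, each compartment into
#' assemblies, and (optionally) large assemblies into two subcomplexes.
#' Every protein belongs to exactly one deepest unit; deterministic given
#' `seed`.
#'
#' @param config a [planted_config()].
#' @param seed integer seed.
#' @return A `PlantedHierarchy`: list with `proteins`, `compartments`,
#'   `assemblies`, `subcomplexes` (possibly empty), the per-protein maps
#'   `compartment_of` / `assembly_of` / `subcomplex_of`, and `config`.
#' @export
sample_planted <- function(config = planted_config(), seed = 1) {
  set.seed(seed)
  n <- config$n; C <- config$n_compartments
  comp_sizes <- rep(n %/% C, C)
  comp_sizes[seq_len(n %% C)] <- comp_sizes[seq_len(n %% C)] + 1L
  proteins <- sprintf("P%04d", seq_len(n))
  shuffled <- sample(proteins)

  compartments <- list(); assemblies <- list(); subcomplexes <- list()
  compartment_of <- assembly_of <- subcomplex_of <-
    setNames(rep(NA_character_, n), proteins)
  pos <- 0L
  for (ck in seq_len(C)) {
    cname <- paste0("COMP", ck)
    members <- shuffled[(pos + 1L):(pos + comp_sizes[ck])]
    pos <- pos + comp_sizes[ck]
    compartments[[cname]] <- sort(members)
    compartment_of[members] <- cname
    sizes <- partition_sizes(comp_sizes[ck], config$assemblies_per_compartment,
                             config$assembly_size[1], config$assembly_size[2])
    apos <- 0L
    for (ak in seq_along(sizes)) {
      aname <- sprintf("ASSY%d_%d", ck, ak)
      amem <- members[(apos + 1L):(apos + sizes[ak])]
      apos <- apos + sizes[ak]
      assemblies[[aname]] <- sort(amem)
      assembly_of[amem] <- aname
      if (isTRUE(config$subcomplexes) && sizes[ak] >= 2 * config$min_plant) {
        half <- sizes[ak] %/% 2
        for (sk in 1:2) {
          smem <- if (sk == 1) amem[seq_len(half)] else amem[(half + 1):sizes[ak]]
          sname <- paste0(aname, "_S", sk)
          subcomplexes[[sname]] <- sort(smem)
          subcomplex_of[smem] <- sname
        }
      }
    }
  }
  structure(list(proteins = proteins, compartments = compartments,
                 assemblies = assemblies, subcomplexes = subcomplexes,
                 compartment_of = compartment_of, assembly_of = assembly_of,
                 subcomplex_of = subcomplex_of, config = config, seed = seed),
            class = "PlantedHierarchy")
}

#' @export
print.PlantedHierarchy <- function(x, ...) {
  cat(sprintf("PlantedHierarchy: %d proteins, %d compartments, %d assemblies%s\n",
              length(x$proteins), length(x$compartments), length(x$assemblies),
              if (length(x$subcomplexes)) sprintf(", %d subcomplexes",
                                                  length(x$subcomplexes)) else ""))
  invisible(x)
}

#' Sample a scored PPI network from a planted hierarchy
#'
#' Each protein pair is connected independently with the edge probability
#' of its deepest shared planted unit (subcomplex > assembly >
#' compartment > background). Edges within a planted unit get scores
#' Uniform(0.7, 1); cross-compartment background edges get scores
#' Uniform(0, 0.7), so a score >= 0.7 confidence filter keeps exactly the
#' planted structure.
#'
#' @param planted a `PlantedHierarchy`.
#' @param p_bg,p_comp,p_assy,p_sub edge probabilities per depth
#'   (defaults from the planted config).
#' @param seed integer seed.
#' @return An `InteractionNetwork` with scores, nodes = all proteins.
#' @export
sample_ppi <- function(planted, p_bg = planted$config$p_bg,
                       p_comp = planted$config$p_comp,
                       p_assy = planted$config$p_assy,
                       p_sub = planted$config$p_sub, seed = 1) {
  cm_assert(p_bg <= p_comp && p_comp < p_assy && p_assy < p_sub && p_sub <= 1,
            "require 0 <= p_bg <= p_comp < p_assy < p_sub <= 1")
  set.seed(seed)
  pr <- planted$proteins; n <- length(pr)
  comp <- as.integer(factor(planted$compartment_of[pr]))
  assy <- as.integer(factor(planted$assembly_of[pr]))
  sub <- planted$subcomplex_of[pr]
  sub_i <- ifelse(is.na(sub), 0L, as.integer(factor(sub)))
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  same_comp <- comp[i] == comp[j]
  same_assy <- assy[i] == assy[j]
  same_sub <- sub_i[i] > 0L & sub_i[i] == sub_i[j]
  prob <- ifelse(same_sub, p_sub,
                 ifelse(same_assy, p_assy,
                        ifelse(same_comp, p_comp, p_bg)))
  hit <- stats::runif(length(prob)) < prob
  planted_edge <- same_comp[hit]
  score <- ifelse(planted_edge, stats::runif(sum(hit), 0.7, 1.0),
                  stats::runif(sum(hit), 0.0, 0.7))
  ed <- data.frame(from = pr[i[hit]], to = pr[j[hit]], score = score,
                   stringsAsFactors = FALSE)
  interaction_network(ed, nodes = pr)
}

#' Sample per-image feature vectors from a planted hierarchy
#'
#' A protein's mean feature vector is its compartment centroid (a block
#' pattern in the first half of the feature dimensions) plus its
#' assembly's offset (a random direction in the orthogonal second half,
#' scaled by `assembly_scale`). Each image is the mean plus isotropic
#' Gaussian noise.
#'
#' @param planted a `PlantedHierarchy`.
#' @param image_dim,images_per_protein,noise_sd generator knobs
#'   (defaults from the planted config).
#' @param seed integer seed.
#' @return An `ImageFeatureTable`.
#' @export
sample_image_features <- function(planted,
                                  image_dim = planted$config$image_dim,
                                  images_per_protein = planted$config$images_per_protein,
                                  noise_sd = planted$config$noise_sd,
                                  seed = 1) {
  cfg <- planted$config
  C <- cfg$n_compartments
  cm_assert(image_dim >= 2 * C, "image_dim must be >= 2 * n_compartments")
  set.seed(seed)
  half <- image_dim %/% 2
  bc <- max(1L, half %/% C)
  centroids <- matrix(0, C, image_dim)
  for (k in seq_len(C))
    centroids[k, ((k - 1) * bc + 1):(k * bc)] <- cfg$comp_scale

  anames <- names(planted$assemblies)
  offsets <- matrix(0, length(anames), image_dim,
                    dimnames = list(anames, NULL))
  if (cfg$assembly_scale > 0) {
    for (a in seq_along(anames)) {
      v <- stats::rnorm(image_dim - half)
      offsets[a, (half + 1):image_dim] <- v / sqrt(sum(v^2)) * cfg$assembly_scale
    }
  }

  pr <- planted$proteins
  comp_i <- as.integer(factor(planted$compartment_of[pr],
                              levels = names(planted$compartments)))
  means <- centroids[comp_i, , drop = FALSE] +
    offsets[planted$assembly_of[pr], , drop = FALSE]
  n_img <- length(pr) * images_per_protein
  rows <- means[rep(seq_along(pr), each = images_per_protein), , drop = FALSE] +
    matrix(stats::rnorm(n_img * image_dim, sd = noise_sd), n_img, image_dim)
  image_feature_table(
    image_id = paste0(rep(pr, each = images_per_protein), "_IMG",
                      rep(seq_len(images_per_protein), length(pr))),
    protein = rep(pr, each = images_per_protein),
    features = rows)
}

#' Reference sets from the planted truth
#'
#' @param planted a `PlantedHierarchy`.
#' @param levels which planted levels become reference terms.
#' @return A `ReferenceSets` with one term per planted unit.
#' @export
truth_sets <- function(planted, levels = c("compartment", "assembly",
                                           "subcomplex")) {
  units <- list()
  if ("compartment" %in% levels) units <- c(units, planted$compartments)
  if ("assembly" %in% levels) units <- c(units, planted$assemblies)
  if ("subcomplex" %in% levels) units <- c(units, planted$subcomplexes)
  reference_sets(names(units), names(units), units)
}

#' Score planted-unit recovery by a hierarchy
#'
#' For each planted unit at the chosen level, the maximum Jaccard overlap
#' with any DAG node (the root included).
#'
#' @param dag a `HierarchyDAG`.
#' @param planted a `PlantedHierarchy`.
#' @param level `"assembly"`, `"compartment"` or `"subcomplex"`.
#' @return List with `per_unit` (named numeric), `mean`, and
#'   `fraction_recovered` (share of units with Jaccard >= 0.5).
#' @export
recovery_score <- function(dag, planted,
                           level = c("assembly", "compartment", "subcomplex")) {
  level <- match.arg(level)
  units <- switch(level, assembly = planted$assemblies,
                  compartment = planted$compartments,
                  subcomplex = planted$subcomplexes)
  cm_assert(length(units) > 0, sprintf("no planted units at level '%s'", level))
  node_sets <- lapply(dag$nodes, `[[`, "members")
  per_unit <- vapply(units, function(u) {
    max(vapply(node_sets, jaccard, 0.0, b = u))
  }, 0.0)
  list(per_unit = per_unit, mean = mean(per_unit),
       fraction_recovered = mean(per_unit >= 0.5))
}

#' Write a complete synthetic input bundle to a directory
#'
#' Generates the planted hierarchy, PPI edge list, image feature table,
#' protein list and truth reference sets, and writes them as the
#' plain-text inputs the pipeline consumes, plus a `config.json`.
#'
#' @param outdir output directory.
#' @param config a [planted_config()].
#' @param seed integer seed (sub-seeds derive from it).
#' @return List with the generated objects and file paths, invisibly.
#' @export
synth_write <- function(outdir, config = planted_config(), seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  planted <- sample_planted(config, seed = seed)
  net <- sample_ppi(planted, seed = seed + 1)
  imgs <- sample_image_features(planted, seed = seed + 2)
  truth <- truth_sets(planted)
  paths <- list(edge_list = file.path(outdir, "ppi_edgelist.tsv"),
                image_features = file.path(outdir, "image_features.tsv"),
                protein_list = file.path(outdir, "proteins.txt"),
                truth = file.path(outdir, "reference_sets.tsv"),
                config = file.path(outdir, "config.json"))
  write_edge_list(net, paths$edge_list)
  write_image_features(imgs, paths$image_features)
  writeLines(planted$proteins, paths$protein_list)
  write_reference_sets(truth, paths$truth)
  jsonlite::write_json(c(unclass(config), list(seed = seed)), paths$config,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(planted = planted, network = net, images = imgs,
                 truth = truth, paths = paths))
}
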