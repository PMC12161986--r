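# Shared fixture builders. Everything is generated in code; no data files.

# Two k-cliques (X*, Y*) optionally joined by one bridge edge X1-Y1.
two_clique_net <- function(k = 5, bridge = TRUE) {
  ed <- expand.grid(a = seq_len(k), b = seq_len(k))
  ed <- ed[ed$a < ed$b, ]
  mk <- function(p) data.frame(from = paste0(p, ed$a), to = paste0(p, ed$b))
  edges <- rbind(mk("X"), mk("Y"))
  if (bridge) edges <- rbind(edges, data.frame(from = "X1", to = "Y1"))
  interaction_network(edges)
}

# Erdos-Renyi network over named nodes, guaranteed at least one edge.
random_net <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  hit <- stats::runif(nrow(ij)) < p
  if (!any(hit)) hit[1] <- TRUE
  interaction_network(data.frame(from = ids[ij[hit, 1]], to = ids[ij[hit, 2]]),
                      nodes = ids)
}

rand_embedding <- function(n, d, seed, modality = "ppi", prefix = "P") {
  set.seed(seed)
  embedding_set(sprintf("%s%03d", prefix, seq_len(n)),
                matrix(stats::rnorm(n * d), n, d), modality)
}

# Exhaustive hypergeometric upper-tail oracle: enumerate all size-s subsets
# of 1..N, count those overlapping the reference set {1..t} in >= k
# elements. Independent of the log-binomial summation under test.
hyper_tail_enum <- function(k, s, t, N) {
  if (k == 0) return(1)
  if (s == 0) return(0)
  subsets <- utils::combn(N, s)
  mean(colSums(subsets <= t) >= k)
}

# Build a HierarchyDAG directly from member sets (bypasses detection).
dag_from_sets <- function(sets, universe = sort(unique(unlist(sets))),
                          persistence = 3L, theta_c = 0.75) {
  comms <- lapply(sets, function(s)
    structure(list(members = sort(s), persistence = persistence,
                   origin = list(threshold_index = 1L, resolution = 1)),
              class = "Community"))
  build_dag(comms, theta_c = theta_c, universe = universe)
}

# Fabricated CommunityPool (for persistence-chain unit tests).
pool_from_cells <- function(cells) {
  entries <- list()
  for (i in seq_along(cells)) {
    for (s in cells[[i]]) {
      entries[[length(entries) + 1L]] <- list(members = sort(s), cell = i,
                                              threshold_index = 1L,
                                              resolution = i)
    }
  }
  structure(list(pool = entries, n_cells = length(cells),
                 edge_fractions = 0.1, resolutions = seq_along(cells),
                 min_size = 1L),
            class = "CommunityPool")
}

# Tiny fast settings for end-to-end pipeline tests.
tiny_planted_config <- function() {
  planted_config("custom", n = 60, n_compartments = 3,
                 assemblies_per_compartment = 2, assembly_size = c(9, 11),
                 image_dim = 16)
}

tiny_pipeline_config <- function(outdir, paths, seed = 1, resume = FALSE,
                                 reference = paths$truth) {
  pipeline_config(outdir, edge_list = paths$edge_list,
                  image_features = paths$image_features,
                  reference = reference, seed = seed, resume = resume,
                  ppi = list(walk_params = list(r = 5, l = 20),
                             sg = list(dimension = 16, epochs = 2)),
                  coembedding = list(latent_dim = 8, hidden_dim = 32,
                                     epochs = 40),
                  hierarchy = list(edge_fractions = c(0.05, 0.1, 0.2),
                                   n_resolutions = 6))
}

# Best-by-quality CPM membership for one cell (thin wrapper for tests).
leiden_cell <- function(g, gamma, seed = 1) {
  cellmapr:::leiden_cpm(g, gamma, seed = seed, n_restarts = 3)
}
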