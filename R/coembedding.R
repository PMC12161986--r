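#' Align two embeddings on their shared protein universe
#'
#' Restricts both embeddings to the intersection of their id sets and
#' orders rows identically (lexicographic).
#'
#' @param embA,embB `EmbeddingSet`s.
#' @return List of the two aligned `EmbeddingSet`s.
#' @export
align_universes <- function(embA, embB) {
  shared <- sort(intersect(embA$ids, embB$ids))
  if (length(shared) == 0L)
    cm_stop(sprintf("embedding universes are disjoint (%d vs %d proteins)",
                    length(embA$ids), length(embB$ids)), "cm_contract_error")
  list(embedding_set(shared, embA$vectors[shared, , drop = FALSE], embA$modality),
       embedding_set(shared, embB$vectors[shared, , drop = FALSE], embB$modality))
}

#' Co-embedding configuration
#'
#' @param latent_dim shared latent dimension `z` (>= 2).
#' @param hidden_dim encoder/decoder hidden width.
#' @param epochs maximum training epochs.
#' @param learning_rate Adam step size.
#' @param triplet_margin alignment triplet margin `m` (> 0).
#' @param pseudo_label_k clusters per modality for pseudo-labels;
#'   `NULL` means `ceiling(sqrt(n))`.
#' @param alignment_weight weight of the triplet alignment term (>= 0).
#' @param refresh_every epochs between triplet resampling.
#' @param patience early-stop plateau length (epochs).
#' @param seed integer seed.
#' @return A `CoembedConfig` list.
#' @export
coembed_config <- function(latent_dim = 128, hidden_dim = 512, epochs = 250,
                           learning_rate = 1e-3, triplet_margin = 0.1,
                           pseudo_label_k = NULL, alignment_weight = 1,
                           refresh_every = 50, patience = 25, seed = 1) {
  cm_assert(latent_dim >= 2, "latent_dim must be >= 2")
  cm_assert(alignment_weight >= 0, "alignment_weight must be >= 0")
  cm_assert(triplet_margin > 0, "triplet_margin must be > 0")
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_dim = as.integer(hidden_dim),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 triplet_margin = triplet_margin,
                 pseudo_label_k = pseudo_label_k,
                 alignment_weight = alignment_weight,
                 refresh_every = as.integer(refresh_every),
                 patience = as.integer(patience), seed = seed),
            class = "CoembedConfig")
}

zscore_columns <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  sweep(sweep(x, 2, mu), 2, s, "/")
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

# Pseudo-label triplets: anchor/positive share a cluster label, negative
# does not. Returns an integer matrix (anchor, positive, negative) or a
# 0-row matrix when no valid triplet exists (degenerate inputs).
sample_triplets <- function(labels, n_triplets) {
  tab <- table(labels)
  ok <- names(tab)[tab >= 2]
  if (length(ok) == 0L || length(unique(labels)) < 2L)
    return(matrix(integer(), 0, 3))
  anchors <- sample(which(labels %in% ok), n_triplets, replace = TRUE)
  out <- matrix(NA_integer_, n_triplets, 3)
  for (i in seq_len(n_triplets)) {
    a <- anchors[i]
    pos_pool <- which(labels == labels[a]); pos_pool <- pos_pool[pos_pool != a]
    neg_pool <- which(labels != labels[a])
    if (length(pos_pool) == 0L || length(neg_pool) == 0L) next
    out[i, ] <- c(a, pos_pool[sample.int(length(pos_pool), 1L)],
                  neg_pool[sample.int(length(neg_pool), 1L)])
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

adam_step <- function(state, grads, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    state$par[[nm]] <- state$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

#' Fit a self-supervised co-embedding of two modalities
#'
#' Dual autoencoder with a shared latent space: each modality has a
#' one-hidden-layer encoder and decoder (tanh hidden units); the latent
#' code of a protein is the average of its two modality codes, and both
#' modalities are reconstructed from that shared code. The objective is
#'
#' `recon(A) + recon(B) + lambda * triplet(latent)`
#'
#' where the triplet term pulls together proteins sharing a pseudo-label
#' (k-means clustering of each modality separately) and pushes apart
#' proteins that do not. Inputs are z-scored per feature; training is
#' full-batch Adam, deterministic given `config$seed`, with early stop on
#' a loss plateau.
#'
#' @param embA,embB aligned or alignable `EmbeddingSet`s.
#' @param config a [coembed_config()].
#' @return A `CoembeddingResult`: list with `embedding` (the unified
#'   `EmbeddingSet`, `modality = "coembedding"`), `loss` (per-epoch total
#'   loss), `loss_parts`, `ids`.
#' @export
fit_coembedding <- function(embA, embB, config = coembed_config()) {
  al <- align_universes(embA, embB)
  A <- zscore_columns(al[[1]]$vectors)
  B <- zscore_columns(al[[2]]$vectors)
  ids <- al[[1]]$ids
  n <- length(ids)
  z <- config$latent_dim; h <- config$hidden_dim
  dA <- ncol(A); dB <- ncol(B)
  lambda <- config$alignment_weight
  margin <- config$triplet_margin

  set.seed(config$seed)
  par <- list(
    WA1 = glorot(dA, h), bA1 = numeric(h), WA2 = glorot(h, z), bA2 = numeric(z),
    WB1 = glorot(dB, h), bB1 = numeric(h), WB2 = glorot(h, z), bB2 = numeric(z),
    VA1 = glorot(z, h), cA1 = numeric(h), VA2 = glorot(h, dA), cA2 = numeric(dA),
    VB1 = glorot(z, h), cB1 = numeric(h), VB2 = glorot(h, dB), cB2 = numeric(dB))
  state <- list(par = par,
                m = lapply(par, function(x) x * 0),
                v = lapply(par, function(x) x * 0))

  k <- config$pseudo_label_k %||% ceiling(sqrt(n))
  labsA <- labsB <- NULL
  if (lambda > 0 && n >= 3 && k >= 2) {
    kA <- min(k, n - 1L); kB <- min(k, n - 1L)
    labsA <- tryCatch(stats::kmeans(A, centers = kA, nstart = 3,
                                    iter.max = 50)$cluster,
                      error = function(e) NULL)
    labsB <- tryCatch(stats::kmeans(B, centers = kB, nstart = 3,
                                    iter.max = 50)$cluster,
                      error = function(e) NULL)
  }
  refresh_triplets <- function() {
    tri <- rbind(
      if (!is.null(labsA)) sample_triplets(labsA, n) else matrix(integer(), 0, 3),
      if (!is.null(labsB)) sample_triplets(labsB, n) else matrix(integer(), 0, 3))
    tri
  }
  tri <- refresh_triplets()

  addmu <- function(x, b) sweep(x, 2, b, "+")
  loss_tr <- numeric(0); rec_tr <- numeric(0); tri_tr <- numeric(0)
  best_window <- Inf; stall <- 0L

  for (ep in seq_len(config$epochs)) {
    if (ep > 1 && ep %% config$refresh_every == 1) tri <- refresh_triplets()

    hA <- tanh(addmu(A %*% state$par$WA1, state$par$bA1))
    zA <- addmu(hA %*% state$par$WA2, state$par$bA2)
    hB <- tanh(addmu(B %*% state$par$WB1, state$par$bB1))
    zB <- addmu(hB %*% state$par$WB2, state$par$bB2)
    Z <- (zA + zB) / 2
    gA <- tanh(addmu(Z %*% state$par$VA1, state$par$cA1))
    Ahat <- addmu(gA %*% state$par$VA2, state$par$cA2)
    gB <- tanh(addmu(Z %*% state$par$VB1, state$par$cB1))
    Bhat <- addmu(gB %*% state$par$VB2, state$par$cB2)

    rec_loss <- mean((Ahat - A)^2) + mean((Bhat - B)^2)

    dZ <- matrix(0, n, z)
    trip_loss <- 0
    if (lambda > 0 && nrow(tri) > 0) {
      Za <- Z[tri[, 1], , drop = FALSE]
      Zp <- Z[tri[, 2], , drop = FALSE]
      Zn <- Z[tri[, 3], , drop = FALSE]
      d2p <- rowSums((Za - Zp)^2); d2n <- rowSums((Za - Zn)^2)
      viol <- d2p - d2n + margin
      act <- viol > 0
      trip_loss <- mean(pmax(viol, 0))
      if (any(act)) {
        coef <- lambda / nrow(tri)
        ga <- 2 * (Zn[act, , drop = FALSE] - Zp[act, , drop = FALSE]) * coef
        gp <- -2 * (Za[act, , drop = FALSE] - Zp[act, , drop = FALSE]) * coef
        gn <- 2 * (Za[act, , drop = FALSE] - Zn[act, , drop = FALSE]) * coef
        for (cc in seq_len(z)) {
          dZ[, cc] <- dZ[, cc] +
            unname(tapply(c(ga[, cc], gp[, cc], gn[, cc]),
                          factor(c(tri[act, 1], tri[act, 2], tri[act, 3]),
                                 levels = seq_len(n)),
                          sum, default = 0))
        }
      }
    }
    total <- rec_loss + lambda * trip_loss
    if (!is.finite(total)) {
      cond <- errorCondition(
        sprintf("co-embedding diverged at epoch %d (loss not finite)", ep),
        class = c("cm_divergence_error", "cellmapr_error", "error", "condition"))
      cond$trajectory <- loss_tr
      stop(cond)
    }
    loss_tr <- c(loss_tr, total); rec_tr <- c(rec_tr, rec_loss)
    tri_tr <- c(tri_tr, trip_loss)

    # backprop
    dAhat <- 2 * (Ahat - A) / (n * dA)
    dBhat <- 2 * (Bhat - B) / (n * dB)
    dgA <- dAhat %*% t(state$par$VA2) * (1 - gA^2)
    dgB <- dBhat %*% t(state$par$VB2) * (1 - gB^2)
    dZ <- dZ + dgA %*% t(state$par$VA1) + dgB %*% t(state$par$VB1)
    dzA <- dZ / 2; dzB <- dZ / 2
    dhA <- dzA %*% t(state$par$WA2) * (1 - hA^2)
    dhB <- dzB %*% t(state$par$WB2) * (1 - hB^2)

    grads <- list(
      WA1 = t(A) %*% dhA, bA1 = colSums(dhA),
      WA2 = t(hA) %*% dzA, bA2 = colSums(dzA),
      WB1 = t(B) %*% dhB, bB1 = colSums(dhB),
      WB2 = t(hB) %*% dzB, bB2 = colSums(dzB),
      VA1 = t(Z) %*% dgA, cA1 = colSums(dgA),
      VA2 = t(gA) %*% dAhat, cA2 = colSums(dAhat),
      VB1 = t(Z) %*% dgB, cB1 = colSums(dgB),
      VB2 = t(gB) %*% dBhat, cB2 = colSums(dBhat))
    state <- adam_step(state, grads, config$learning_rate, ep)

    # plateau early stop on a smoothed window
    if (ep >= 2 * config$patience) {
      w <- mean(tail(loss_tr, config$patience))
      if (w < best_window - 1e-7) { best_window <- w; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }

  hA <- tanh(addmu(A %*% state$par$WA1, state$par$bA1))
  zA <- addmu(hA %*% state$par$WA2, state$par$bA2)
  hB <- tanh(addmu(B %*% state$par$WB1, state$par$bB1))
  zB <- addmu(hB %*% state$par$WB2, state$par$bB2)
  Z <- (zA + zB) / 2

  structure(list(embedding = embedding_set(ids, Z, modality = "coembedding"),
                 loss = loss_tr,
                 loss_parts = data.frame(epoch = seq_along(loss_tr),
                                         total = loss_tr,
                                         reconstruction = rec_tr,
                                         triplet = tri_tr),
                 ids = ids),
            class = "CoembeddingResult")
}

#' @export
print.CoembeddingResult <- function(x, ...) {
  cat(sprintf("CoembeddingResult: %d proteins x %d dims, %d epochs (final loss %.4g)\n",
              length(x$ids), x$embedding$d, length(x$loss), tail(x$loss, 1)))
  invisible(x)
}

cosine_all_pairs <- function(emb) {
  V <- emb$vectors
  norms <- sqrt(rowSums(V^2))
  cm_assert(all(norms > 0), "zero vector in embedding")
  S <- tcrossprod(V / norms)
  S
}

#' Evaluate pair similarities against reference assemblies
#'
#' Computes, for each decile of all pairwise cosine similarities, the
#' fraction of pairs that co-occur in at least one reference term, plus a
#' standardized Wilcoxon rank-sum statistic comparing within-term pair
#' similarities to all remaining pairs (larger = within-term pairs rank
#' higher).
#'
#' @param emb an `EmbeddingSet`.
#' @param reference a `ReferenceSets`.
#' @return List with `deciles` (data.frame `decile`, `n_pairs`,
#'   `co_complex_fraction`; decile 10 = most similar), `rank_sum_z`,
#'   `n_within`, `n_pairs`, and `within_pairs` (2-column matrix of ids).
#' @export
evaluate_pair_similarity <- function(emb, reference) {
  universe <- emb$ids
  covered <- intersect(universe, unique(unlist(reference$members)))
  if (length(covered) < 2L)
    cm_stop("fewer than 2 embedding proteins overlap the reference members",
            "cm_contract_error")
  n <- length(universe)
  S <- cosine_all_pairs(emb)
  ut <- upper.tri(S)
  sims <- S[ut]

  idx <- setNames(seq_len(n), universe)
  within <- logical(length(sims))
  # linear index of (i, j), i < j, in upper.tri order (column-major)
  pair_pos <- function(i, j) (j - 1) * (j - 2) / 2 + i
  within_pairs <- character(0)
  for (m in reference$members) {
    mm <- sort(idx[intersect(m, universe)])
    if (length(mm) < 2L) next
    cmb <- utils::combn(mm, 2L)
    within[pair_pos(cmb[1, ], cmb[2, ])] <- TRUE
  }
  n_within <- sum(within)
  wp <- if (n_within > 0) {
    all_pairs <- which(within)
    j <- ceiling((1 + sqrt(1 + 8 * all_pairs)) / 2)
    i <- all_pairs - (j - 1) * (j - 2) / 2
    cbind(universe[i], universe[j])
  } else matrix(character(), 0, 2)

  rk <- rank(sims)
  n1 <- n_within; n2 <- length(sims) - n_within
  z_stat <- if (n1 > 0 && n2 > 0) {
    W <- sum(rk[within])
    (W - n1 * (n1 + n2 + 1) / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  } else NA_real_

  dec <- ceiling(rk / length(sims) * 10)
  dec[dec < 1] <- 1
  deciles <- data.frame(
    decile = 1:10,
    n_pairs = as.integer(tabulate(dec, 10)),
    co_complex_fraction = vapply(1:10, function(d) {
      nd <- sum(dec == d)
      if (nd == 0) NA_real_ else sum(within[dec == d]) / nd
    }, 0.0))

  list(deciles = deciles, rank_sum_z = z_stat, n_within = n_within,
       n_pairs = length(sims), within_pairs = wp)
}

#' Project an embedding to 2-D for visualization
#'
#' Deterministic principal-component projection (the first two PCs, with a
#' sign convention fixing the largest-magnitude loading positive). A
#' nonlinear neighbor embedding can be substituted externally; the
#' contract here is finite, seeded-deterministic coordinates.
#'
#' @param emb an `EmbeddingSet` with >= 10 proteins.
#' @param seed accepted for interface compatibility (the PCA projection
#'   is deterministic regardless).
#' @return n x 2 coordinate matrix with protein rownames.
#' @export
project_2d <- function(emb, seed = 1) {
  n <- length(emb$ids)
  if (n < 10)
    cm_stop(sprintf("only %d proteins; plot the raw coordinates directly instead", n),
            "cm_contract_error")
  set.seed(seed)
  pc <- stats::prcomp(emb$vectors, center = TRUE, scale. = FALSE, rank. = 2)
  coords <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    k <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[k, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- emb$ids
  colnames(coords) <- c("dim1", "dim2")
  coords
}

find_embedding_file <- function(dir_or_file, modality = "ppi") {
  if (file.exists(dir_or_file) && !dir.exists(dir_or_file))
    return(dir_or_file)
  cand <- list.files(dir_or_file, pattern = "\\.tsv$", full.names = TRUE)
  pref <- cand[basename(cand) %in% c("ppi_emb.tsv", "image_emb.tsv",
                                     "coembedding.tsv")]
  if (length(pref) > 0) return(pref[1])
  if (length(cand) > 0) return(cand[1])
  cm_stop(sprintf("no embedding TSV found in %s", dir_or_file), "cm_parse_error")
}

#' Co-embedding stage: integrate two embedding directories
#'
#' @param inputA,inputB `EmbeddingSet`s, embedding TSV paths, or stage
#'   directories containing one.
#' @param outdir stage directory.
#' @param config a [coembed_config()].
#' @param inputs extra provenance inputs.
#' @return The `CoembeddingResult`, invisibly.
#' @export
coembed <- function(inputA, inputB, outdir, config = coembed_config(),
                    inputs = character()) {
  load_emb <- function(x, modality) {
    if (inherits(x, "EmbeddingSet")) return(list(emb = x, src = NULL))
    f <- find_embedding_file(x, modality)
    list(emb = read_embedding_tsv(f, modality), src = x)
  }
  ea <- load_emb(inputA, "ppi"); eb <- load_emb(inputB, "image")
  inputs <- unique(c(inputs, unlist(c(ea$src, eb$src))))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- fit_coembedding(ea$emb, eb$emb, config)
  write_embedding_tsv(l2_normalize(res$embedding),
                      file.path(outdir, "coembedding.tsv"))
  utils::write.table(res$loss_parts, file.path(outdir, "loss_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(res$ids) >= 10) {
    coords <- project_2d(res$embedding, seed = config$seed)
    writeLines(c("id\tdim1\tdim2",
                 paste(rownames(coords), sprintf("%.17g", coords[, 1]),
                       sprintf("%.17g", coords[, 2]), sep = "\t")),
               file.path(outdir, "projection_2d.tsv"))
  }
  stage_log(outdir, "coembedding",
            sprintf("proteins=%d latent=%d epochs_run=%d final_loss=%.6g",
                    length(res$ids), config$latent_dim, length(res$loss),
                    tail(res$loss, 1)))
  register_stage(outdir, inputs = inputs,
                 params = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
                 stage_name = "coembedding")
  invisible(res)
}
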