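# Phenotype identification: feature standardisation, multi-cluster feature
# selection (MCFS: spectral analysis + L1-regularised least squares),
# Laplacian-eigenmap embedding, DBSCAN clustering and a k-means cross-check.

#' Standardise a feature matrix
#'
#' Z-scores each column; constant columns (sd < 1e-12) are dropped and
#' recorded. Standardised columns have mean 0 and sd 1 to within 1e-9.
#'
#' @param X numeric matrix or data.frame (subjects x features).
#' @return list with `values` (standardised matrix), `center`, `scale`,
#'   and `dropped` (names of constant columns).
#' @export
standardize_features <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds < 1e-12]
  keep <- sds >= 1e-12
  Xs <- scale(X[, keep, drop = FALSE])
  values <- Xs[, , drop = FALSE]
  attr(values, "scaled:center") <- NULL
  attr(values, "scaled:scale") <- NULL
  list(values = values,
       center = attr(Xs, "scaled:center"), scale = attr(Xs, "scaled:scale"),
       dropped = dropped)
}

# Symmetric k-nearest-neighbour graph with heat-kernel weights
# w_ij = exp(-d_ij^2 / t); t defaults to the mean squared retained-edge
# distance. A disconnected graph is augmented with the edges of the Euclidean
# minimum spanning tree that join distinct components.
knn_graph <- function(X, k = 5, heat_t = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    dk <- sort(D[i, others])[min(k, n - 1)]
    # ties at the k-th distance are all included, so exactly duplicated
    # subjects receive identical neighbourhoods (and identical embeddings)
    nb <- others[D[i, others] <= dk + 1e-12]
    A[i, nb] <- TRUE
  }
  A <- A | t(A)
  augmented <- FALSE
  aug <- matrix(FALSE, n, n)
  comp <- graph_components(A)
  if (max(comp) > 1) {
    augmented <- TRUE
    M <- ape::mst(stats::dist(X))
    add <- which(M == 1 & !A, arr.ind = TRUE)
    for (r in seq_len(nrow(add)))
      if (comp[add[r, 1]] != comp[add[r, 2]]) {
        A[add[r, 1], add[r, 2]] <- A[add[r, 2], add[r, 1]] <- TRUE
        aug[add[r, 1], add[r, 2]] <- aug[add[r, 2], add[r, 1]] <- TRUE
      }
  }
  knn_edges <- A & !aug
  if (is.null(heat_t)) heat_t <- mean(D[knn_edges]^2)
  if (heat_t <= 0) heat_t <- 1
  W <- matrix(0, n, n)
  W[A] <- exp(-D[A]^2 / heat_t)
  if (augmented) {
    # augmentation edges over large distances get vanishing heat weights and
    # a far outlier would then dominate the small end of the spectrum as a
    # quasi-disconnected indicator; floor them at the weakest genuine edge
    floor_w <- min(W[knn_edges])
    W[aug] <- pmax(W[aug], floor_w)
  }
  list(W = W, heat_t = heat_t, augmented = augmented)
}

# Connected components of a logical adjacency matrix (BFS).
graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Smallest nontrivial generalized eigenvectors of L y = lambda D y
# (L = D - W), via the symmetric form D^{-1/2} L D^{-1/2}. The smallest
# eigenvector (constant, eigenvalue 0 for a connected graph) is excluded.
# Eigenvectors are D-normalised (y' D y = 1).
laplacian_eigenvectors <- function(W, k) {
  d <- rowSums(W)
  d[d <= 0] <- 1e-12
  ds <- 1 / sqrt(d)
  Lsym <- -(W * outer(ds, ds))
  diag(Lsym) <- diag(Lsym) + 1
  e <- eigen(Lsym, symmetric = TRUE)
  n <- nrow(W)
  ord <- n:1                       # ascending eigenvalues
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  sel <- 2:(k + 1)                 # drop the trivial (constant) eigenvector
  Y <- vecs[, sel, drop = FALSE] * ds
  for (j in seq_len(ncol(Y))) Y[, j] <- Y[, j] / sqrt(sum(d * Y[, j]^2))
  list(vectors = Y, values = vals[sel], trivial_value = vals[1])
}

#' Multi-cluster feature selection (MCFS)
#'
#' Unsupervised feature ranking: (i) build a symmetric `p_nn`-nearest-
#' neighbour heat-kernel graph on the subjects; (ii) compute the `k_eigen`
#' smallest nontrivial generalized eigenvectors of the graph Laplacian;
#' (iii) regress each eigenvector on the features with an L1-penalised least
#' squares path, keeping at most `d` active features per eigenvector;
#' (iv) score each feature by the maximum |coefficient| across eigenvectors
#' and return the top `d` (ties broken by feature order). Exactly duplicated
#' columns share the score of their representative.
#'
#' Collinear biomarkers measure the same contrast (e.g. the lateral T-wave
#' amplitudes and inversion flags), and an L1 path assigns the whole
#' coefficient of such a block to a single representative. The earned
#' coefficient therefore reflects a block's importance undiluted, and the
#' score is shared afterwards across near-duplicate features (absolute
#' correlation >= `share_cor`, a generalisation of the exact-duplicate
#' symmetry): every member of a block is *ranked* by the block's score, while
#' the returned top-`d` *selection* takes distinct earned-score winners so
#' that one block cannot crowd out the other contrasts.
#'
#' @param X standardised numeric matrix (subjects x features).
#' @param d number of features to retain (default 7).
#' @param k_eigen number of eigenvectors (default 5).
#' @param p_nn graph neighbourhood size (default 5).
#' @param heat_t heat-kernel bandwidth (default: mean squared edge distance).
#' @param share_cor |correlation| above which features share their block's
#'   score (default 0.9).
#' @param diversity_cor |correlation| above which a feature is skipped during
#'   the top-`d` walk because a correlated feature is already selected
#'   (default 0.95; keeps exact near-duplicates from flooding the selection
#'   while still allowing several members of an informative family).
#' @param stability_reps optional number of stability-selection subsample
#'   replicates whose block-shared scores are averaged with the full-cohort
#'   scores (default 0 = single full-cohort pass).
#' @param stability_frac fraction of subjects per replicate (default 0.75).
#' @param stability_seed internal RNG seed for the subsample draws; the
#'   global RNG state is restored afterwards.
#' @param spectral_weighting apply 1/lambda spectral weighting to the
#'   per-eigenvector coefficients (default TRUE): cluster-separating
#'   eigenvectors have near-zero eigenvalues and dominate the scores, while
#'   smooth within-cluster modes, whose regressions would credit noise
#'   features, are suppressed without a hard cut-off.
#' @return list with `selected` (column names, length d, block
#'   representatives by earned score), `scores` (per feature, block-shared --
#'   use for ranking), `earned` (per feature, before sharing), and `graph`
#'   diagnostics.
#' @export
mcfs_select <- function(X, d = 7, k_eigen = 5, p_nn = 10, heat_t = NULL,
                        share_cor = 0.9, diversity_cor = 0.95,
                        stability_reps = 0, stability_frac = 0.75,
                        stability_seed = 20140601, spectral_weighting = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 10) stop("MCFS needs at least 10 subjects")
  if (d >= p) stop("d must be smaller than the number of features")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))
  # representative of each set of exactly duplicated columns
  key <- apply(round(X, 10), 2, paste, collapse = ",")
  rep_idx <- match(key, key)
  uniq <- which(rep_idx == seq_len(p))

  # earned score of each unique feature for one subject subset: graph ->
  # separator eigenvectors (eigengap heuristic: eigenvectors past the largest
  # consecutive eigenvalue gap describe smooth within-cluster variation and
  # would award scores to noise features) -> L1 path per eigenvector
  earned_for <- function(rows) {
    Xs <- X[rows, , drop = FALSE]
    Xu <- Xs[, uniq, drop = FALSE]
    g <- knn_graph(Xs, k = p_nn, heat_t = heat_t)
    ev <- laplacian_eigenvectors(g$W, k = min(k_eigen, length(rows) - 2))
    use <- seq_len(ncol(ev$vectors))
    # spectral weighting: an eigenvector's coefficients count in proportion
    # to 1/lambda (relative to the smallest nontrivial eigenvalue), so
    # cluster-separating eigenvectors (lambda near 0) dominate the scores
    # and smooth within-cluster modes (large lambda), whose regressions
    # would credit noise features, are suppressed without a hard cut-off
    wts <- if (spectral_weighting) pmax(ev$values, 1e-12)[1] /
             pmax(ev$values, 1e-12) else rep(1, length(use))
    earned_u <- numeric(length(uniq))
    for (j in use) {
      y <- ev$vectors[, j]
      fit <- glmnet::glmnet(Xu, y, alpha = 1, standardize = FALSE,
                            intercept = TRUE)
      df <- fit$df
      ok <- which(df <= d & df > 0)
      pick <- if (length(ok)) ok[length(ok)] else which(df > 0)[1]
      if (is.na(pick)) next
      beta <- abs(as.numeric(fit$beta[, pick])) * wts[j]
      earned_u <- pmax(earned_u, beta)
    }
    attr(earned_u, "graph") <- list(heat_t = g$heat_t,
                                    augmented = g$augmented,
                                    eigenvalues = ev$values)
    earned_u
  }

  C <- abs(suppressWarnings(stats::cor(X)))
  C[is.na(C)] <- 0
  # block sharing: a replicate's L1 path credits one arbitrary member of a
  # collinear block, so every member inherits its block's best earned score
  # before replicates are aggregated
  share <- function(earned_p) {
    vapply(seq_len(p), function(j)
      max(earned_p[C[j, ] >= share_cor | seq_len(p) == j]), numeric(1))
  }

  full <- earned_for(seq_len(n))
  gdiag <- attr(full, "graph")
  # stability aggregation: the lasso path and the eigengap estimate both
  # vary under perturbation of the cohort, so the block-shared scores are
  # averaged over deterministic random subsets of the subjects
  if (stability_reps > 0) {
    m <- max(10L, floor(stability_frac * n))
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(stability_seed)
    subsets <- replicate(stability_reps, sort(sample.int(n, m)),
                         simplify = FALSE)
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
    acc <- share(as.numeric(full)[match(rep_idx, uniq)])
    for (s in subsets)
      acc <- acc + share(as.numeric(earned_for(s))[match(rep_idx, uniq)])
    scores <- acc / (stability_reps + 1)
  } else {
    scores <- share(as.numeric(full)[match(rep_idx, uniq)])
  }
  names(scores) <- colnames(X)
  earned <- as.numeric(full)[match(rep_idx, uniq)]
  names(earned) <- colnames(X)
  # diverse top-d: walk features by aggregated score and skip near-duplicates
  # of already-picked features, so one collinear block contributes one member
  ord <- order(-scores, seq_len(p))
  selected <- character(0)
  sel_idx <- integer(0)
  for (j in ord) {
    if (scores[j] <= 0 && length(selected) > 0) break
    if (length(sel_idx) && any(C[j, sel_idx] >= diversity_cor)) next
    selected <- c(selected, colnames(X)[j])
    sel_idx <- c(sel_idx, j)
    if (length(selected) == d) break
  }
  if (length(selected) < d) {
    extra <- setdiff(colnames(X)[ord], selected)
    selected <- c(selected, extra[seq_len(d - length(selected))])
  }
  list(selected = selected, scores = scores, earned = earned,
       graph = gdiag)
}

#' Laplacian-eigenmap embedding to two dimensions
#'
#' Eigenvectors for the two smallest nonzero generalized eigenvalues of the
#' neighbourhood-graph Laplacian, D-orthonormalised. The per-axis sign is
#' fixed by making the largest-|value| entry positive, so the embedding is
#' deterministic.
#'
#' @param X numeric matrix (subjects x selected features), standardised.
#' @param p_nn neighbourhood size (default 5).
#' @param heat_t heat-kernel bandwidth (default: mean squared edge distance).
#' @return list of class `embedding2d`: `coordinates` (n x 2), `graph`
#'   (weight matrix), `eigenvalues`, `trivial_eigenvalue`, `augmented`.
#' @export
embed_laplacian <- function(X, p_nn = 10, heat_t = NULL) {
  g <- knn_graph(as.matrix(X), k = p_nn, heat_t = heat_t)
  ev <- laplacian_eigenvectors(g$W, k = 2)
  Y <- ev$vectors
  for (j in 1:2) if (Y[which.max(abs(Y[, j])), j] < 0) Y[, j] <- -Y[, j]
  structure(list(coordinates = Y, graph = g$W, eigenvalues = ev$values,
                 trivial_eigenvalue = ev$trivial_value,
                 augmented = g$augmented),
            class = "embedding2d")
}

#' DBSCAN clustering with deterministic parameter defaults
#'
#' Standard DBSCAN core/border/noise semantics on Euclidean distance.
#' `min_pts` defaults to floor(n/25) clamped to >= 3. `eps`, when not given,
#' is auto-selected at the maximum-curvature (knee) point of the sorted
#' min_pts-nearest-neighbour distance curve (largest perpendicular distance
#' to the chord joining the curve endpoints). Core points are those with at
#' least `min_pts` neighbours within `eps` (counting themselves); clusters
#' are connected components of the core-core reachability graph; border
#' points join the cluster of their nearest core within `eps`. Labels are
#' renumbered by descending cluster size; noise is labelled 0.
#'
#' @param coords numeric matrix of embedding coordinates (n x 2).
#' @param min_pts minimum cluster membership (default floor(n/25), >= 3).
#' @param eps neighbourhood radius, or `NULL` for automatic selection.
#' @return list of class `cluster_assignment`: `labels` (integer, 0 = noise),
#'   `n_clusters`, `min_pts`, `eps`, `core` (logical), `algorithm`.
#' @export
dbscan_cluster <- function(coords, min_pts = NULL, eps = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(min_pts)) min_pts <- max(3L, n %/% 25L)
  D <- as.matrix(stats::dist(coords))
  if (is.null(eps)) eps <- auto_eps(D, min_pts)
  within <- D <= eps
  core <- rowSums(within) >= min_pts          # includes self (d = 0)
  labels <- integer(n)
  if (any(core) && eps > 0) {
    A <- within & outer(core, core, "&")
    diag(A) <- core
    comp <- graph_components(A | t(A))
    comp[!core] <- 0L
    labels[core] <- comp[core]
    for (i in which(!core)) {
      cand <- which(core & within[i, ])
      if (length(cand)) {
        nearest <- cand[order(D[i, cand], cand)][1]
        labels[i] <- labels[nearest]
      }
    }
  }
  labels <- renumber_by_size(labels)
  structure(list(labels = labels,
                 n_clusters = length(setdiff(unique(labels), 0L)),
                 min_pts = min_pts, eps = eps, core = core,
                 algorithm = "dbscan"),
            class = "cluster_assignment")
}

# Automatic eps from the sorted min_pts-NN distance curve. For points inside
# clusters of at least min_pts members the k-distance stays within-cluster,
# so the curve never contains between-cluster distances: its maximum is the
# widest cluster's internal scale and is the natural eps. Only genuine
# low-density outliers produce k-distances beyond that scale, and they show
# up as a sharp curvature break (a multiplicative jump) at the top of the
# curve. Fewer than min_pts points can never form a cluster of their own, so
# an outlier regime occupies at most the top min_pts - 1 curve positions: the
# rule scans those positions for the largest consecutive ratio, and a jump
# >= 3x marks the outlier regime (eps is set just below it); otherwise eps is
# the curve maximum. A cut lower down would clip the internal tail of a
# loose-but-legitimate cluster.
auto_eps <- function(D, k) {
  n <- nrow(D)
  kd <- sort(vapply(seq_len(n), function(i) sort(D[i, -i])[min(k, n - 1)],
                    numeric(1)))
  m <- length(kd)
  if (kd[m] <= 0) return(0)
  if (m < 4) return(kd[m])
  start <- max(m - k + 1L, 2L)
  idx <- seq(start, m - 1L)
  idx <- idx[kd[idx] > 0]
  if (!length(idx)) return(kd[m])
  ratios <- kd[idx + 1L] / kd[idx]
  i <- idx[which.max(ratios)]
  if (max(ratios) >= 3) kd[i] else kd[m]
}

renumber_by_size <- function(labels) {
  ids <- setdiff(unique(labels), 0L)
  if (!length(ids)) return(labels)
  sizes <- vapply(ids, function(i) sum(labels == i), integer(1))
  first <- vapply(ids, function(i) which(labels == i)[1], integer(1))
  ids <- ids[order(-sizes, first)]
  out <- labels
  for (j in seq_along(ids)) out[labels == ids[j]] <- j
  out
}

#' k-means cross-check of a DBSCAN partition
#'
#' Runs k-means (k-means++-style multiple restarts via `nstart`) on the same
#' embedding with k equal to the number of DBSCAN clusters and returns the
#' adjusted Rand index between the two label sets, noise points excluded.
#'
#' @param coords embedding coordinates (n x 2).
#' @param labels DBSCAN labels (0 = noise).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart number of restarts (default 50).
#' @return list with `ari`, `kmeans_labels`, and `k`.
#' @export
crosscheck_kmeans <- function(coords, labels, seed = 1, nstart = 50) {
  k <- length(setdiff(unique(labels), 0L))
  if (k < 2) stop("k-means cross-check needs at least 2 DBSCAN clusters")
  set.seed(seed)
  km <- tryCatch(
    stats::kmeans(coords, centers = k, nstart = nstart),
    error = function(e) {
      # near-duplicate coordinates can empty a cluster under Hartigan-Wong;
      # fall back to deterministic farthest-point seeding with Lloyd updates
      ctr <- coords[farthest_points(coords, k), , drop = FALSE]
      stats::kmeans(coords, centers = ctr, algorithm = "Lloyd",
                    iter.max = 100)
    })
  keep <- labels != 0L
  list(ari = mclust::adjustedRandIndex(labels[keep], km$cluster[keep]),
       kmeans_labels = km$cluster, k = k)
}

#' Full phenotyping pipeline: select, embed, cluster
#'
#' Selects `d` QRS-morphology features (Hermite coefficients) by MCFS,
#' embeds with Laplacian eigenmaps, clusters with DBSCAN, and cross-checks
#' with k-means when at least two clusters emerge. In `qrs_only` mode the
#' embedding input is the selected QRS features alone. In `qrs_plus_t` mode
#' the MCFS selection is applied before merging the T-wave biomarkers: the
#' standardised T-wave block (per-lead amplitudes, inversion flags, TWI and
#' T axis) is appended to the selected QRS features, scaled by
#' `sqrt(d / n_T)` so both biomarker families contribute comparable total
#' variance to the embedding distances (an appended block of n_T unit-
#' variance columns would otherwise drown the QRS structure). Depolarisation
#' structure is therefore preserved between the two modes and the T-wave
#' biomarkers act to subdivide, exactly the behaviour of repeating the
#' clustering "with the addition of" repolarisation biomarkers.
#'
#' @param features data.frame from [cohort_features()] (`subject_id` +
#'   feature columns with a `feature_types` attribute), or a plain numeric
#'   feature matrix plus an explicit `types` vector.
#' @param mode `"qrs_only"` or `"qrs_plus_t"`.
#' @param d number of MCFS features (default 7).
#' @param p_nn,k_eigen,heat_t graph/spectral hyperparameters.
#' @param min_pts,eps DBSCAN parameters (defaults: floor(n/25) >= 3, auto).
#' @param seed seed for the k-means cross-check.
#' @param types optional feature-type tags overriding the attribute.
#' @param ... further arguments passed to [mcfs_select()].
#' @return list of class `phenotyping_result`: `labels`, `n_clusters`,
#'   `embedding`, `selected_features`, `dbscan`, `kmeans_ari`, `mode`,
#'   `params`.
#' @export
run_phenotyping <- function(features, mode = c("qrs_plus_t", "qrs_only"),
                            d = 7, p_nn = 10, k_eigen = 5, heat_t = NULL,
                            min_pts = NULL, eps = NULL, seed = 1,
                            types = NULL, ...) {
  mode <- match.arg(mode)
  if (is.data.frame(features) && "subject_id" %in% colnames(features)) {
    ids <- features$subject_id
    X <- as.matrix(features[, setdiff(colnames(features), "subject_id"),
                            drop = FALSE])
    if (is.null(types)) types <- attr(features, "feature_types")
  } else {
    X <- as.matrix(features)
    ids <- rownames(X)
  }
  if (is.null(types)) types <- feature_types(colnames(X))
  keep_q <- types == "qrs_morphology"
  if (!any(keep_q)) stop("no feature columns match mode '", mode, "'")
  st <- standardize_features(X[, keep_q, drop = FALSE])
  Xs <- st$values
  sel <- mcfs_select(Xs, d = d, k_eigen = k_eigen, p_nn = p_nn,
                     heat_t = heat_t, ...)
  Xemb <- Xs[, sel$selected, drop = FALSE]
  dropped_t <- character(0)
  if (mode == "qrs_plus_t") {
    keep_t <- types == "t_wave"
    if (!any(keep_t)) stop("no feature columns match mode '", mode, "'")
    st_t <- standardize_features(X[, keep_t, drop = FALSE])
    dropped_t <- st_t$dropped
    bal <- sqrt(d / ncol(st_t$values))
    Xemb <- cbind(Xemb, st_t$values * bal)
  }
  emb <- embed_laplacian(Xemb, p_nn = p_nn, heat_t = heat_t)
  cl <- dbscan_cluster(emb$coordinates, min_pts = min_pts, eps = eps)
  km <- if (cl$n_clusters >= 2)
    crosscheck_kmeans(emb$coordinates, cl$labels, seed = seed) else NULL
  structure(list(subject_id = ids, labels = cl$labels,
                 n_clusters = cl$n_clusters, embedding = emb,
                 selected_features = sel$selected,
                 feature_scores = sel$scores, dbscan = cl,
                 kmeans_ari = if (is.null(km)) NA_real_ else km$ari,
                 mode = mode,
                 params = list(d = d, p_nn = p_nn, k_eigen = k_eigen,
                               heat_t = heat_t, min_pts = cl$min_pts,
                               eps = cl$eps, seed = seed,
                               dropped = c(st$dropped, dropped_t))),
            class = "phenotyping_result")
}

# Deterministic farthest-point (maximin) seeding: start from the point
# farthest from the centroid, then repeatedly add the point maximising the
# distance to the nearest chosen seed.
farthest_points <- function(coords, k) {
  ctr <- colMeans(coords)
  d0 <- sqrt(colSums((t(coords) - ctr)^2))
  chosen <- which.max(d0)
  while (length(chosen) < k) {
    D <- vapply(seq_len(nrow(coords)), function(i)
      min(sqrt(colSums((t(coords[chosen, , drop = FALSE]) - coords[i, ])^2))),
      numeric(1))
    D[chosen] <- -1
    chosen <- c(chosen, which.max(D))
  }
  chosen
}

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper over [mclust::adjustedRandIndex()] that optionally drops
#' noise points (label 0) present in either labeling.
#'
#' @param a,b label vectors of equal length.
#' @param drop_noise drop positions where either label is 0 (default TRUE).
#' @return adjusted Rand index.
#' @export
adjusted_rand <- function(a, b, drop_noise = TRUE) {
  if (drop_noise) {
    keep <- a != 0 & b != 0
    a <- a[keep]; b <- b[keep]
  }
  mclust::adjustedRandIndex(a, b)
}
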