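test_that("standardisation yields unit-variance columns and drops constants", {
  set.seed(3)
  X <- cbind(a = rnorm(30, 5, 2), b = runif(30), c = rep(4, 30))
  st <- standardize_features(X)
  expect_equal(st$dropped, "c")
  expect_lt(max(abs(colMeans(st$values))), 1e-9)
  expect_lt(max(abs(apply(st$values, 2, sd) - 1)), 1e-9)
})

test_that("MCFS retains d features and finds informative blob features", {
  bl <- blob_matrix(seed = 1)
  Xs <- standardize_features(bl$X)$values
  sel <- mcfs_select(Xs, d = 7)
  expect_length(sel$selected, 7)
  expect_true(all(order(-sel$scores)[1:2] %in% 1:2))
  # an exactly duplicated column receives the identical score
  Xd <- cbind(Xs, dup = Xs[, 1])
  seld <- mcfs_select(Xd, d = 7)
  expect_equal(unname(seld$scores["dup"]), unname(seld$scores[1]))
  expect_error(mcfs_select(Xs[1:5, ]), "10 subjects")
  expect_error(mcfs_select(Xs, d = 22), "smaller")
})

test_that("Laplacian embedding separates blobs and is deterministic", {
  bl <- blob_matrix(seed = 5)
  Xs <- standardize_features(bl$X[, 1:2])$values
  emb <- embed_laplacian(Xs)
  expect_equal(ncol(emb$coordinates), 2)
  expect_lt(abs(emb$trivial_eigenvalue), 1e-8)
  # the first coordinate's sign separates the two blobs perfectly
  side <- emb$coordinates[, 1] > mean(range(emb$coordinates[, 1]))
  expect_true(adjusted_rand(1 + side, bl$labels, drop_noise = FALSE) == 1)
  # duplicated subjects map to identical coordinates
  Xdup <- rbind(Xs, Xs[1:4, ])
  emb2 <- embed_laplacian(Xdup)
  expect_equal(emb2$coordinates[nrow(Xs) + 1:4, ], emb2$coordinates[1:4, ],
               tolerance = 1e-8)
  # sign convention: the largest-magnitude entry of each axis is positive
  for (j in 1:2) {
    v <- emb$coordinates[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  emb3 <- embed_laplacian(Xs)
  expect_identical(emb$coordinates, emb3$coordinates)
})

test_that("DBSCAN defaults follow the n/25 rule and recover blobs", {
  set.seed(8)
  co86 <- matrix(rnorm(86 * 2), 86)
  cl86 <- dbscan_cluster(co86)
  expect_equal(cl86$min_pts, 3L)
  cl100 <- dbscan_cluster(matrix(rnorm(200 * 2), 100))
  expect_equal(cl100$min_pts, 4L)
  cl30 <- dbscan_cluster(matrix(rnorm(60), 30))
  expect_equal(cl30$min_pts, 3L)
  # three well-separated Gaussian blobs: 3 clusters, no noise
  set.seed(2)
  lab <- rep(1:3, c(30, 25, 20))
  Y <- matrix(rnorm(150), 75)
  Y[, 1] <- Y[, 1] + c(0, 15, 30)[lab]
  cl <- dbscan_cluster(Y)
  expect_equal(cl$n_clusters, 3)
  expect_equal(sum(cl$labels == 0), 0)
  expect_equal(adjusted_rand(cl$labels, lab), 1)
  # labels are renumbered by descending size
  expect_equal(as.integer(table(cl$labels)), c(30, 25, 20))
  # eps = 0 marks everything as noise
  cl0 <- dbscan_cluster(Y, eps = 0)
  expect_equal(cl0$n_clusters, 0)
  expect_true(all(cl0$labels == 0))
})

test_that("DBSCAN equals the brute-force reachability oracle on small instances", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(10:30, 1)
    co <- matrix(rnorm(2 * n, sd = 1), n)
    if (rep %% 2 == 0) co[seq_len(n %/% 2), 1] <- co[seq_len(n %/% 2), 1] + 6
    for (eps in c(0.4, 0.9, 1.5)) {
      got <- dbscan_cluster(co, min_pts = 3, eps = eps)
      want <- dbscan_oracle(co, eps = eps, min_pts = 3)
      expect_identical(got$labels, want)
    }
  }
})

test_that("k-means cross-check scores agreement correctly", {
  set.seed(4)
  lab <- rep(1:3, each = 20)
  co <- matrix(rnorm(120, sd = 0.3), 60)
  co[, 1] <- co[, 1] + c(0, 5, 10)[lab]
  km <- crosscheck_kmeans(co, lab, seed = 1)
  expect_equal(km$ari, 1)
  expect_equal(km$k, 3)
  # identical label sets give ARI exactly 1
  expect_equal(adjusted_rand(lab, lab), 1)
  # the ARI null is centred at zero
  set.seed(10)
  nulls <- replicate(100, adjusted_rand(sample(lab), lab, drop_noise = FALSE))
  expect_lt(abs(mean(nulls)), 0.1)
  expect_error(crosscheck_kmeans(co, rep(1, 60)), "at least 2")
})

test_that("phenotyping is invariant to subject order and respects modes", {
  bl <- blob_matrix(seed = 13, n = 40, noise_cols = 12)
  X <- bl$X
  colnames(X) <- c(paste0("hermite_II_c", 0:3), paste0("hermite_V4_c", 0:3),
                   paste0("t_amp_V", 1:6))
  feats <- data.frame(subject_id = sprintf("S%02d", 1:40), X,
                      check.names = FALSE)
  attr(feats, "feature_types") <- feature_types(colnames(X))
  r <- run_phenotyping(feats, mode = "qrs_plus_t", seed = 1)
  perm <- sample(40)
  fp <- feats[perm, ]
  attr(fp, "feature_types") <- attr(feats, "feature_types")
  rp <- run_phenotyping(fp, mode = "qrs_plus_t", seed = 1)
  expect_equal(adjusted_rand(rp$labels, r$labels[perm], drop_noise = FALSE), 1)
  # qrs_only mode must not see the t_amp columns
  r2 <- run_phenotyping(feats, mode = "qrs_only", seed = 1, d = 1,
                        min_pts = 3)
  expect_true(all(grepl("^hermite_", r2$selected_features)))
  feats_no_t <- feats[, 1:3]
  attr(feats_no_t, "feature_types") <- feature_types(colnames(feats_no_t)[-1])
  expect_error(
    run_phenotyping(data.frame(subject_id = feats$subject_id,
                               qtc_ms = rnorm(40)),
                    mode = "qrs_only"), "no feature columns")
})

test_that("single-blob data yields one cluster", {
  set.seed(6)
  co <- matrix(rnorm(50 * 2, sd = 0.5), 50)
  cl <- dbscan_cluster(co)
  expect_equal(cl$n_clusters, 1)
  expect_lte(sum(cl$labels == 0), 2)
})
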