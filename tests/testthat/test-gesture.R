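test_that("time-domain features match closed forms", {
  fs <- 2000
  n <- 500
  zero_ds <- list(traces = list(new_emg_trace(matrix(0, n, 2), fs)),
                  labels = 1L)
  fz <- extract_features(zero_ds, epoch_len = n)
  expect_true(all(fz[paste0(c("mav", "rms", "zc", "ssc", "wl"),
                            "_ch1")] == 0))

  f0 <- 100
  t <- (0:(n - 1)) / fs
  amp <- 2
  sine_ds <- list(traces = list(new_emg_trace(
    matrix(amp * sin(2 * pi * f0 * t), ncol = 1), fs)), labels = 2L)
  fs_ <- extract_features(sine_ds, epoch_len = n)
  expect_equal(fs_$rms_ch1, amp / sqrt(2), tolerance = 1e-2)
  expect_equal(fs_$mav_ch1, amp * 2 / pi, tolerance = 1e-2)
  expect_equal(fs_$zc_ch1, 2 * f0 * n / fs, tolerance = 0.05)
})

test_that("feature extraction keeps dimensional bookkeeping", {
  cfg <- gesture_config(seed = 3)
  cfg$duration <- 0.25
  ds <- generate_gesture_dataset(cfg, n_trials_per_class = 10)
  feats <- extract_features(ds)  # 250 ms epochs: exactly one per trial
  expect_identical(nrow(feats), 40L)
  expect_length(feature_names <- setdiff(names(feats),
                                         c("label", "trial", "epoch")), 20L)
  expect_false(anyNA(feats))
  expect_error(extract_features(ds, epoch_len = 2000), "shorter")
})

test_that("PCA recovers rank, honours variance_keep and is sign-stable", {
  set.seed(10)
  basis <- matrix(rnorm(40), 20, 2)
  scores2 <- matrix(rnorm(120), 60, 2)
  x <- scores2 %*% t(basis)
  tbl <- tibble::as_tibble(as.data.frame(x))
  names(tbl) <- paste0("f", 1:20)
  p <- fit_pca(tbl, variance_keep = 0.999)
  expect_identical(p$k, 2L)

  pall <- fit_pca(tbl, variance_keep = 1)
  expect_identical(pall$k, 2L)  # only 2 nonzero-variance directions

  # reconstruction error equals the sum of discarded eigenvalues
  set.seed(11)
  xf <- matrix(rnorm(60 * 6), 60, 6)
  tbl2 <- tibble::as_tibble(as.data.frame(xf))
  p2 <- fit_pca(tbl2, variance_keep = 0.6)
  z <- scale(xf, p2$center, p2$scale)
  recon <- project_pca(p2, tbl2) %*% t(p2$rotation)
  err <- sum((z - recon)^2) / (nrow(xf) - 1)
  expect_equal(err, sum(p2$sdev[-seq_len(p2$k)]^2), tolerance = 1e-9)

  tbl3 <- tbl2
  tbl3$f7 <- 5
  expect_warning(p3 <- fit_pca(tbl3), "constant")
  expect_false("f7" %in% p3$feature_names)
})

test_that("class distances are Euclidean centroid distances", {
  scores <- rbind(c(0, 0), c(0, 0), c(3, 4), c(3, 4),
                  c(0, 0), c(0, 0), c(6, 8), c(0, 0))
  labels <- c(1, 1, 2, 2, 3, 3, 4, 4)
  d <- class_distances(scores, labels)
  expect_equal(d["1", "2"], 5)
  expect_equal(d["1", "3"], 0)
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_error(class_distances(scores[1:4, ], labels[1:4], classes = 1:4),
               "missing")
  # merged super-class centroid is the epoch-weighted mean of the union
  cents <- emgtwin:::group_centroids(scores, labels, list(c(2, 4)))
  expect_equal(cents[1, ], c(3, 4))
})

test_that("the tree merges closest classes first and separates blobs", {
  feats <- blob_features()
  model <- build_svm_tree(feats, variance_keep = 1)
  expect_identical(sort(unlist(model$merge_order[[1]]$merged)), c(1L, 2L))
  expect_length(model$nodes, 3L)
  # every class sits at exactly one leaf
  leaves <- c(model$nodes[[1]]$side_a,
              model$nodes[[2]]$side_a,
              model$nodes[[3]]$side_a, model$nodes[[3]]$side_b)
  expect_identical(sort(leaves), 1:4)
  expect_identical(predict(model, feats), as.integer(feats$label))

  model2 <- build_svm_tree(feats, variance_keep = 1)
  expect_identical(tidy(model2), tidy(model))

  few <- feats[c(which(feats$label == 1)[1], which(feats$label > 1)), ]
  expect_error(build_svm_tree(few), "fewer than 2")
  expect_error(build_svm_tree(feats[feats$label != 3, ]), "missing")
})

test_that("tree traversal agrees with a one-vs-one majority-vote oracle", {
  feats <- blob_features(n_per_class = 40, sd = 0.5, seed = 77)
  model <- build_svm_tree(feats, variance_keep = 1)
  test <- blob_features(n_per_class = 50, sd = 0.5, seed = 78)
  ours <- predict(model, test)
  # independent oracle: libsvm's native one-vs-one multiclass vote on the
  # same projected features
  scores <- project_pca(model$pca, feats)
  ovo <- e1071::svm(x = scores, y = factor(feats$label), kernel = "linear",
                    cost = 1, scale = FALSE)
  oracle <- as.integer(as.character(
    predict(ovo, project_pca(model$pca, test))))
  expect_gte(mean(ours == oracle), 0.99)
})

test_that("evaluation builds a conserved, permutation-equivariant confusion matrix", {
  feats <- blob_features(n_per_class = 30)
  test <- blob_features(n_per_class = 20, seed = 43)
  model <- build_svm_tree(feats, variance_keep = 1)
  cm <- evaluate_gestures(model, test)
  expect_identical(unname(rowSums(cm$table)), rep(20, 4))
  expect_equal(cm$accuracy, sum(diag(cm$table)) / sum(cm$table))
  expect_equal(cm$accuracy, 1)  # separable blobs

  # relabelling classes permutes the confusion matrix accordingly
  perm <- c(3L, 1L, 4L, 2L)  # new label of old class k
  relabel <- function(d) dplyr::mutate(d, label = perm[label])
  cmp <- evaluate_gestures(build_svm_tree(relabel(feats), variance_keep = 1),
                           relabel(test))
  expect_equal(unname(cmp$table[perm, perm]), unname(cm$table))
  expect_error(evaluate_gestures(model, feats[0, ]), "empty")
})

test_that("random guessing scores at chance on balanced classes", {
  set.seed(99)
  truth <- rep(1:4, each = 500)
  guess <- sample(1:4, 2000, replace = TRUE)
  acc <- mean(truth == guess)
  expect_lt(abs(acc - 0.25), 0.05)
})

test_that("accuracy grows with the generator's separability", {
  seps <- c(0.5, 1, 2, 3)
  means <- sapply(seps, function(sep) {
    mean(sapply(1:5, function(s) {
      run_gesture_pipeline(seed = s, n_trials_per_class = 15,
                           separability = sep)$accuracy
    }))
  })
  expect_true(all(diff(means) >= 0))
  expect_gte(means[4], 0.95)
})
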