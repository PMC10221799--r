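#' Time-domain features per epoch
#'
#' Cuts every trial into epochs and computes, per channel, the five standard
#' myoelectric time-domain features: mean absolute value (MAV), RMS, zero
#' crossings (ZC), slope-sign changes (SSC) and waveform length (WL).  ZC
#' and SSC use a dead band of three times a per-epoch noise standard
#' deviation estimate (robust MAD of the second difference), so baseline
#' noise does not register as activity.
#'
#' @param dataset A `gesture_dataset` from [generate_gesture_dataset()], or
#'   a list with `traces` and `labels`.
#' @param epoch_len Epoch length in samples (>= 64); default 250 ms at the
#'   trial rate.
#' @param overlap Fractional overlap between consecutive epochs in
#'   `[0, 1)`.
#' @return A tibble of class `feature_matrix`: columns `label`, `trial`,
#'   `epoch`, then `<feature>_<channel>` columns
#'   (`mav`/`rms`/`zc`/`ssc`/`wl` x channels).
#' @export
extract_features <- function(dataset, epoch_len = NULL, overlap = 0.5) {
  traces <- dataset$traces
  labels <- dataset$labels
  stopifnot(length(traces) == length(labels))
  if (length(traces) == 0L) {
    rlang::abort("empty dataset: no trials to featurise")
  }
  fs <- trace_fs(traces[[1]])
  if (!all(purrr::map_dbl(traces, trace_fs) == fs)) {
    rlang::abort("all trials must share one sampling rate")
  }
  epoch_len <- as.integer(epoch_len %||% round(0.25 * fs))
  if (epoch_len < 64L) rlang::abort("epoch_len must be at least 64 samples")
  if (overlap < 0 || overlap >= 1) rlang::abort("overlap must be in [0, 1)")
  hop <- max(1L, as.integer(round(epoch_len * (1 - overlap))))

  rows <- purrr::imap_dfr(traces, function(tr, i) {
    mat <- trace_matrix(tr)
    if (nrow(mat) < epoch_len) {
      rlang::abort(sprintf("trial %d shorter than one epoch", i))
    }
    starts <- seq(1L, nrow(mat) - epoch_len + 1L, by = hop)
    purrr::imap_dfr(starts, function(s, e_idx) {
      seg <- mat[s:(s + epoch_len - 1L), , drop = FALSE]
      feats <- unlist(lapply(seq_len(ncol(seg)), function(ch) {
        td_features(seg[, ch])
      }))
      names(feats) <- paste0(rep(c("mav", "rms", "zc", "ssc", "wl"),
                                 times = ncol(seg)),
                             "_ch", rep(seq_len(ncol(seg)), each = 5))
      tibble::as_tibble_row(c(label = labels[[i]], trial = i,
                              epoch = e_idx, feats))
    })
  })
  structure(rows, class = c("feature_matrix", class(rows)))
}

# MAV, RMS, ZC, SSC, WL for one epoch of one channel
td_features <- function(x) {
  n <- length(x)
  d2 <- diff(x, differences = 2)
  noise_sd <- stats::median(abs(d2)) / (0.6744898 * sqrt(6))
  thr <- 3 * noise_sd
  d1 <- diff(x)
  zc <- sum(x[-n] * x[-1] < 0 & abs(d1) >= thr)
  ssc <- if (n >= 3) {
    sum((x[2:(n - 1)] - x[1:(n - 2)]) * (x[2:(n - 1)] - x[3:n]) > thr^2)
  } else 0
  c(mav = mean(abs(x)), rms = sqrt(mean(x^2)), zc = zc, ssc = ssc,
    wl = sum(abs(d1)))
}

feature_cols <- function(features) {
  setdiff(names(features), c("label", "trial", "epoch"))
}

#' Fit the PCA projection of a feature matrix
#'
#' Standardised (centred, unit-variance) principal components; constant
#' feature columns are dropped with a warning before fitting.  The smallest
#' number of components whose cumulative explained variance reaches
#' `variance_keep` is retained, and each loading vector is sign-fixed so
#' its largest-magnitude entry is positive, making the projection
#' deterministic.
#'
#' @param features A `feature_matrix` from [extract_features()], or any
#'   data frame whose non-id columns are features.
#' @param variance_keep Cumulative explained-variance fraction to retain.
#' @return An `emg_pca`: loadings, centring/scaling vectors, component
#'   standard deviations, the retained count `k` and the explained-variance
#'   fractions.
#' @export
fit_pca <- function(features, variance_keep = 0.95) {
  check_number(variance_keep, "variance_keep", lower = 0, upper = 1,
               strict_lower = TRUE)
  x <- as.matrix(features[feature_cols(features)])
  if (nrow(x) < 2L) rlang::abort("need at least two epochs to fit a PCA")
  const <- apply(x, 2, function(col) diff(range(col)) == 0)
  if (any(const)) {
    rlang::warn(sprintf("dropping %d constant feature column(s): %s",
                        sum(const),
                        paste(colnames(x)[const], collapse = ", ")))
    x <- x[, !const, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  ev_frac <- ev / sum(ev)
  nonzero <- ev > max(ev) * 1e-12
  k <- which(cumsum(ev_frac) >= variance_keep - 1e-12)[1]
  if (variance_keep >= 1) k <- sum(nonzero)
  k <- min(k, sum(nonzero))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2, flip, "*")
  structure(
    list(rotation = rot, center = pc$center, scale = pc$scale,
         sdev = pc$sdev, explained = ev_frac, k = k,
         feature_names = colnames(x)),
    class = "emg_pca")
}

#' @export
print.emg_pca <- function(x, ...) {
  cat(sprintf("# emg_pca: %d of %d components (%.1f%% variance)\n",
              x$k, length(x$explained),
              100 * sum(x$explained[seq_len(x$k)])))
  invisible(x)
}

#' Project features into the retained PCA space
#'
#' @param pca An `emg_pca`.
#' @param features A feature matrix or data frame with the fitted columns.
#' @return A numeric score matrix, epochs x retained components.
#' @export
project_pca <- function(pca, features) {
  x <- as.matrix(features[pca$feature_names])
  scale(x, center = pca$center, scale = pca$scale) %*% pca$rotation
}

#' Euclidean distances between class centroids
#'
#' Inter-class distances in the retained PCA space, the quantity that
#' orders the binary tree.  Merged super-classes are handled by taking the
#' centroid of the union (the epoch-weighted mean of member centroids).
#'
#' @param scores Score matrix from [project_pca()].
#' @param labels Class label per row.
#' @param classes Which classes must be present (error if one is missing).
#' @return A symmetric distance matrix with zero diagonal, dimnames the
#'   class labels.
#' @export
class_distances <- function(scores, labels, classes = sort(unique(labels))) {
  missing <- setdiff(classes, unique(labels))
  if (length(missing)) {
    rlang::abort(paste("class(es) missing from labels:",
                       paste(missing, collapse = ", ")))
  }
  cents <- group_centroids(scores, labels, as.list(classes))
  d <- as.matrix(stats::dist(cents))
  dimnames(d) <- list(classes, classes)
  d
}

# centroids for a list of label groups (unions allowed), one row per group
group_centroids <- function(scores, labels, groups) {
  t(vapply(groups, function(g) {
    colMeans(scores[labels %in% g, , drop = FALSE])
  }, numeric(ncol(scores))))
}

#' Train the distance-ordered binary-tree SVM
#'
#' Implements the multiclass scheme used for the four gestures: (1) the two
#' closest classes in PCA space train the deepest separator, SVM3, and are
#' merged; (2) distances are recomputed and SVM2 is trained between the
#' merged super-class and its nearest remaining class, which is then merged
#' in; (3) SVM1 separates the final two super-classes.  Prediction walks
#' the tree from SVM1 downwards, emitting a leaf class as soon as a node
#' assigns its non-merged side.  Each node is a soft-margin binary SVM
#' (linear kernel, `C = 1` by default) on the PCA scores.  Distance ties
#' break toward the smallest class label, so refitting the same data always
#' yields the same tree.
#'
#' @param features A `feature_matrix` with labels in 1..4; every class
#'   needs at least two epochs.
#' @param variance_keep Passed to [fit_pca()].
#' @param kernel,cost Binary SVM kernel and soft-margin cost
#'   (see [e1071::svm()]).
#' @return An `svm_tree` model: the fitted `pca`, the three `nodes` (from
#'   SVM1 at the root down), and the recorded `merge_order` with the
#'   distances that chose each merge.
#' @export
build_svm_tree <- function(features, variance_keep = 0.95,
                           kernel = "linear", cost = 1) {
  labels <- features$label
  classes <- 1:4
  counts <- table(factor(labels, levels = classes))
  if (any(counts == 0)) {
    rlang::abort(paste("all four classes must be present; missing:",
                       paste(classes[counts == 0], collapse = ", ")))
  }
  if (any(counts < 2)) {
    rlang::abort(paste("class(es) with fewer than 2 epochs cannot train an SVM:",
                       paste(classes[counts < 2], collapse = ", ")))
  }
  pca <- fit_pca(features, variance_keep)
  scores <- project_pca(pca, features)

  groups <- lapply(classes, identity)  # active super-classes
  merge_order <- list()
  deep_nodes <- list()                 # SVM3 first, then SVM2, then SVM1
  while (length(groups) > 2L) {
    cents <- group_centroids(scores, labels, groups)
    d <- as.matrix(stats::dist(cents))
    if (length(merge_order) == 0L) {
      # first step: globally closest pair
      pair <- closest_pair(d, groups)
    } else {
      # later steps: the previously merged super-class (kept in slot 1)
      # against its nearest remaining class
      nn <- nearest_to(d, 1L, groups)
      pair <- c(1L, nn)
    }
    a <- groups[[pair[1]]]; b <- groups[[pair[2]]]
    if (length(merge_order) > 0L) {
      # non-root inner node: the leaf (non-merged) side must be side "a"
      # so traversal can emit it and descend into the merged branch
      a <- groups[[pair[2]]]; b <- groups[[pair[1]]]
    }
    deep_nodes[[length(deep_nodes) + 1L]] <-
      fit_node(scores, labels, side_a = a, side_b = b,
               kernel = kernel, cost = cost)
    merge_order[[length(merge_order) + 1L]] <-
      list(merged = list(a, b), distance = d[pair[1], pair[2]])
    merged <- sort(c(a, b))
    groups <- c(list(merged), groups[-pair])
  }
  # root: the final two super-classes; the merged branch is side_b so
  # traversal descends into it
  cents <- group_centroids(scores, labels, groups)
  root_leaf <- groups[[2]]
  root_merged <- groups[[1]]
  deep_nodes[[length(deep_nodes) + 1L]] <-
    fit_node(scores, labels, side_a = root_leaf, side_b = root_merged,
             kernel = kernel, cost = cost)
  nodes <- rev(deep_nodes)  # nodes[[1]] = SVM1 (root) ... nodes[[3]] = SVM3
  structure(
    list(pca = pca, nodes = nodes, merge_order = merge_order,
         classes = classes, kernel = kernel, cost = cost),
    class = "svm_tree")
}

closest_pair <- function(d, groups) {
  d[upper.tri(d, diag = TRUE)] <- Inf
  # ties toward the smallest class labels: order candidates lexicographically
  idx <- which(d == min(d), arr.ind = TRUE)
  key <- order(vapply(seq_len(nrow(idx)),
                      function(i) min(groups[[idx[i, 1]]], groups[[idx[i, 2]]]),
                      numeric(1)))[1]
  sort(idx[key, ])
}

nearest_to <- function(d, i, groups) {
  cand <- setdiff(seq_len(nrow(d)), i)
  best <- cand[d[i, cand] == min(d[i, cand])]
  best[order(vapply(best, function(j) min(groups[[j]]), numeric(1)))][1]
}

# one binary separator; side "a" is the leaf (non-merged) side at its node
fit_node <- function(scores, labels, side_a, side_b, kernel, cost) {
  sel <- labels %in% c(side_a, side_b)
  y <- factor(ifelse(labels[sel] %in% side_a, "a", "b"), levels = c("a", "b"))
  fit <- e1071::svm(x = scores[sel, , drop = FALSE], y = y,
                    kernel = kernel, cost = cost, scale = FALSE)
  list(svm = fit, side_a = side_a, side_b = side_b)
}

#' Predict gesture classes
#'
#' Traverses the tree from SVM1 down: at each node, epochs assigned to the
#' non-merged side take that leaf label; the rest descend into the merged
#' branch until the last node, whose two sides are both leaves.
#'
#' @param object An `svm_tree`.
#' @param newdata A `feature_matrix` (or data frame with the fitted feature
#'   columns).
#' @param ... Unused.
#' @return Integer class labels, one per epoch.
#' @export
predict.svm_tree <- function(object, newdata, ...) {
  if (!all(object$pca$feature_names %in% names(newdata))) {
    rlang::abort("newdata lacks the feature columns the model was fitted on")
  }
  scores <- project_pca(object$pca, newdata)
  out <- rep(NA_integer_, nrow(scores))
  todo <- seq_len(nrow(scores))
  for (i in seq_along(object$nodes)) {
    node <- object$nodes[[i]]
    if (!length(todo)) break
    pred <- stats::predict(node$svm, scores[todo, , drop = FALSE])
    is_a <- pred == "a"
    last <- i == length(object$nodes)
    out[todo[is_a]] <- node$side_a[1]
    if (last) {
      out[todo[!is_a]] <- node$side_b[1]
    }
    todo <- todo[!is_a]
  }
  out
}

#' @export
print.svm_tree <- function(x, ...) {
  cat("# svm_tree: distance-ordered binary tree of", length(x$nodes),
      "binary SVMs (", x$kernel, "kernel )\n")
  for (m in x$merge_order) {
    cat(sprintf("  merged {%s} with {%s} at distance %.3g\n",
                paste(m$merged[[1]], collapse = ","),
                paste(m$merged[[2]], collapse = ","), m$distance))
  }
  invisible(x)
}

#' @method tidy svm_tree
#' @export
tidy.svm_tree <- function(x, ...) {
  purrr::imap_dfr(x$nodes, function(nd, i) {
    tibble::tibble(node = paste0("SVM", i),
                   leaf_side = paste(nd$side_a, collapse = ","),
                   merged_side = paste(nd$side_b, collapse = ","),
                   n_support = sum(nd$svm$nSV))
  })
}

#' @method glance svm_tree
#' @export
glance.svm_tree <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$nodes),
                 pca_components = x$pca$k,
                 kernel = x$kernel, cost = x$cost)
}

#' Evaluate a gesture model on held-out epochs
#'
#' @param model An `svm_tree`.
#' @param features A disjoint `feature_matrix` with true labels.
#' @return A `confusion_matrix`: the 4 x 4 count table (rows = true,
#'   columns = predicted), overall `accuracy` and per-class `recall`.
#' @export
evaluate_gestures <- function(model, features) {
  if (nrow(features) == 0L) rlang::abort("empty test set")
  pred <- predict(model, features)
  truth <- factor(features$label, levels = model$classes)
  pred <- factor(pred, levels = model$classes)
  tab <- table(truth, pred)
  structure(
    list(table = unclass(tab),
         accuracy = sum(diag(tab)) / sum(tab),
         recall = diag(tab) / pmax(rowSums(tab), 1)),
    class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("# confusion_matrix: accuracy %.3f\n", x$accuracy))
  print(x$table)
  invisible(x)
}

#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame(as.table(x$table),
                                  responseName = "n"))
}

#' @method glance confusion_matrix
#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = sum(x$table),
                 min_recall = min(x$recall))
}

#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy.confusion_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted", y = "true", fill = "count")
}

#' End-to-end gesture pipeline for one seed
#'
#' Generates the default synthetic gesture dataset, extracts features,
#' splits trials 70/30 stratified by class, trains the PCA + tree SVM on
#' the training epochs and evaluates on the held-out epochs.
#'
#' @param seed Integer seed driving generation and the split.
#' @param config Generator configuration (see [gesture_config()]).
#' @param n_trials_per_class,separability Passed to
#'   [generate_gesture_dataset()].
#' @param train_frac Fraction of trials per class used for training.
#' @param variance_keep,kernel,cost Passed to [build_svm_tree()].
#' @return A list with the fitted `model`, the `confusion` matrix and the
#'   held-out `accuracy`.
#' @export
run_gesture_pipeline <- function(seed = 1L, config = NULL,
                                 n_trials_per_class = 40, separability = 3,
                                 train_frac = 0.7, variance_keep = 0.95,
                                 kernel = "linear", cost = 1) {
  config <- config %||% gesture_config(seed = seed)
  ds <- generate_gesture_dataset(config,
                                 n_trials_per_class = n_trials_per_class,
                                 separability = separability)
  features <- extract_features(ds)
  split <- stratified_trial_split(ds$labels, train_frac, seed)
  train <- features[features$trial %in% split$train, ]
  test <- features[features$trial %in% split$test, ]
  model <- build_svm_tree(train, variance_keep = variance_keep,
                          kernel = kernel, cost = cost)
  confusion <- evaluate_gestures(model, test)
  list(model = model, confusion = confusion,
       accuracy = confusion$accuracy)
}

# per-class random split of trial indices; deterministic given seed
stratified_trial_split <- function(labels, train_frac, seed) {
  idx_by_class <- split(seq_along(labels), labels)
  picks <- withr::with_seed(as.integer(seed) + 10000L, {
    lapply(idx_by_class, function(idx) {
      n_train <- max(1L, round(train_frac * length(idx)))
      sample(idx, n_train)
    })
  })
  train <- sort(unlist(picks))
  list(train = train, test = setdiff(seq_along(labels), train))
}
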