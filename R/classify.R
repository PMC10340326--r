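#' Euclidean distance between two feature vectors
#'
#' @param x1,x2 Numeric vectors of equal length.
#' @return `sqrt(sum((x1 - x2)^2))`.
#' @export
euclidean_distance <- function(x1, x2) {
  if (length(x1) != length(x2))
    stop("feature vectors must have equal length", call. = FALSE)
  sqrt(sum((x1 - x2)^2))
}

#' Classifier specification
#'
#' @param kind `"knn"`, `"dt"` or `"svm"`.
#' @param knn_k Neighbor count for KNN (default 5).
#' @param svm_C Soft-margin penalty parameter C for the linear SVM (default 1).
#' @param dt_maxdepth,dt_minsplit,dt_cp Decision-tree growth controls
#'   (defaults: depth 30, minimum split size 2, complexity 0 — the tree grows
#'   until nodes are pure or depth-limited).
#' @param seed Seed fixing any stochastic classifier state.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(kind = c("knn", "dt", "svm"), knn_k = 5L,
                            svm_C = 1, dt_maxdepth = 30L, dt_minsplit = 2L,
                            dt_cp = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (knn_k < 1L) stop("knn_k must be >= 1", call. = FALSE)
  if (!(svm_C > 0)) stop("svm_C must be > 0", call. = FALSE)
  structure(list(kind = kind, knn_k = as.integer(knn_k), svm_C = svm_C,
                 dt_maxdepth = as.integer(dt_maxdepth),
                 dt_minsplit = as.integer(dt_minsplit), dt_cp = dt_cp,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

check_training_input <- function(x, y) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty training set", call. = FALSE)
  if (nrow(x) != length(y))
    stop("need one label per training row", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  x
}

#' K-nearest-neighbour classifier
#'
#' Majority vote among the `knn_k` training points nearest in Euclidean
#' distance. The prediction is deterministic: neighbour ranking ties break by
#' training index; vote ties break in favour of the class whose neighbours
#' have the smaller summed distance, then by alphabetical label order.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Class labels.
#' @param spec A [classifier_spec()] with `kind = "knn"`.
#' @return `knn_train()` a model object; `knn_predict()` a character vector of
#'   predicted labels.
#' @export
knn_train <- function(x, y, spec = classifier_spec("knn")) {
  x <- check_training_input(x, y)
  if (spec$knn_k > nrow(x))
    stop("knn_k exceeds the training-set size", call. = FALSE)
  structure(list(x = x, y = as.character(y), k = spec$knn_k),
            class = "knn_model")
}

#' @rdname knn_train
#' @param model A fitted `knn_model`.
#' @param newx Feature matrix of query samples.
#' @export
knn_predict <- function(model, newx) {
  newx <- matrix(as.numeric(newx), ncol = ncol(model$x))
  classes <- sort(unique(model$y))
  apply(newx, 1L, function(q) {
    d <- sqrt(colSums((t(model$x) - q)^2))
    nn <- order(d, seq_along(d))[seq_len(model$k)]
    votes <- table(factor(model$y[nn], levels = classes))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(cl) sum(d[nn][model$y[nn] == cl]),
                     numeric(1))
      top <- top[order(sums, top)]
    }
    top[1L]
  })
}

#' Decision-tree classifier (Gini, recursive binary partitioning)
#'
#' Axis-aligned binary recursive partitioning on Gini impurity: each node
#' takes the split (feature, midpoint threshold) with the largest impurity
#' decrease, breaking ties by lowest feature index then lowest threshold.
#' While a node is impure, a split is taken even when the immediate impurity
#' decrease is zero (so interaction structure like XOR is still resolved);
#' growth stops at pure nodes, at `dt_minsplit`/`dt_maxdepth`, or when every
#' feature is constant, and splits whose decrease falls below `dt_cp` are
#' rejected. Each leaf predicts its majority class (ties to the
#' alphabetically first label). Fully deterministic.
#'
#' @inheritParams knn_train
#' @return `dt_train()` a model object; `dt_predict()` predicted labels.
#' @export
dt_train <- function(x, y, spec = classifier_spec("dt")) {
  x <- check_training_input(x, y)
  classes <- sort(unique(as.character(y)))
  y <- as.character(y)

  gini <- function(counts) 1 - sum((counts / sum(counts))^2)

  best_split <- function(rows) {
    n <- length(rows)
    parent_counts <- table(factor(y[rows], levels = classes))
    parent_gini <- gini(parent_counts)
    best <- NULL
    for (j in seq_len(ncol(x))) {
      xj <- x[rows, j]
      ord <- order(xj)
      xs <- xj[ord]
      boundary <- which(xs[-n] < xs[-1])  # split between distinct values
      if (length(boundary) == 0L) next
      yl <- matrix(0, nrow = n, ncol = length(classes))
      yl[cbind(seq_len(n), match(y[rows][ord], classes))] <- 1
      cum <- apply(yl, 2L, cumsum)
      left <- cum[boundary, , drop = FALSE]
      right <- rep(parent_counts, each = length(boundary)) - left
      nl <- boundary; nr <- n - boundary
      gl <- 1 - rowSums((left / nl)^2)
      gr <- 1 - rowSums((right / nr)^2)
      decrease <- parent_gini - (nl * gl + nr * gr) / n
      bi <- which.max(decrease)  # ties -> lowest threshold
      if (decrease[bi] < spec$dt_cp) next
      if (is.null(best) || decrease[bi] > best$decrease + 1e-12) {
        best <- list(feature = j,
                     threshold = (xs[boundary[bi]] + xs[boundary[bi] + 1L]) / 2,
                     decrease = decrease[bi])
      }
    }
    best
  }

  grow <- function(rows, depth) {
    counts <- table(factor(y[rows], levels = classes))
    majority <- classes[which.max(counts)]
    pure <- sum(counts > 0L) == 1L
    if (pure || length(rows) < spec$dt_minsplit || depth >= spec$dt_maxdepth)
      return(list(leaf = TRUE, label = majority))
    split <- best_split(rows)
    if (is.null(split)) return(list(leaf = TRUE, label = majority))
    go_left <- x[rows, split$feature] <= split$threshold
    list(leaf = FALSE, feature = split$feature, threshold = split$threshold,
         left = grow(rows[go_left], depth + 1L),
         right = grow(rows[!go_left], depth + 1L))
  }

  structure(list(tree = grow(seq_len(nrow(x)), 0L), p = ncol(x)),
            class = "dt_model")
}

#' @rdname dt_train
#' @param model A fitted `dt_model`.
#' @param newx Feature matrix of query samples.
#' @export
dt_predict <- function(model, newx) {
  newx <- matrix(as.numeric(newx), ncol = model$p)
  descend <- function(node, row) {
    while (!node$leaf) {
      node <- if (row[node$feature] <= node$threshold) node$left else node$right
    }
    node$label
  }
  vapply(seq_len(nrow(newx)), function(i) descend(model$tree, newx[i, ]),
         character(1))
}

#' Soft-margin linear support vector machine
#'
#' Minimizes `0.5 * ||w||^2 + C * sum(xi)` subject to
#' `y_i (w'x_i + b) >= 1 - xi_i`, `xi_i >= 0`, with labels mapped to
#' `{-1, +1}`; prediction is `sign(w'x + b)`. Solved with the libsvm dual
#' solver (\pkg{e1071}) on unscaled features.
#'
#' @inheritParams knn_train
#' @return `svm_train()` a model object; `svm_predict()` predicted labels.
#' @export
svm_train <- function(x, y, spec = classifier_spec("svm")) {
  x <- check_training_input(x, y)
  set.seed(spec$seed)
  fit <- e1071::svm(x = x, y = factor(y), kernel = "linear",
                    cost = spec$svm_C, scale = FALSE)
  structure(list(fit = fit, p = ncol(x)), class = "svm_model")
}

#' @rdname svm_train
#' @param model A fitted `svm_model`.
#' @param newx Feature matrix of query samples.
#' @export
svm_predict <- function(model, newx) {
  newx <- matrix(as.numeric(newx), ncol = model$p)
  colnames(newx) <- colnames(model$fit$SV)
  as.character(predict(model$fit, newdata = newx))
}

#' Hyperplane of a fitted linear SVM
#'
#' @param model A fitted `svm_model`.
#' @return List with weight vector `w` and offset `b` such that the decision
#'   value for the model's first factor level is `w'x + b`.
#' @export
svm_hyperplane <- function(model) {
  w <- drop(t(model$fit$coefs) %*% model$fit$SV)
  list(w = w, b = -model$fit$rho)
}

train_classifier <- function(spec, x, y) {
  switch(spec$kind,
         knn = knn_train(x, y, spec),
         dt = dt_train(x, y, spec),
         svm = svm_train(x, y, spec))
}

predict_classifier <- function(model, newx) {
  switch(class(model),
         knn_model = knn_predict(model, newx),
         dt_model = dt_predict(model, newx),
         svm_model = svm_predict(model, newx))
}

#' Stratified k-fold assignment
#'
#' Each class is shuffled under the seed and dealt round-robin into the folds,
#' with the dealing pointer carried across classes so total fold sizes also
#' differ by at most one. Per-class fold sizes differ by at most one sample,
#' so every fold preserves the overall class proportions.
#'
#' @param labels Class label per sample.
#' @param k Number of folds (>= 2); every class must have at least `k` members.
#' @param seed Shuffle seed.
#' @return A `fold_assignment`: integer fold index (1..k) per sample plus `k`.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  counts <- table(labels)
  if (any(counts < k))
    stop(sprintf("class '%s' has fewer than k = %d members",
                 names(counts)[which.min(counts)], k), call. = FALSE)
  set.seed(seed)
  fold <- integer(length(labels))
  ptr <- 0L
  for (cl in sort(unique(as.character(labels)))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((ptr + seq_along(idx) - 1L) %% k) + 1L
    ptr <- (ptr + length(idx)) %% k
  }
  structure(list(fold = fold, k = k), class = "fold_assignment")
}

#' Confusion counts for a binary prediction
#'
#' @param y_true,y_pred Equal-length label vectors over the two known classes.
#' @param positive The positive class (default `"geo_authentic"`).
#' @return A `confusion_counts` object with fields TP, FN, TN, FP.
#' @export
confusion <- function(y_true, y_pred, positive = "geo_authentic") {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  known <- unique(c(y_true, y_pred))
  if (!positive %in% y_true)
    stop("positive class absent from y_true", call. = FALSE)
  if (length(known) > 2L)
    stop("labels must come from exactly two classes", call. = FALSE)
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  structure(list(TP = tp, FN = fn, TN = tn, FP = fp),
            class = "confusion_counts")
}

add_confusion <- function(a, b) {
  structure(list(TP = a$TP + b$TP, FN = a$FN + b$FN, TN = a$TN + b$TN,
                 FP = a$FP + b$FP), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' `ACC = (TP + TN) / total * 100`, `SEN = REC = TP / (TP + FN) * 100`
#' (percentages); `PRE = TP / (TP + FP)` and
#' `F1 = 2 * PRE * REC / (PRE + REC)` (fractions, with recall as a fraction
#' inside F1). Any 0/0 ratio is defined as 0 and reported with a message.
#'
#' @param counts A [confusion()] result.
#' @return List with ACC, SEN (percent), PRE, REC, F1 (fractions; `SEN ==
#'   REC * 100`).
#' @export
compute_metrics <- function(counts) {
  total <- counts$TP + counts$FN + counts$TN + counts$FP
  if (total == 0L) stop("no evaluated samples", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      message(sprintf("0/0 in %s defined as 0", what))
      return(0)
    }
    num / den
  }
  rec <- safe_div(counts$TP, counts$TP + counts$FN, "recall")
  pre <- safe_div(counts$TP, counts$TP + counts$FP, "precision")
  f1 <- safe_div(2 * pre * rec, pre + rec, "F1")
  list(ACC = (counts$TP + counts$TN) / total * 100,
       SEN = rec * 100, PRE = pre, REC = rec, F1 = f1)
}

#' Run one experiment regime under stratified cross-validation
#'
#' Builds the regime's features, assigns stratified folds, trains on each
#' training portion and predicts its held-out fold, and reports per-fold and
#' pooled confusion counts and metrics plus the total train + predict wall
#' time. Regimes mirror the study design: `exp1_raw` classifies the cropped
#' intensity vectors; `exp2_preprocessed` additionally excises the solvent
#' regions; `exp3_lbp` renders each preprocessed spectrum to a grayscale
#' image and classifies its riu2 LBP histogram.
#'
#' @param dataset A labeled `nmr_dataset`.
#' @param regime `"exp1_raw"`, `"exp2_preprocessed"` or `"exp3_lbp"`.
#' @param classifier A [classifier_spec()].
#' @param k Fold count (default 5).
#' @param seed Seed for the fold assignment.
#' @param preprocess A [preprocess_spec()]; defaults to the regime's standard
#'   crop/exclusion settings.
#' @param render A [render_spec()] (exp3 only).
#' @param lbp An [lbp_config()] (exp3 only).
#' @param positive Positive class label.
#' @return An `evaluation_report`: per-fold counts and metrics, pooled counts
#'   and metrics, fold-mean metrics, and `elapsed_seconds`.
#' @export
run_experiment <- function(dataset,
                           regime = c("exp1_raw", "exp2_preprocessed", "exp3_lbp"),
                           classifier = classifier_spec("svm"), k = 5L,
                           seed = 1L, preprocess = NULL,
                           render = render_spec(), lbp = lbp_config(),
                           positive = "geo_authentic") {
  regime <- match.arg(regime)
  if (anyNA(dataset$labels))
    stop("dataset must be fully labeled", call. = FALSE)
  if (is.null(preprocess)) {
    preprocess <- default_preprocess_spec(if (regime == "exp1_raw") 1L else 2L)
  }
  features <- build_features(dataset, regime, preprocess, render, lbp)
  y <- dataset$labels
  folds <- stratified_kfold(y, k, seed = seed)

  fold_counts <- vector("list", k)
  fold_metrics <- vector("list", k)
  pooled <- structure(list(TP = 0L, FN = 0L, TN = 0L, FP = 0L),
                      class = "confusion_counts")
  elapsed <- 0
  for (f in seq_len(k)) {
    test <- folds$fold == f
    t0 <- proc.time()[["elapsed"]]
    model <- train_classifier(classifier, features[!test, , drop = FALSE],
                              y[!test])
    pred <- predict_classifier(model, features[test, , drop = FALSE])
    elapsed <- elapsed + (proc.time()[["elapsed"]] - t0)
    cc <- confusion(y[test], pred, positive = positive)
    fold_counts[[f]] <- cc
    fold_metrics[[f]] <- compute_metrics(cc)
    pooled <- add_confusion(pooled, cc)
  }
  fold_mean <- as.list(colMeans(do.call(rbind, lapply(fold_metrics, unlist))))
  structure(list(regime = regime, classifier = classifier$kind, k = k,
                 folds = folds, fold_counts = fold_counts,
                 fold_metrics = fold_metrics, pooled_counts = pooled,
                 pooled_metrics = compute_metrics(pooled),
                 fold_mean_metrics = fold_mean,
                 elapsed_seconds = elapsed),
            class = "evaluation_report")
}

build_features <- function(dataset, regime, preprocess, render, lbp) {
  pp <- preprocess_apply(preprocess, dataset)
  if (regime %in% c("exp1_raw", "exp2_preprocessed")) {
    feats <- t(pp$intensities)
  } else {
    feats <- lbp_features(rasterize_dataset(pp, render), lbp)
  }
  rownames(feats) <- dataset$sample_ids
  feats
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$pooled_metrics
  cat(sprintf("<evaluation_report> %s / %s, %d-fold CV\n", x$regime,
              x$classifier, x$k))
  cat(sprintf("  pooled: ACC %.2f%%  SEN %.2f%%  F1 %.4f  (%.2fs train+predict)\n",
              m$ACC, m$SEN, m$F1, x$elapsed_seconds))
  invisible(x)
}

#' Flatten an evaluation report to a one-row summary
#'
#' Columns mirror the result table of the study design: experiment, classifier,
#' pooled Accuracy (%), Sensitivity (%) and F1-score, plus fold-mean values
#' and wall time.
#'
#' @param report An `evaluation_report`.
#' @return A one-row `data.frame`.
#' @export
summarize_report <- function(report) {
  pm <- report$pooled_metrics
  fm <- report$fold_mean_metrics
  data.frame(experiment = report$regime, classifier = report$classifier,
             accuracy = pm$ACC, sensitivity = pm$SEN, f1_score = pm$F1,
             fold_mean_accuracy = fm$ACC, fold_mean_sensitivity = fm$SEN,
             fold_mean_f1 = fm$F1, seconds = report$elapsed_seconds)
}
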