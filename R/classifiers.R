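#' Classifier model specifications
#'
#' A `har_model_spec` names a model family and its hyperparameters. The
#' families mirror the classical suite compared for on-phone activity
#' recognition: nearest centroid, a CART decision tree, a bagged random
#' forest, k-nearest neighbors, a one-vs-rest linear support-vector machine,
#' and feed-forward neural networks with one or two hidden layers. All are
#' implemented in base R.
#'
#' @param family one of `"nearest_centroid"`, `"decision_tree"`,
#'   `"random_forest"`, `"knn"`, `"svm"`, `"nnet"`.
#' @param label display label.
#' @param ... family-specific hyperparameters (e.g. `k`, `ntree`,
#'   `max_depth`, `hidden`, `alpha`, `lambda`).
#' @return an object of class `har_model_spec`.
#' @export
model_spec <- function(family, label = family, ...) {
  known <- c("nearest_centroid", "decision_tree", "random_forest",
             "knn", "svm", "nnet")
  if (!family %in% known) {
    har_stop(sprintf("unknown model family '%s' (known: %s)",
                     family, paste(known, collapse = ", ")),
             "weakhar_config_error")
  }
  structure(list(family = family, label = label, params = list(...)),
            class = "har_model_spec")
}

#' The seven-model comparison suite
#'
#' Nearest centroid, decision tree, random forest, kNN (k = 5), multi-class
#' linear SVM, and two network topologies: one hidden layer of 12 units and
#' two hidden layers of 36 and 12 units (18 inputs, 5 outputs).
#'
#' @return named list of 7 [model_spec()] objects.
#' @export
model_suite <- function() {
  list(
    nearest_centroid = model_spec("nearest_centroid", "Nearest Centroid"),
    decision_tree    = model_spec("decision_tree", "DT", max_depth = 20),
    random_forest    = model_spec("random_forest", "Random Forests",
                                  ntree = 50, max_depth = 20),
    knn              = model_spec("knn", "kNN", k = 5),
    svm              = model_spec("svm", "Multi-class SVM", lambda = 1e-3),
    nnet_12          = model_spec("nnet", "NN 18x12x6", hidden = c(12), alpha = 0.01),
    nnet_36_12       = model_spec("nnet", "NN 18x36x12x6", hidden = c(36, 12),
                                  alpha = 0.01)
  )
}

#' Fit a model
#'
#' @param spec a [model_spec()].
#' @param x numeric feature matrix (rows = samples; standardize upstream —
#'   [run_cv()] does).
#' @param y character class labels (training labels; in the weak-label
#'   protocol these are the heuristic's labels, never the manual ones).
#' @param seed integer seed for the stochastic families.
#' @return a fitted model object (class `har_model`).
#' @export
har_fit <- function(spec, x, y, seed = 1) {
  x <- as.matrix(x)
  classes <- intersect(HAR_ACTIVITIES, unique(y))
  if (!length(classes)) classes <- sort(unique(y))
  yi <- match(y, classes)
  fit <- withr::with_seed(seed, switch(
    spec$family,
    nearest_centroid = fit_centroid(x, yi, length(classes)),
    decision_tree = fit_tree_model(x, yi, length(classes), spec$params),
    random_forest = fit_forest(x, yi, length(classes), spec$params),
    knn = list(x = x, y = yi, k = spec$params$k %||% 5),
    svm = fit_svm_ovr(x, yi, length(classes), spec$params),
    nnet = fit_mlp(x, yi, length(classes), spec$params)
  ))
  structure(list(family = spec$family, label = spec$label,
                 classes = classes, fit = fit),
            class = "har_model")
}

#' Predict class labels
#'
#' @param model a fitted `har_model`.
#' @param x numeric feature matrix.
#' @return character vector of predicted labels.
#' @export
har_predict <- function(model, x) {
  x <- as.matrix(x)
  yi <- switch(model$family,
    nearest_centroid = predict_centroid(model$fit, x),
    decision_tree = predict_tree(model$fit$tree, x),
    random_forest = predict_forest(model$fit, x),
    knn = predict_knn(model$fit, x),
    svm = predict_svm_ovr(model$fit, x),
    nnet = predict_mlp(model$fit, x))
  model$classes[yi]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- nearest centroid -------------------------------------------------

fit_centroid <- function(x, yi, K) {
  cent <- t(vapply(seq_len(K), function(k) colMeans(x[yi == k, , drop = FALSE]),
                   numeric(ncol(x))))
  list(centroids = cent)
}

predict_centroid <- function(fit, x) {
  d <- sq_dist(x, fit$centroids)
  max.col(-d, ties.method = "first")
}

sq_dist <- function(a, b) {
  # squared Euclidean distances, rows of a vs rows of b
  an <- rowSums(a^2); bn <- rowSums(b^2)
  outer(an, bn, `+`) - 2 * tcrossprod(a, b)
}

## ---- kNN ---------------------------------------------------------------

predict_knn <- function(fit, x) {
  d <- sq_dist(x, fit$x)
  k <- min(fit$k, ncol(d))
  K <- max(fit$y)
  apply_rows <- vapply(seq_len(nrow(d)), function(i) {
    nn <- order(d[i, ])[seq_len(k)]
    votes <- tabulate(fit$y[nn], nbins = K)
    top <- which(votes == max(votes))
    if (length(top) > 1) {
      # tie: smaller summed distance among tied classes, then class priority
      sums <- vapply(top, function(cl) sum(d[i, nn[fit$y[nn] == cl]]), numeric(1))
      top <- top[order(sums)][1]
    }
    as.integer(top[1])
  }, integer(1))
  apply_rows
}

## ---- CART decision tree ------------------------------------------------

fit_tree_model <- function(x, yi, K, params) {
  list(tree = build_tree(x, yi, K,
                         max_depth = params$max_depth %||% 20,
                         min_split = params$min_split %||% 4,
                         min_bucket = params$min_bucket %||% 2,
                         mtry = params$mtry %||% ncol(x)))
}

build_tree <- function(x, yi, K, max_depth, min_split, min_bucket, mtry, depth = 0) {
  n <- length(yi)
  counts <- tabulate(yi, nbins = K)
  majority <- which.max(counts)
  if (n < min_split || depth >= max_depth || counts[majority] == n) {
    return(list(leaf = TRUE, class = majority))
  }
  sp <- best_split(x, yi, K, mtry, min_bucket)
  if (is.null(sp)) return(list(leaf = TRUE, class = majority))
  go_left <- x[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = build_tree(x[go_left, , drop = FALSE], yi[go_left], K,
                         max_depth, min_split, min_bucket, mtry, depth + 1),
       right = build_tree(x[!go_left, , drop = FALSE], yi[!go_left], K,
                          max_depth, min_split, min_bucket, mtry, depth + 1))
}

best_split <- function(x, yi, K, mtry, min_bucket) {
  p <- ncol(x); n <- length(yi)
  feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
  best <- NULL; best_score <- Inf
  for (j in feats) {
    xs <- x[, j]
    ord <- order(xs)
    xo <- xs[ord]; yo <- yi[ord]
    oh <- matrix(0, n, K); oh[cbind(seq_len(n), yo)] <- 1
    cum <- apply(oh, 2, cumsum)
    i <- seq_len(n - 1)
    ln <- i; rn <- n - i
    gl <- 1 - rowSums((cum[i, , drop = FALSE] / ln)^2)
    right <- sweep(-cum[i, , drop = FALSE], 2, cum[n, ], `+`)
    gr <- 1 - rowSums((right / rn)^2)
    score <- (ln * gl + rn * gr) / n
    valid <- xo[i] < xo[i + 1] & ln >= min_bucket & rn >= min_bucket
    if (!any(valid)) next
    score[!valid] <- Inf
    m <- which.min(score)
    if (score[m] < best_score - 1e-12) {
      best_score <- score[m]
      best <- list(feature = j, threshold = (xo[m] + xo[m + 1]) / 2)
    }
  }
  # refuse splits that do not improve node impurity
  node_gini <- 1 - sum((tabulate(yi, K) / n)^2)
  if (!is.null(best) && best_score >= node_gini - 1e-12) best <- NULL
  best
}

predict_tree <- function(tree, x) {
  out <- integer(nrow(x))
  recurse <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$class; return() }
    left <- x[idx, node$feature] <= node$threshold
    recurse(node$left, idx[left])
    recurse(node$right, idx[!left])
  }
  recurse(tree, seq_len(nrow(x)))
  out
}

## ---- random forest (bagged CART with feature subsampling) --------------

fit_forest <- function(x, yi, K, params) {
  ntree <- params$ntree %||% 50
  mtry <- params$mtry %||% max(1, floor(sqrt(ncol(x))))
  trees <- lapply(seq_len(ntree), function(b) {
    idx <- sample.int(length(yi), replace = TRUE)
    build_tree(x[idx, , drop = FALSE], yi[idx], K,
               max_depth = params$max_depth %||% 20,
               min_split = params$min_split %||% 2,
               min_bucket = params$min_bucket %||% 1,
               mtry = mtry)
  })
  list(trees = trees, K = K)
}

predict_forest <- function(fit, x) {
  votes <- matrix(0L, nrow(x), fit$K)
  for (tr in fit$trees) {
    pred <- predict_tree(tr, x)
    votes[cbind(seq_len(nrow(x)), pred)] <- votes[cbind(seq_len(nrow(x)), pred)] + 1L
  }
  max.col(votes, ties.method = "first")
}

## ---- one-vs-rest linear SVM (squared hinge, full-batch GD) -------------

fit_svm_ovr <- function(x, yi, K, params) {
  lambda <- params$lambda %||% 1e-3
  iters <- params$iters %||% 300
  lr <- params$lr %||% 0.05
  xb <- cbind(x, 1)
  W <- matrix(0, ncol(xb), K)
  for (k in seq_len(K)) {
    yk <- ifelse(yi == k, 1, -1)
    w <- numeric(ncol(xb))
    step <- lr
    for (it in seq_len(iters)) {
      m <- yk * drop(xb %*% w)
      act <- m < 1
      grad <- if (any(act)) {
        lambda * w -
          2 * colSums(xb[act, , drop = FALSE] * ((1 - m[act]) * yk[act])) / length(yk)
      } else lambda * w
      w <- w - step * grad
      step <- step * 0.995
    }
    W[, k] <- w
  }
  list(W = W)
}

predict_svm_ovr <- function(fit, x) {
  scores <- cbind(x, 1) %*% fit$W
  max.col(scores, ties.method = "first")
}

## ---- feed-forward neural network (ReLU, softmax, Adam) -----------------

fit_mlp <- function(x, yi, K, params) {
  hidden <- params$hidden %||% c(12)
  alpha <- params$alpha %||% 0.01
  epochs <- params$epochs %||% 300
  lr <- params$lr %||% 0.01
  patience <- params$patience %||% 30
  sizes <- c(ncol(x), hidden, K)
  L <- length(sizes) - 1
  W <- lapply(seq_len(L), function(l) {
    matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1])
  })
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  n <- nrow(x)
  Yoh <- matrix(0, n, K); Yoh[cbind(seq_len(n), yi)] <- 1
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best_loss <- Inf; stall <- 0
  for (ep in seq_len(epochs)) {
    # forward
    A <- vector("list", L + 1); A[[1]] <- x
    for (l in seq_len(L)) {
      Zl <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], `+`)
      A[[l + 1]] <- if (l < L) pmax(Zl, 0) else Zl
    }
    Zout <- A[[L + 1]]
    Zs <- Zout - apply(Zout, 1, max)
    P <- exp(Zs); P <- P / rowSums(P)
    loss <- -mean(log(pmax(P[cbind(seq_len(n), yi)], 1e-12))) +
      alpha * 0.5 * sum(vapply(W, function(w) sum(w^2), numeric(1))) / n
    if (loss < best_loss - 1e-8) { best_loss <- loss; stall <- 0 } else stall <- stall + 1
    if (stall >= patience) break
    # backward
    delta <- (P - Yoh) / n
    for (l in rev(seq_len(L))) {
      gW <- crossprod(A[[l]], delta) + alpha * W[[l]] / n
      gb <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      mhW <- mW[[l]] / (1 - beta1^ep); vhW <- vW[[l]] / (1 - beta2^ep)
      mhb <- mb[[l]] / (1 - beta1^ep); vhb <- vb[[l]] / (1 - beta2^ep)
      W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
      b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
  }
  list(W = W, b = b)
}

predict_mlp <- function(fit, x) {
  A <- x
  L <- length(fit$W)
  for (l in seq_len(L)) {
    A <- sweep(A %*% fit$W[[l]], 2, fit$b[[l]], `+`)
    if (l < L) A <- pmax(A, 0)
  }
  max.col(A, ties.method = "first")
}
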