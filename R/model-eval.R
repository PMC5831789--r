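# Classification and evaluation: own ROC/AUC implementation, classifier
# adapters (random forest via ranger by default; SVM, naive Bayes, CART,
# neural network),
# stratified k-fold cross-validation over feature-set combinations, and
# cross-product pair scoring.

#' ROC curve and AUC
#'
#' The AUC is computed as the Mann-Whitney rank statistic (ties contribute
#' 1/2): the probability that a random positive scores above a random
#' negative. The curve is a threshold sweep over the unique scores, from
#' (0, 0) to (1, 1); its trapezoidal area equals the rank AUC.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels 0/1 labels (or logical).
#' @return Object of class `roc_result`: list with `points` (data.frame
#'   `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(.9, .8, .4, .3), c(1, 1, 0, 0))$auc  # 1
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    gpcr_stop("scores and labels differ in length", "gpcr_evaluation_error")
  if (anyNA(scores) || anyNA(labels) || !all(labels %in% c(0L, 1L)))
    gpcr_stop("labels must be 0/1 and scores non-missing", "gpcr_evaluation_error")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    gpcr_stop("both classes must be present to compute a ROC curve",
              "gpcr_evaluation_error")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # cumulative counts at each distinct threshold
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_tie]
  fp <- cumsum(1L - l)[last_of_tie]
  points <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

# trapezoidal area under an ROC point set (internal; equals the rank AUC)
trapezoid_area <- function(points) {
  dx <- diff(points$fpr)
  sum(dx * (head(points$tpr, -1) + points$tpr[-1]) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positives, %d negatives, %d points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l",
       xlab = "False positive rate", ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

ALGORITHMS <- c("random_forest", "svm", "naive_bayes", "cart", "neural_network")

#' Train a binding classifier
#'
#' Adapters around standard implementations, all exposing the same
#' `probability-of-binding` scoring contract: random forest
#' (\pkg{ranger}, probability forest), SVM (\pkg{e1071}, probability model),
#' naive Bayes
#' (\pkg{e1071}), CART (\pkg{rpart}) and a single-hidden-layer neural
#' network (\pkg{nnet}). Hyperparameters are the underlying defaults,
#' recorded in the returned handle; zero-variance columns are dropped for
#' the scale-sensitive learners (SVM, naive Bayes, neural network).
#'
#' @param dataset A `binding_dataset` (or list with `X` and `y`).
#' @param algorithm One of `"random_forest"`, `"svm"`, `"naive_bayes"`,
#'   `"cart"`, `"neural_network"`.
#' @param seed Integer seed (training is deterministic given it).
#' @param feature_tags Optional feature-set tags to train on.
#' @param ... Passed to the underlying fitting function.
#' @return Object of class `gpcr_model` with a [predict_scores()] method.
#' @export
train <- function(dataset, algorithm = "random_forest", seed = 1L,
                  feature_tags = NULL, ...) {
  if (!algorithm %in% ALGORITHMS)
    gpcr_stop(sprintf("unknown algorithm '%s' (use one of %s)", algorithm,
                      paste(ALGORITHMS, collapse = ", ")),
              "gpcr_config_error")
  cols <- feature_columns(dataset, feature_tags)
  X <- dataset$X[, cols, drop = FALSE]
  y <- dataset$y
  if (length(unique(y)) < 2L)
    gpcr_stop("training data must contain both classes", "gpcr_evaluation_error")
  keep <- seq_len(ncol(X))
  if (algorithm %in% c("svm", "naive_bayes", "neural_network")) {
    v <- apply(X, 2L, stats::var)
    keep <- which(v > 0)
    if (length(keep) == 0L)
      gpcr_stop("all features are constant", "gpcr_evaluation_error")
  }
  # model matrices use positional names; original names kept for validation
  orig <- colnames(X)[keep]
  Xm <- X[, keep, drop = FALSE]
  colnames(Xm) <- paste0("V", seq_along(keep))
  yf <- factor(y, levels = c(0L, 1L))

  fit <- with_seed(seed, switch(algorithm,
    random_forest = ranger::ranger(x = Xm, y = yf, probability = TRUE,
                                   num.threads = 1L, seed = seed, ...),
    svm = e1071::svm(x = Xm, y = yf, probability = TRUE, ...),
    naive_bayes = e1071::naiveBayes(x = Xm, y = yf, ...),
    cart = rpart::rpart(y ~ ., data = data.frame(y = yf, Xm),
                        method = "class", ...),
    neural_network = nnet::nnet(x = Xm, y = as.numeric(y), size = 5,
                                maxit = 200, MaxNWts = 50000L,
                                trace = FALSE, ...)
  ))
  params <- switch(algorithm,
    random_forest = list(num.trees = fit$num.trees, mtry = fit$mtry),
    svm = list(kernel = "radial", cost = 1, gamma = fit$gamma),
    naive_bayes = list(laplace = 0),
    cart = list(cp = 0.01, minsplit = 20),
    neural_network = list(size = 5, maxit = 200))
  structure(list(fit = fit, algorithm = algorithm, columns = orig,
                 seed = seed, params = params),
            class = "gpcr_model")
}

#' Score feature rows with a trained model
#'
#' @param model A `gpcr_model`.
#' @param X Numeric matrix whose columns include the model's training
#'   columns (by name).
#' @return Numeric vector of probability-like scores in `[0, 1]`.
#' @export
predict_scores <- function(model, X) {
  missing <- setdiff(model$columns, colnames(X))
  if (length(missing))
    gpcr_stop(sprintf("feature columns missing from input: %s",
                      paste(head(missing, 5L), collapse = ", ")),
              "gpcr_shape_error")
  Xm <- X[, model$columns, drop = FALSE]
  colnames(Xm) <- paste0("V", seq_len(ncol(Xm)))
  switch(model$algorithm,
    random_forest = unname(predict(model$fit, data = as.data.frame(Xm),
                                   num.threads = 1L)$predictions[, "1"]),
    svm = {
      p <- predict(model$fit, Xm, probability = TRUE)
      unname(attr(p, "probabilities")[, "1"])
    },
    naive_bayes = unname(predict(model$fit, as.data.frame(Xm),
                                 type = "raw")[, "1"]),
    cart = unname(predict(model$fit, as.data.frame(Xm), type = "prob")[, "1"]),
    neural_network = unname(predict(model$fit, Xm)[, 1L])
  )
}

#' @export
print.gpcr_model <- function(x, ...) {
  cat(sprintf("<gpcr_model> %s on %d features (seed %d)\n",
              x$algorithm, length(x$columns), x$seed))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Shuffles each class separately (seeded), deals pairs into k folds,
#' trains on k-1 folds and scores the held-out fold; per-fold AUC from
#' [roc_auc()] and accuracy at a 0.5 score threshold.
#'
#' @param dataset A `binding_dataset`.
#' @param algorithm Classifier name (see [train()]).
#' @param k Number of folds (>= 2).
#' @param feature_tags Optional feature-set tags to restrict the columns.
#' @param seed Integer seed controlling fold assignment and training.
#' @param ... Passed to the fitting function.
#' @return Object of class `cv_report`: `fold_auc`, `fold_accuracy`,
#'   `mean_auc`, `mean_accuracy`, plus the configuration.
#' @export
cross_validate <- function(dataset, algorithm = "random_forest", k = 10L,
                           feature_tags = NULL, seed = 1L, ...) {
  if (!is_count(k) || k < 2) gpcr_stop("k must be an integer >= 2", "gpcr_config_error")
  y <- dataset$y
  n <- length(y)
  fold <- integer(n)
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      gpcr_stop(sprintf("class %d has %d members, fewer than k = %d folds",
                        cls, length(idx), k), "gpcr_evaluation_error")
    idx <- with_seed(derive_seed(seed, 100L + cls), sample(idx))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold_auc <- numeric(k); fold_acc <- numeric(k)
  params <- NULL
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    sub <- structure(list(X = dataset$X[tr, , drop = FALSE], y = y[tr],
                          column_tags = dataset$column_tags),
                     class = "binding_dataset")
    model <- train(sub, algorithm, seed = derive_seed(seed, f),
                   feature_tags = feature_tags, ...)
    params <- model$params
    sc <- predict_scores(model, dataset$X[te, , drop = FALSE])
    roc <- roc_auc(sc, y[te])
    fold_auc[f] <- roc$auc
    fold_acc[f] <- mean((sc >= 0.5) == (y[te] == 1L))
  }
  structure(list(algorithm = algorithm, feature_tags = feature_tags, k = k,
                 seed = seed, params = params, fold_auc = fold_auc,
                 fold_accuracy = fold_acc, mean_auc = mean(fold_auc),
                 mean_accuracy = mean(fold_acc)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  tags <- if (is.null(x$feature_tags)) "all features"
          else paste(x$feature_tags, collapse = " & ")
  cat(sprintf("<cv_report> %s, %d-fold, %s: mean AUC %.4f, mean accuracy %.4f\n",
              x$algorithm, x$k, tags, x$mean_auc, x$mean_accuracy))
  invisible(x)
}

#' The 7 x 7 feature-set combination grid
#'
#' All combinations of the seven receptor feature sets (MF, 1AAF, 2AAF and
#' their unions, "All") with the seven ligand feature sets (4chars, Hub,
#' Cycle and their unions, "All").
#'
#' @return data.frame with `receptor_set`, `ligand_set` (display names) and
#'   a `tags` list-column of tag vectors for [cross_validate()].
#' @export
feature_grid <- function() {
  rsets <- list("MF" = "MF", "1AAF" = "1AAF", "2AAF" = "2AAF",
                "MF & 1AAF" = c("MF", "1AAF"), "MF & 2AAF" = c("MF", "2AAF"),
                "1AAF & 2AAF" = c("1AAF", "2AAF"),
                "All" = c("MF", "1AAF", "2AAF"))
  lsets <- list("4chars" = "4chars", "Hub" = "Hub", "Cycle" = "Cycle",
                "4chars & Hub" = c("4chars", "Hub"),
                "4chars & Cycle" = c("4chars", "Cycle"),
                "Hub & Cycle" = c("Hub", "Cycle"),
                "All" = c("4chars", "Hub", "Cycle"))
  grid <- expand.grid(receptor_set = names(rsets), ligand_set = names(lsets),
                      stringsAsFactors = FALSE)
  grid$tags <- lapply(seq_len(nrow(grid)), function(i)
    c(rsets[[grid$receptor_set[i]]], lsets[[grid$ligand_set[i]]]))
  grid
}

#' Cross-validate every feature-set combination
#'
#' Runs [cross_validate()] for each of the 49 grid cells (or a subset).
#'
#' @param dataset A `binding_dataset`.
#' @param grid Rows of [feature_grid()] (default: full grid).
#' @param ... Passed to [cross_validate()].
#' @return data.frame `receptor_set`, `ligand_set`, `mean_auc`,
#'   `mean_accuracy`.
#' @export
cv_grid <- function(dataset, grid = feature_grid(), ...) {
  res <- lapply(seq_len(nrow(grid)), function(i)
    cross_validate(dataset, feature_tags = grid$tags[[i]], ...))
  data.frame(receptor_set = grid$receptor_set, ligand_set = grid$ligand_set,
             mean_auc = vapply(res, `[[`, 0, "mean_auc"),
             mean_accuracy = vapply(res, `[[`, 0, "mean_accuracy"))
}

#' Score and rank all receptor-ligand pairs
#'
#' Builds the receptor x ligand cross-product, concatenates feature rows,
#' scores with the model and returns the top-ranked pairs (ties broken by
#' receptor then ligand ID).
#'
#' @param model A `gpcr_model`.
#' @param receptor_vectors,ligand_vectors Feature matrices with ID rownames.
#' @param top_n Number of pairs to return (capped at the cross-product).
#' @return data.frame `receptor_id`, `ligand_id`, `score`, descending score.
#' @export
predict_pairs <- function(model, receptor_vectors, ligand_vectors,
                          top_n = 100L) {
  rids <- rownames(receptor_vectors); lids <- rownames(ligand_vectors)
  grid <- expand.grid(l = seq_along(lids), r = seq_along(rids))
  X <- cbind(receptor_vectors[grid$r, , drop = FALSE],
             ligand_vectors[grid$l, , drop = FALSE])
  sc <- predict_scores(model, X)
  out <- data.frame(receptor_id = rids[grid$r], ligand_id = lids[grid$l],
                    score = sc)
  out <- out[corder(-out$score, out$receptor_id, out$ligand_id), ]
  rownames(out) <- NULL
  head(out, min(top_n, nrow(out)))
}
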