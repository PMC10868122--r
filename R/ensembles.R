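# Nine published ensemble configurations across three families
# (blending / bagging / boosting), a standard scaler, and the m1a_fit
# modelling surface.

# rpart caps maxdepth at 30; published deeper settings saturate there.
RPART_MAXDEPTH <- 30L

#' Registry of the published model configurations
#'
#' One entry per classifier: the blending stack (ANN + 3-NN + RBF-SVM +
#' decision tree under a gradient-boosted meta-learner), four bagging
#' models and four boosting models, each with its published
#' hyperparameters.
#'
#' @return Named list of model specs (family, name, hyperparameters).
#' @export
model_registry <- function() {
  list(
    blending = list(
      family = "blending", name = "blending",
      params = list(
        ann = list(hidden = 5L, alpha = 1e-4),
        knn = list(k = 3L),
        svm = list(cost = 10, gamma = 1e-4, kernel = "radial"),
        dt = list(max_depth = 80L, min_samples_leaf = 4L),
        meta = list(n_estimators = 100L, learning_rate = 0.1),
        holdout = 0.2)),
    random_forest = list(
      family = "bagging", name = "random_forest",
      params = list(n_estimators = 200L, max_depth = 50L,
                    min_samples_split = 10L, min_samples_leaf = 5L)),
    extra_trees = list(
      family = "bagging", name = "extra_trees",
      params = list(n_estimators = 100L, max_depth = 40L)),
    decision_tree = list(
      family = "bagging", name = "decision_tree",
      params = list(max_depth = 80L, min_samples_leaf = 4L)),
    bagging_classifier = list(
      family = "bagging", name = "bagging_classifier",
      params = list(n_estimators = 100L, oob_score = TRUE,
                    min_weight_fraction_leaf = 0.1)),
    gradient_boost = list(
      family = "boosting", name = "gradient_boost",
      params = list(learning_rate = 0.1, n_estimators = 100L,
                    max_depth = 3L)),
    hgb = list(
      family = "boosting", name = "hgb",
      params = list(max_iter = 200L, max_depth = 40L)),
    adaboost = list(
      family = "boosting", name = "adaboost",
      params = list(n_estimators = 50L)),
    xgb = list(
      family = "boosting", name = "xgb",
      params = list(max_iter = 100L, max_depth = 40L))
  )
}

#' Build a model specification
#'
#' @param name One of the nine registry names (see [model_registry()]).
#' @param ... Hyperparameter overrides merged over the published values.
#' @return A `model_spec` list (family, name, params).
#' @export
model_spec <- function(name, ...) {
  reg <- model_registry()
  if (!name %in% names(reg))
    stop("unknown model '", name, "'; known: ",
         paste(names(reg), collapse = ", "))
  spec <- reg[[name]]
  over <- list(...)
  for (p in names(over)) spec$params[[p]] <- over[[p]]
  counts <- unlist(spec$params[names(spec$params) %in%
                                 c("n_estimators", "max_iter")])
  if (length(counts) && any(counts <= 0))
    stop("estimator/iteration counts must be positive")
  class(spec) <- "model_spec"
  spec
}

#' Fit a standard scaler on a training feature table
#'
#' Column-wise mean/sd learned from the training rows only; constant
#' columns keep sd treated as 1 so they scale to zero rather than
#' dividing by zero.
#'
#' @param X Numeric feature matrix (training rows).
#' @return A `scaler_state` list with `center`, `scale`, `columns`.
#' @export
fit_scaler <- function(X) {
  ctr <- colMeans(X)
  sc <- apply(X, 2L, stats::sd)
  sc[!is.finite(sc) | sc == 0] <- 1
  structure(list(center = ctr, scale = sc, columns = colnames(X)),
            class = "scaler_state")
}

#' Apply a fitted scaler
#' @param state A `scaler_state` from [fit_scaler()].
#' @param X Feature matrix whose columns match the fitting columns.
#' @return Scaled matrix.
#' @export
apply_scaler <- function(state, X) {
  if (!is.null(state$columns) && !is.null(colnames(X)) &&
      !identical(colnames(X), state$columns))
    stop("feature column manifest mismatch between scaler and input")
  sweep(sweep(X, 2L, state$center, "-"), 2L, state$scale, "/")
}

# ---- internal fitting engines -------------------------------------------
# each .fit_* returns an opaque state; each .score_* returns P(class 1)

rpart_data <- function(X, y = NULL) {
  d <- as.data.frame(X)
  colnames(d) <- paste0("f", seq_len(ncol(X)))
  if (!is.null(y)) d$.y <- factor(y, levels = c(0, 1))
  d
}

fit_rpart_tree <- function(X, y, max_depth, min_bucket, weights = NULL) {
  ctl <- rpart::rpart.control(
    maxdepth = min(max_depth, RPART_MAXDEPTH), cp = 0,
    minbucket = min_bucket, minsplit = max(2L * min_bucket, 2L),
    xval = 0L)
  rpart::rpart(.y ~ ., data = rpart_data(X, y), method = "class",
               weights = weights, control = ctl)
}

score_rpart <- function(tree, X) {
  unname(predict(tree, rpart_data(X), type = "prob")[, "1"])
}

fit_xgb <- function(X, y, nrounds, max_depth, eta, tree_method, seed) {
  set.seed(seed)
  xgboost::xgboost(
    x = X, y = factor(y, levels = c(0, 1)),
    objective = "binary:logistic", nrounds = nrounds,
    max_depth = max_depth, learning_rate = eta,
    tree_method = tree_method, nthreads = 1L, seed = seed,
    verbosity = 0L)
}

score_xgb <- function(fit, X) {
  pr <- predict(fit, X, type = "response", validate_features = FALSE)
  if (is.matrix(pr)) pr <- pr[, ncol(pr)]
  as.numeric(pr)
}

# bootstrap aggregation of rpart trees with out-of-bag scoring
fit_bagging <- function(X, y, n_estimators, min_wfrac, seed) {
  set.seed(seed)
  n <- nrow(X)
  min_bucket <- max(1L, ceiling(min_wfrac * n))
  trees <- vector("list", n_estimators)
  oob_votes <- matrix(NA_real_, n, n_estimators)
  for (b in seq_len(n_estimators)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- fit_rpart_tree(X[idx, , drop = FALSE], y[idx],
                                 RPART_MAXDEPTH, min_bucket)
    oob <- setdiff(seq_len(n), unique(idx))
    if (length(oob))
      oob_votes[oob, b] <- score_rpart(trees[[b]], X[oob, , drop = FALSE])
  }
  oob_score <- mean((rowMeans(oob_votes, na.rm = TRUE) >= 0.5) == y,
                    na.rm = TRUE)
  list(trees = trees, oob_score = oob_score)
}

score_bagging <- function(fit, X) {
  rowMeans(vapply(fit$trees, function(tr) score_rpart(tr, X),
                  numeric(nrow(X))))
}

# AdaBoost (SAMME) over shallow rpart trees
fit_adaboost <- function(X, y, n_estimators, seed) {
  set.seed(seed)
  n <- nrow(X)
  w <- rep(1 / n, n)
  yy <- ifelse(y == 1, 1, -1)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    tree <- fit_rpart_tree(X, y, max_depth = 1L, min_bucket = 1L,
                           weights = w * n)
    pred <- ifelse(score_rpart(tree, X) >= 0.5, 1, -1)
    err <- sum(w * (pred != yy))
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(stumps = stumps, alphas = alphas)
}

score_adaboost <- function(fit, X) {
  agg <- numeric(nrow(X))
  for (m in seq_along(fit$stumps)) {
    pred <- ifelse(score_rpart(fit$stumps[[m]], X) >= 0.5, 1, -1)
    agg <- agg + fit$alphas[m] * pred
  }
  tot <- sum(fit$alphas)
  if (tot == 0) return(rep(0.5, nrow(X)))
  stats::plogis(2 * agg)  # logistic squash of the margin to [0, 1]
}

fit_ranger <- function(X, y, n_trees, max_depth, min_node, extra, seed) {
  d <- rpart_data(X, y)
  ranger::ranger(
    dependent.variable.name = ".y", data = d, probability = TRUE,
    num.trees = n_trees, max.depth = max_depth,
    min.node.size = min_node,
    splitrule = if (extra) "extratrees" else "gini",
    num.random.splits = 1L,
    seed = seed, num.threads = 1L)
}

score_ranger <- function(fit, X) {
  unname(predict(fit, rpart_data(X), num.threads = 1L)$predictions[, "1"])
}

# blending base learners
fit_blend_bases <- function(X, y, p, seed) {
  set.seed(seed)
  ann <- nnet::nnet(x = X, y = as.numeric(y), size = p$ann$hidden,
                    decay = p$ann$alpha, entropy = TRUE, maxit = 200L,
                    MaxNWts = 50000L, trace = FALSE)
  svm <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                    kernel = p$svm$kernel, cost = p$svm$cost,
                    gamma = p$svm$gamma, probability = TRUE,
                    scale = FALSE)
  dt <- fit_rpart_tree(X, y, p$dt$max_depth, p$dt$min_samples_leaf)
  list(ann = ann, svm = svm, dt = dt,
       knn_train = X, knn_y = factor(y, levels = c(0, 1)), knn_k = p$knn$k)
}

score_blend_bases <- function(bases, X) {
  ann <- as.numeric(predict(bases$ann, X))
  svm_pred <- predict(bases$svm, X, probability = TRUE)
  svm <- attr(svm_pred, "probabilities")[, "1"]
  kn <- class::knn(train = bases$knn_train, test = X, cl = bases$knn_y,
                   k = bases$knn_k, prob = TRUE)
  kprob <- attr(kn, "prob")
  knn <- ifelse(kn == "1", kprob, 1 - kprob)
  dt <- score_rpart(bases$dt, X)
  cbind(ann = ann, knn = as.numeric(knn), svm = unname(svm), dt = dt)
}

fit_blending <- function(X, y, p, seed) {
  set.seed(seed)
  n <- nrow(X)
  # stratified inner holdout for the meta-learner's training features
  hold <- unlist(lapply(split(seq_len(n), y), function(idx) {
    sample(idx, max(1L, round(p$holdout * length(idx))))
  }), use.names = FALSE)
  inner <- setdiff(seq_len(n), hold)
  bases_inner <- fit_blend_bases(X[inner, , drop = FALSE], y[inner],
                                 p, seed)
  Z <- score_blend_bases(bases_inner, X[hold, , drop = FALSE])
  meta <- fit_xgb(Z, y[hold], nrounds = p$meta$n_estimators,
                  max_depth = 3L, eta = p$meta$learning_rate,
                  tree_method = "exact", seed = seed)
  # refit bases on the full training partition for prediction time
  bases <- fit_blend_bases(X, y, p, seed)
  list(bases = bases, meta = meta)
}

score_blending <- function(fit, X) {
  Z <- score_blend_bases(fit$bases, X)
  score_xgb(fit$meta, Z)
}

fit_engine <- function(spec, X, y, seed) {
  p <- spec$params
  switch(spec$name,
    blending = fit_blending(X, y, p, seed),
    random_forest = fit_ranger(X, y, p$n_estimators, p$max_depth,
                               p$min_samples_leaf, extra = FALSE,
                               seed = seed),
    extra_trees = fit_ranger(X, y, p$n_estimators, p$max_depth,
                             min_node = 1L, extra = TRUE, seed = seed),
    decision_tree = {
      set.seed(seed)
      fit_rpart_tree(X, y, p$max_depth, p$min_samples_leaf)
    },
    bagging_classifier = fit_bagging(X, y, p$n_estimators,
                                     p$min_weight_fraction_leaf, seed),
    gradient_boost = fit_xgb(X, y, p$n_estimators, p$max_depth,
                             p$learning_rate, "exact", seed),
    hgb = fit_xgb(X, y, p$max_iter, p$max_depth, 0.1, "hist", seed),
    adaboost = fit_adaboost(X, y, p$n_estimators, seed),
    xgb = fit_xgb(X, y, p$max_iter, p$max_depth, 0.3, "hist", seed),
    stop("unknown model '", spec$name, "'"))
}

score_engine <- function(spec, fit, X) {
  s <- switch(spec$name,
    blending = score_blending(fit, X),
    random_forest = ,
    extra_trees = score_ranger(fit, X),
    decision_tree = score_rpart(fit, X),
    bagging_classifier = score_bagging(fit, X),
    gradient_boost = ,
    hgb = ,
    xgb = score_xgb(fit, X),
    adaboost = score_adaboost(fit, X),
    stop("unknown model '", spec$name, "'"))
  pmin(pmax(as.numeric(s), 0), 1)
}

# ---- modelling surface ---------------------------------------------------

#' Fit an m1A site classifier
#'
#' The main fitting entry point. Takes either a list of labelled
#' `rna_window` objects (encoded internally) or a precomputed feature
#' matrix with a 0/1 label vector, standard-scales the features on the
#' training rows, and trains one of the nine published ensemble
#' configurations.
#'
#' @param x List of labelled `rna_window`s, or numeric feature matrix.
#' @param y Binary labels (0/1) when `x` is a matrix; ignored otherwise.
#' @param model Registry name (see [model_registry()]) or a
#'   `model_spec` object; default `"hgb"`, the best-performing
#'   configuration.
#' @param seed Integer seed; the whole train path is deterministic in it.
#' @param u,v Hahn shape parameters used when encoding windows.
#' @param ... Hyperparameter overrides passed to [model_spec()].
#' @return An object of class `m1a_fit`: the fitted state plus the
#'   scaler, feature-column manifest, spec, and threshold.
#' @examples
#' win <- synth_windows(30, 30, effect = 3, seed = 1)
#' fit <- m1a_fit(win, model = "decision_tree", seed = 1)
#' predict(fit, win[1:2])
#' @export
m1a_fit <- function(x, y = NULL, model = "hgb", seed = 1L, u = 0, v = 0,
                    ...) {
  spec <- if (inherits(model, "model_spec")) model else
    model_spec(model, ...)
  if (is.list(x) && !is.matrix(x)) {
    labels <- vapply(x, function(w) w$label, character(1L))
    if (any(labels == "unlabeled"))
      stop("all windows must be labelled positive/negative for fitting")
    y <- as.integer(labels == "positive")
    x <- feature_matrix(x, u = u, v = v)
  }
  if (is.null(y)) stop("labels y required with a feature matrix input")
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  scaler <- fit_scaler(x)
  Xs <- apply_scaler(scaler, x)
  fit <- fit_engine(spec, Xs, y, seed)
  structure(list(spec = spec, scaler = scaler, fit = fit,
                 manifest = colnames(x), seed = as.integer(seed),
                 u = u, v = v, threshold = 0.5,
                 n_train = nrow(x), class_counts = table(y),
                 version = "m1apred-bundle-1"),
            class = "m1a_fit")
}

#' Predict m1A calls or scores from a fitted classifier
#'
#' @param object An `m1a_fit`.
#' @param newdata Feature matrix with matching columns, or a list of
#'   `rna_window`s (encoded with the fit's Hahn parameters).
#' @param type `"class"` for 0/1 calls at the fit's threshold, `"prob"`
#'   for class-1 scores in \[0, 1\].
#' @param ... Unused.
#' @return Numeric vector of calls or scores.
#' @export
predict.m1a_fit <- function(object, newdata,
                            type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.matrix(newdata))
    newdata <- feature_matrix(newdata, u = object$u, v = object$v)
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$manifest))
    stop("feature column manifest mismatch")
  Xs <- apply_scaler(object$scaler, newdata)
  s <- score_engine(object$spec, object$fit, Xs)
  if (type == "prob") s else as.integer(s >= object$threshold)
}

#' @export
print.m1a_fit <- function(x, ...) {
  cat(sprintf("m1A site classifier: %s (%s family)\n",
              x$spec$name, x$spec$family))
  cat(sprintf("  trained on %d windows (%s), %d features, seed %d\n",
              x$n_train,
              paste(sprintf("%s=%d", names(x$class_counts),
                            as.integer(x$class_counts)), collapse = ", "),
              length(x$manifest), x$seed))
  invisible(x)
}

#' @export
summary.m1a_fit <- function(object, ...) {
  print(object)
  cat("  hyperparameters:\n")
  p <- object$spec$params
  for (nm in names(p)) {
    val <- p[[nm]]
    if (is.list(val)) val <- paste(sprintf("%s=%s", names(unlist(val)),
                                           unlist(val)), collapse = " ")
    cat(sprintf("    %s = %s\n", nm, paste(val, collapse = ",")))
  }
  if (identical(object$spec$name, "bagging_classifier"))
    cat(sprintf("  out-of-bag accuracy: %.3f\n", object$fit$oob_score))
  invisible(object)
}
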