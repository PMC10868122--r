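# End-to-end orchestration: encode -> scale -> train -> evaluate ->
# predict, with persisted model bundles.

#' Train and evaluate a classifier from a labelled FASTA
#'
#' Reads labelled windows, encodes them, and either holds out a
#' stratified 30% independent test partition or runs k-fold
#' cross-validation; the returned bundle is the model refit on the full
#' training data of the chosen protocol.
#'
#' @param fasta Path to a labelled FASTA (headers carrying
#'   `|label=pos|neg`, as written by [write_fasta()]).
#' @param model Registry name (default `"hgb"`).
#' @param protocol `"independent"` (70/30) or `"kfold"`.
#' @param k Folds when `protocol = "kfold"`.
#' @param W Window length.
#' @param seed Integer seed controlling split and training.
#' @param u,v Hahn shape parameters.
#' @param threshold Call threshold.
#' @param bundle_out Optional path; when given the fitted bundle is
#'   saved there with [saveRDS()].
#' @return List with `model` (an [m1a_fit] object) and `report` (one
#'   `evaluation_report` for the independent protocol; per-fold reports
#'   plus a `mean` row for k-fold).
#' @export
run_train <- function(fasta, model = "hgb",
                      protocol = c("independent", "kfold"), k = 10L,
                      W = 41L, seed = 1L, u = 0, v = 0, threshold = 0.5,
                      bundle_out = NULL) {
  protocol <- match.arg(protocol)
  windows <- parse_labeled_fasta(fasta, W = W)
  if (length(windows) == 0L) stop("no valid windows in input")
  labels <- vapply(windows, function(w) w$label, character(1L))
  if (any(labels == "unlabeled"))
    stop("training input contains unlabeled records")
  y <- as.integer(labels == "positive")
  X <- feature_matrix(windows, u = u, v = v)
  if (protocol == "independent") {
    sp <- split_70_30(y, seed = seed)
    fit <- m1a_fit(X[sp$train, , drop = FALSE], y[sp$train],
                   model = model, seed = seed, u = u, v = v)
    fit$threshold <- threshold
    scores <- predict(fit, X[sp$test, , drop = FALSE], type = "prob")
    report <- evaluate_predictions(y[sp$test], scores,
                                   threshold = threshold)
  } else {
    folds <- kfold_plan(length(y), k = k, seed = seed)
    reports <- lapply(seq_len(k), function(f) {
      tr <- which(folds != f); te <- which(folds == f)
      ff <- m1a_fit(X[tr, , drop = FALSE], y[tr], model = model,
                    seed = seed, u = u, v = v)
      ff$threshold <- threshold
      evaluate_predictions(y[te],
                           predict(ff, X[te, , drop = FALSE],
                                   type = "prob"),
                           threshold = threshold)
    })
    names(reports) <- paste0("fold", seq_len(k))
    metric_names <- c("Acc", "Sp", "Sn", "MCC", "F1", "AUROC")
    means <- vapply(metric_names, function(m) {
      mean(vapply(reports, function(r) r[[m]], numeric(1L)))
    }, numeric(1L))
    fit <- m1a_fit(X, y, model = model, seed = seed, u = u, v = v)
    fit$threshold <- threshold
    report <- c(reports, list(mean = as.list(means)))
  }
  if (!is.null(bundle_out)) saveRDS(fit, bundle_out)
  list(model = fit, report = report)
}

#' Call m1A sites on arbitrary-length sequences
#'
#' Scans every adenosine with full flanks in each record of a FASTA
#' file, encodes the surrounding window and scores it with a trained
#' bundle.
#'
#' @param model An `m1a_fit` object, or a path to a bundle saved by
#'   [run_train()].
#' @param fasta FASTA of sequences of any length >= the window size.
#' @param W Window length (must match the training window).
#' @param threshold Call threshold; default the bundle's own.
#' @return A data.frame with columns `record`, `position`, `score`,
#'   `call` (`"m1A"` / `"non-m1A"`); zero rows (with a warning) when no
#'   adenosine has full flanks.
#' @export
run_predict <- function(model, fasta, W = 41L, threshold = NULL) {
  if (is.character(model)) model <- readRDS(model)
  if (!inherits(model, "m1a_fit")) stop("not an m1a_fit bundle")
  if (!identical(model$version, "m1apred-bundle-1"))
    stop("unrecognized bundle version: ", model$version)
  if (is.null(threshold)) threshold <- model$threshold
  rec <- read_fasta(fasta)
  out <- data.frame(record = character(0), position = integer(0),
                    score = numeric(0), call = character(0))
  for (i in seq_len(nrow(rec))) {
    sites <- suppressWarnings(scan_sites(rec$seq[i], W = W,
                                         id = rec$id[i]))
    if (length(sites) == 0L) next
    X <- feature_matrix(lapply(sites, `[[`, "window"),
                        u = model$u, v = model$v)
    s <- predict(model, X, type = "prob")
    out <- rbind(out, data.frame(
      record = rec$id[i],
      position = vapply(sites, `[[`, integer(1L), "position"),
      score = s,
      call = ifelse(s >= threshold, "m1A", "non-m1A")))
  }
  if (nrow(out) == 0L)
    warning("no adenosine with full flanks found in the input")
  rownames(out) <- NULL
  out
}

#' Pairwise significance comparison of model configurations
#'
#' Trains each named configuration on a shared stratified 70/30 split
#' and reports, for every pair, the pooled two-proportion z test on
#' test accuracies, McNemar's test on the discordant test calls, and
#' the resampled paired t test.
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param models Character vector (or list mixing registry names and
#'   `model_spec` objects) of length >= 2.
#' @param trials Resampling trials for the paired t test.
#' @param seed Integer seed.
#' @return A data.frame with one row per model pair and columns
#'   `model_a`, `model_b`, `z`, `z_p`, `t`, `t_p`, `mcnemar_p`.
#' @export
run_compare <- function(X, y, models, trials = 5L, seed = 1L) {
  if (length(models) < 2L) stop("need at least two model names")
  y <- as.integer(y)
  if (is.character(models)) models <- as.list(models)
  labels_of <- vapply(models, function(m) {
    if (is.character(m)) m else m$name
  }, character(1L))
  sp <- split_70_30(y, seed = seed)
  preds <- lapply(models, function(m) {
    fit <- m1a_fit(X[sp$train, , drop = FALSE], y[sp$train], model = m,
                   seed = seed)
    predict(fit, X[sp$test, , drop = FALSE])
  })
  yte <- y[sp$test]
  n_te <- length(yte)
  pairs <- utils::combn(seq_along(models), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    ok_a <- preds[[a]] == yte; ok_b <- preds[[b]] == yte
    zt <- z_two_proportion(sum(ok_a), n_te, sum(ok_b), n_te)
    disc_b <- sum(ok_a & !ok_b); disc_c <- sum(!ok_a & ok_b)
    mc_p <- if (disc_b + disc_c == 0) 1 else
      mcnemar_test(disc_b, disc_c)$p
    tt <- resampled_paired_ttest(X, y, models[[a]], models[[b]],
                                 trials = trials, seed = seed)
    data.frame(model_a = labels_of[a], model_b = labels_of[b],
               z = zt$z, z_p = zt$p, t = tt$t, t_p = tt$p,
               mcnemar_p = mc_p)
  })
  do.call(rbind, rows)
}
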