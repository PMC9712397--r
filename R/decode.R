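#' Cut band-limited epochs into fixed-length window samples
#'
#' Every preprocessed 2-s epoch (512 samples at 256 Hz) is band-reconstructed
#' and split into non-overlapping 32-sample windows (16 per epoch), each a
#' 32-timestep x 32-channel sequence inheriting the epoch's label. These
#' windows are the classifier inputs: flattened for the classical models,
#' consumed as sequences by the CNN/LSTM. A non-divisible trailing remainder
#' is dropped with a warning.
#'
#' @param epochs list of `eeg_epoch` objects.
#' @param band band name (`"raw"`, `"delta"`, `"theta"`, `"alpha"`,
#'   `"beta"`).
#' @param window window length in samples (default 32).
#' @param spec a [wavelet_spec()].
#' @return A `window_set`: list(x = n x window x channels array, labels,
#'   epoch_id, band, window).
#' @export
make_windows <- function(epochs, band, window = 32, spec = wavelet_spec()) {
  if (length(epochs) == 0L)
    return(structure(list(x = array(0, c(0, window, 0)),
                          labels = character(0), epoch_id = integer(0),
                          band = band, window = window),
                     class = "window_set"))
  n_ch <- nrow(epochs[[1]]$data)
  per <- floor(ncol(epochs[[1]]$data) / window)
  if (ncol(epochs[[1]]$data) %% window != 0L)
    warning(sprintf("epoch length %d not divisible by window %d; dropping %d trailing samples",
                    ncol(epochs[[1]]$data), window,
                    ncol(epochs[[1]]$data) %% window))
  n <- length(epochs) * per
  x <- array(0, c(n, window, n_ch))
  labels <- character(n)
  epoch_id <- integer(n)
  pos <- 0L
  for (i in seq_along(epochs)) {
    sig <- epoch_band_signals(epochs[[i]], band, spec)
    for (w in seq_len(per)) {
      pos <- pos + 1L
      cols <- ((w - 1L) * window + 1L):(w * window)
      x[pos, , ] <- t(sig[, cols, drop = FALSE])
      labels[pos] <- epochs[[i]]$label
      epoch_id[pos] <- i
    }
  }
  structure(list(x = x, labels = labels, epoch_id = epoch_id, band = band,
                 window = window),
            class = "window_set")
}

window_subset <- function(ws, idx) {
  structure(list(x = ws$x[idx, , , drop = FALSE], labels = ws$labels[idx],
                 epoch_id = ws$epoch_id[idx], band = ws$band,
                 window = ws$window),
            class = "window_set")
}

flatten_windows <- function(ws) {
  m <- matrix(ws$x, dim(ws$x)[1], dim(ws$x)[2] * dim(ws$x)[3])
  colnames(m) <- paste0("f", seq_len(ncol(m)))
  m
}

#' Subsample the majority class to a cap
#'
#' Class imbalance biases classifiers toward the majority state, so the
#' majority class is randomly subsampled (without replacement) to `cap`
#' while the minority class is kept intact. At production scale the cap is
#' 200,000 windows; for a balanced set pass `cap = ` the minority-class
#' count.
#'
#' @param ws a `window_set`.
#' @param cap maximum retained majority-class windows (default: minority
#'   count, giving exactly balanced classes).
#' @param seed RNG seed for the subsample.
#' @return A `window_set` with the majority class capped.
#' @export
balance_subsample <- function(ws, cap = NULL, seed = 1) {
  tab <- table(ws$labels)
  if (length(tab) != 2L) stop("need exactly two classes to balance")
  maj <- names(tab)[which.max(tab)]
  if (is.null(cap)) cap <- min(tab)
  if (cap > max(tab))
    stop(sprintf("cap (%d) exceeds majority class size (%d)", cap, max(tab)))
  keep_maj <- with_seed(seed, sample(which(ws$labels == maj), cap))
  idx <- sort(c(which(ws$labels != maj), keep_maj))
  window_subset(ws, idx)
}

#' Cap every class at a fixed number of windows
#'
#' Random, seed-reproducible subsample of each class to at most `per_class`
#' windows. Applied after [balance_subsample()] this yields an exactly
#' balanced, desk-sized training set; [balance_subsample()] alone caps only
#' the majority class.
#'
#' @param ws a `window_set`.
#' @param per_class maximum windows kept per class.
#' @param seed RNG seed.
#' @return The capped `window_set`.
#' @export
cap_windows <- function(ws, per_class, seed = 1) {
  keep <- with_seed(seed, {
    unlist(lapply(unique(ws$labels), function(cl) {
      idx <- which(ws$labels == cl)
      if (length(idx) > per_class) sample(idx, per_class) else idx
    }))
  })
  window_subset(ws, sort(keep))
}

# stratified assignment of epochs (not windows) to k groups; returns the
# per-window group index. Guards against within-epoch leakage across folds.
epoch_folds <- function(ws, k, seed) {
  eps <- unique(ws$epoch_id)
  lab <- ws$labels[match(eps, ws$epoch_id)]
  fold_of <- integer(length(eps))
  with_seed(seed, {
    for (cl in unique(lab)) {
      members <- sample(which(lab == cl))
      if (length(members) < k)
        stop(sprintf("k = %d exceeds the %d epochs of class '%s'", k,
                     length(members), cl))
      fold_of[members] <- rep_len(seq_len(k), length(members))
    }
  })
  fold_of[match(ws$epoch_id, eps)]
}

confusion2 <- function(truth, pred) {
  lv <- c("attention", "distraction")
  table(factor(truth, levels = lv), factor(pred, levels = lv),
        dnn = c("truth", "predicted"))
}

report_from <- function(band, model, protocol, seed, truth, pred,
                        extra = list()) {
  cm <- confusion2(truth, pred)
  c(list(band = band, model = model, protocol = protocol, seed = seed,
         accuracy = sum(diag(cm)) / sum(cm), confusion = cm,
         n_eval = sum(cm)), extra)
}

fit_classical <- function(model, X, y, seed, opts = list()) {
  switch(model,
    "svm-rbf" = e1071::svm(X, factor(y), kernel = "radial",
                           scale = opts$scale %||% TRUE),
    "rf" = ranger::ranger(x = X, y = factor(y),
                          num.trees = opts$num_trees %||% 50,
                          max.depth = opts$max_depth %||% 16,
                          splitrule = "gini", seed = seed,
                          num.threads = 1),
    "mlp" = {
      sc <- list(mu = colMeans(X), sd = pmax(apply(X, 2, stats::sd), 1e-8))
      Xs <- sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")
      fit <- mlp_train(Xs, as.numeric(y == "attention"),
                       hidden = opts$hidden %||% c(16, 8, 4),
                       epochs = opts$epochs %||% 30, seed = seed)
      list(fit = fit, scale = sc)
    },
    stop("unknown classical model: ", model))
}

predict_classical <- function(model, fit, X) {
  switch(model,
    "svm-rbf" = as.character(predict(fit, X)),
    # fixed predict seed: tied majority votes are broken by ranger's RNG,
    # which is otherwise seeded from the global RNG at predict time
    "rf" = as.character(predict(fit, data = X, num.threads = 1,
                                seed = 1L)$predictions),
    "mlp" = {
      Xs <- sweep(sweep(X, 2, fit$scale$mu), 2, fit$scale$sd, "/")
      ifelse(nn_predict(fit$fit, Xs) > 0.5, "attention", "distraction")
    })
}

#' Stratified k-fold evaluation of the classical models
#'
#' Evaluates SVM-RBF, the 16-8-4 MLP, or the 50-tree depth-16 Gini random
#' forest under stratified k-fold cross-validation (default k = 10), with
#' whole epochs assigned to folds so that windows from one epoch never
#' straddle a fold boundary. Features are the flattened windows
#' (32 x 32 = 1024 values).
#'
#' @param ws a `window_set` (typically balanced first).
#' @param model `"svm-rbf"`, `"mlp"` or `"rf"`.
#' @param k number of folds.
#' @param seed RNG seed (fold assignment and model fitting).
#' @param opts model-specific options (e.g. `num_trees`, `hidden`).
#' @return A `classification_report` list: band, model, protocol, seed,
#'   accuracy (pooled over folds), confusion (2x2), n_eval, fold_accuracy.
#' @export
train_eval_kfold <- function(ws, model = c("rf", "svm-rbf", "mlp"), k = 10,
                             seed = 1, opts = list()) {
  model <- match.arg(model)
  folds <- epoch_folds(ws, k, seed)
  X <- flatten_windows(ws)
  pred <- character(length(ws$labels))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(ws$labels[tr])) < 2 ||
        length(unique(ws$labels[!tr])) < 2)
      stop("a fold lost one of the classes; reduce k")
    fit <- fit_classical(model, X[tr, , drop = FALSE], ws$labels[tr],
                         seed = derive_seed(seed, f), opts = opts)
    pf <- predict_classical(model, fit, X[!tr, , drop = FALSE])
    pred[!tr] <- pf
    fold_acc[f] <- mean(pf == ws$labels[!tr])
  }
  structure(report_from(ws$band, model, sprintf("%d-fold", k), seed,
                        ws$labels, pred,
                        list(fold_accuracy = fold_acc)),
            class = "classification_report")
}

# stratified epoch-grouped 60:20:20 partition; returns per-window partition
split_partitions <- function(ws, ratios, seed) {
  eps <- unique(ws$epoch_id)
  lab <- ws$labels[match(eps, ws$epoch_id)]
  part_of <- character(length(eps))
  with_seed(seed, {
    for (cl in unique(lab)) {
      members <- sample(which(lab == cl))
      n <- length(members)
      n_tr <- round(ratios[1] * n)
      n_va <- round(ratios[2] * n)
      if (n_tr < 1 || n_va < 1 || n - n_tr - n_va < 1)
        stop("not enough epochs of class '", cl, "' for a ",
             paste(ratios, collapse = ":"), " split")
      part_of[members] <- rep(c("train", "val", "test"),
                              c(n_tr, n_va, n - n_tr - n_va))
    }
  })
  part_of[match(ws$epoch_id, eps)]
}

#' Train/validation/test evaluation of the sequence models
#'
#' Splits epochs (stratified, whole epochs per partition) 60:20:20 into
#' training, validation and test sets, trains the 1D-CNN or LSTM with early
#' stopping on validation accuracy, and reports test-set accuracy with the
#' confusion matrix. Sequence inputs are the 32-step x 32-channel windows.
#'
#' @param ws a `window_set`.
#' @param model `"lstm"` or `"cnn1d"`.
#' @param ratios train/validation/test proportions (must sum to 1).
#' @param seed RNG seed (split and training).
#' @param opts options forwarded to the trainer (e.g. `hidden`, `filters`,
#'   `epochs`).
#' @return A `classification_report` (accuracy and confusion computed on the
#'   held-out test partition).
#' @export
train_eval_split <- function(ws, model = c("lstm", "cnn1d"),
                             ratios = c(0.6, 0.2, 0.2), seed = 1,
                             opts = list()) {
  model <- match.arg(model)
  stopifnot(abs(sum(ratios) - 1) < 1e-9)
  part <- split_partitions(ws, ratios, seed)
  for (pn in c("train", "val", "test"))
    if (length(unique(ws$labels[part == pn])) < 2)
      stop("partition '", pn, "' contains a single class")
  y <- as.numeric(ws$labels == "attention")
  tr <- part == "train"; va <- part == "val"; te <- part == "test"
  # per-feature standardization fitted on the training partition only
  mu <- apply(ws$x[tr, , , drop = FALSE], c(2, 3), mean)
  sd_ <- pmax(apply(ws$x[tr, , , drop = FALSE], c(2, 3), stats::sd), 1e-8)
  # band-limited class differences are carried by signal energy, not mean;
  # appending the squared signal as extra channels exposes that energy to
  # the sequence models as a first-moment feature (without it, gradient
  # training stalls on a long plateau that only some initializations escape)
  augment <- isTRUE(opts$augment %||% TRUE)
  norm <- function(a) {
    n_i <- dim(a)[1]
    out <- if (augment)
      array(0, c(n_i, dim(a)[2], 2 * dim(a)[3])) else a
    for (i in seq_len(n_i)) {
      z <- (a[i, , ] - mu) / sd_
      if (augment) out[i, , ] <- cbind(z, z^2) else out[i, , ] <- z
    }
    out
  }
  Xtr <- norm(ws$x[tr, , , drop = FALSE])
  Xva <- norm(ws$x[va, , , drop = FALSE])
  Xte <- norm(ws$x[te, , , drop = FALSE])
  # weight-initialization restarts: train each candidate from its own seed
  # and keep the one with the best validation accuracy (amplitude-coded
  # classes give these networks a long initial plateau that only some
  # initializations escape)
  restarts <- opts$restarts %||% 1
  fit <- NULL
  best_val <- -Inf
  for (r in seq_len(restarts)) {
    cand <- if (model == "lstm")
      lstm_train(Xtr, y[tr], hidden = opts$hidden %||% 32,
                 dropout = opts$dropout %||% 0.4, lr = opts$lr %||% 1e-3,
                 batch = opts$batch %||% 32, epochs = opts$epochs %||% 40,
                 patience = opts$patience %||% 8,
                 X_val = Xva, y_val = y[va], seed = derive_seed(seed, 71L, r))
    else
      cnn1d_train(Xtr, y[tr], filters = opts$filters %||% 32,
                  kernel = opts$kernel %||% 5,
                  dropout = opts$dropout %||% 0.4, lr = opts$lr %||% 1e-3,
                  batch = opts$batch %||% 32, epochs = opts$epochs %||% 40,
                  patience = opts$patience %||% 8,
                  X_val = Xva, y_val = y[va], seed = derive_seed(seed, 72L, r))
    val_acc <- mean((nn_predict(cand, Xva) > 0.5) == y[va])
    if (val_acc > best_val) { best_val <- val_acc; fit <- cand }
  }
  pred <- ifelse(nn_predict(fit, Xte) > 0.5, "attention", "distraction")
  structure(report_from(ws$band, model, "60:20:20", seed, ws$labels[te],
                        pred, list(n_train = sum(tr), n_val = sum(va))),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> band=%s model=%s protocol=%s acc=%.3f (n=%d)\n",
              x$band, x$model, x$protocol, x$accuracy, x$n_eval))
  print(x$confusion)
  invisible(x)
}

#' Band x model accuracy comparison table
#'
#' @param reports list of `classification_report` objects.
#' @return Long-format data.frame (band, model, protocol, accuracy, seed,
#'   n_eval, best); every report tied for the maximum accuracy is flagged
#'   best.
#' @export
band_comparison <- function(reports) {
  if (length(reports) == 0L) stop("need at least one report")
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(band = r$band, model = r$model, protocol = r$protocol,
               accuracy = r$accuracy, seed = r$seed, n_eval = r$n_eval,
               stringsAsFactors = FALSE)))
  df$best <- df$accuracy == max(df$accuracy)
  df
}

#' Cross-dataset transfer evaluation
#'
#' Fits a model on every window of one dataset and evaluates it once on
#' another — the generalization probe: transfer between datasets that share
#' generative structure should approach within-set accuracy, transfer
#' between datasets with different effect topographies should collapse
#' toward chance.
#'
#' @param ws_train training `window_set`.
#' @param ws_test test `window_set` (same band, window and channel count).
#' @param model a classical model name (default `"rf"`).
#' @param seed RNG seed.
#' @param opts model options (e.g. `num_trees = 100, max_depth = 40`).
#' @return A `classification_report` evaluated on `ws_test`.
#' @export
evaluate_transfer <- function(ws_train, ws_test, model = "rf", seed = 1,
                              opts = list()) {
  if (!identical(dim(ws_train$x)[-1], dim(ws_test$x)[-1]))
    stop("feature schema mismatch between train and test window sets")
  if (!identical(ws_train$band, ws_test$band))
    stop("band mismatch: ", ws_train$band, " vs ", ws_test$band)
  fit <- fit_classical(model, flatten_windows(ws_train), ws_train$labels,
                       seed = seed, opts = opts)
  pred <- predict_classical(model, fit, flatten_windows(ws_test))
  structure(report_from(ws_test$band, model, "transfer", seed,
                        ws_test$labels, pred),
            class = "classification_report")
}
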