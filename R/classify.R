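# 1-D convolutional classifier over GC feature vectors, plus an SVM
# alternative. Architecture: n_conv_blocks x (conv1d[32 filters, kernel 3,
# same padding, ReLU] -> max-pool[2]) -> flatten -> dense(100, ReLU) ->
# dropout(0.1) -> dense(100, ReLU) -> softmax. Integer-class cross-entropy
# loss, Adam optimizer. The network is small enough (inputs of 112-2048)
# that dense BLAS matrix products per mini-batch are fast on one core.

#' Classifier configuration
#'
#' @param n_conv_blocks Number of conv+pool blocks; `NULL` (default) picks
#'   2 for inputs shorter than 1024 features and 6 otherwise, matching the
#'   two pipeline regimes (112 and 2048 features).
#' @param filters Convolution filters per layer (default 32).
#' @param kernel Convolution kernel size (default 3, "same" padding).
#' @param dense_units Units in each dense layer (default 100).
#' @param dropout Dropout fraction between the dense layers (default 0.1).
#' @param batch_size Mini-batch size (default 32).
#' @param epochs Training epochs (default 30).
#' @param n_classes Number of output classes.
#' @param lr Adam learning rate (default 1e-3).
#' @param seed Integer seed for weight init, shuffling and dropout.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(n_conv_blocks = NULL, filters = 32L,
                              kernel = 3L, dense_units = 100L,
                              dropout = 0.1, batch_size = 32L,
                              epochs = 30L, n_classes = 4L,
                              lr = 1e-3, seed = 1L) {
  if (!is.null(n_conv_blocks) && n_conv_blocks < 1L) {
    stop("'n_conv_blocks' must be >= 1", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) stop("'dropout' must be in [0, 1)",
                                        call. = FALSE)
  if (n_classes < 2L) stop("'n_classes' must be >= 2", call. = FALSE)
  structure(list(n_conv_blocks = n_conv_blocks, filters = as.integer(filters),
                 kernel = as.integer(kernel),
                 dense_units = as.integer(dense_units),
                 dropout = dropout, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), n_classes = as.integer(n_classes),
                 lr = lr, seed = as.integer(seed)),
            class = "classifier_config")
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Build the 1-D CNN model
#'
#' Initializes weights (He-normal) for the architecture described in
#' [classifier_config()]. Each pooling stage halves the sequence length
#' (window 2, stride 2), so `input_len` must be at least
#' `2^n_conv_blocks`.
#'
#' @param cfg A [classifier_config()].
#' @param input_len Feature-vector length (e.g. `2 * N` for GC features).
#' @return A `cnn1d` model object (untrained).
#' @examples
#' m <- build_classifier(classifier_config(n_classes = 4), input_len = 112)
#' m$lens  # sequence length after each pooling stage: 56 28
#' @export
build_classifier <- function(cfg, input_len) {
  stopifnot(inherits(cfg, "classifier_config"))
  blocks <- cfg$n_conv_blocks
  if (is.null(blocks)) blocks <- if (input_len >= 1024L) 6L else 2L
  if (input_len < 2^blocks) {
    stop(sprintf("input length %d too short for %d pooling stages",
                 input_len, blocks), call. = FALSE)
  }
  set.seed(cfg$seed)
  lens <- integer(blocks)
  len <- input_len
  params <- list()
  cin <- 1L
  for (b in seq_len(blocks)) {
    fan_in <- cfg$kernel * cin
    params[[paste0("convW", b)]] <-
      array(stats::rnorm(cfg$kernel * cin * cfg$filters,
                         sd = sqrt(2 / fan_in)),
            dim = c(cfg$kernel, cin, cfg$filters))
    params[[paste0("convb", b)]] <- numeric(cfg$filters)
    len <- len %/% 2L
    lens[b] <- len
    cin <- cfg$filters
  }
  flat <- len * cfg$filters
  params$W1 <- he_init(flat, cfg$dense_units, flat)
  params$b1 <- numeric(cfg$dense_units)
  params$W2 <- he_init(cfg$dense_units, cfg$dense_units, cfg$dense_units)
  params$b2 <- numeric(cfg$dense_units)
  params$Wo <- he_init(cfg$dense_units, cfg$n_classes, cfg$dense_units)
  params$bo <- numeric(cfg$n_classes)
  cfg$n_conv_blocks <- blocks
  structure(list(cfg = cfg, input_len = as.integer(input_len),
                 lens = lens, flat = flat, params = params,
                 trained = FALSE, center = NULL, scale = NULL,
                 history = NULL),
            class = "cnn1d")
}

#' @export
print.cnn1d <- function(x, ...) {
  cat(sprintf(
    "<cnn1d> input %d -> %d conv blocks (%d filters, kernel %d) -> flatten %d -> %d -> %d -> %d classes%s\n",
    x$input_len, x$cfg$n_conv_blocks, x$cfg$filters, x$cfg$kernel, x$flat,
    x$cfg$dense_units, x$cfg$dense_units, x$cfg$n_classes,
    if (x$trained) " [trained]" else " [untrained]"))
  invisible(x)
}

# ---- layer primitives -------------------------------------------------

relu <- function(x) {
  x[x < 0] <- 0
  x
}

conv1d_fw <- function(A, W, bias) {
  d <- dim(A)
  B <- d[1L]; Tn <- d[2L]; Cin <- d[3L]
  K <- dim(W)[1L]; Cout <- dim(W)[3L]
  pad <- (K - 1L) %/% 2L
  Ap <- array(0, c(B, Tn + 2L * pad, Cin))
  Ap[, pad + seq_len(Tn), ] <- A
  out <- matrix(rep(bias, each = B * Tn), B * Tn, Cout)
  for (k in seq_len(K)) {
    Xk <- matrix(Ap[, k:(k + Tn - 1L), , drop = FALSE], B * Tn, Cin)
    out <- out + Xk %*% matrix(W[k, , ], Cin, Cout)
  }
  array(out, c(B, Tn, Cout))
}

conv1d_bw <- function(A, W, dZ) {
  d <- dim(A)
  B <- d[1L]; Tn <- d[2L]; Cin <- d[3L]
  K <- dim(W)[1L]; Cout <- dim(W)[3L]
  pad <- (K - 1L) %/% 2L
  Ap <- array(0, c(B, Tn + 2L * pad, Cin))
  Ap[, pad + seq_len(Tn), ] <- A
  dZm <- matrix(dZ, B * Tn, Cout)
  dW <- array(0, dim(W))
  dAp <- array(0, c(B, Tn + 2L * pad, Cin))
  for (k in seq_len(K)) {
    Xk <- matrix(Ap[, k:(k + Tn - 1L), , drop = FALSE], B * Tn, Cin)
    dW[k, , ] <- crossprod(Xk, dZm)
    dXk <- dZm %*% t(matrix(W[k, , ], Cin, Cout))
    dAp[, k:(k + Tn - 1L), ] <- dAp[, k:(k + Tn - 1L), , drop = FALSE] +
      array(dXk, c(B, Tn, Cin))
  }
  list(dA = dAp[, pad + seq_len(Tn), , drop = FALSE],
       dW = dW, db = colSums(dZm))
}

pool_fw <- function(A) {
  d <- dim(A)
  T2 <- d[2L] %/% 2L
  a <- A[, seq(1L, 2L * T2, by = 2L), , drop = FALSE]
  b <- A[, seq(2L, 2L * T2, by = 2L), , drop = FALSE]
  P <- pmax(a, b)
  dim(P) <- c(d[1L], T2, d[3L])
  list(P = P, mask = a >= b, Tin = d[2L])
}

pool_bw <- function(dP, pool) {
  d <- dim(dP)
  T2 <- d[2L]
  dA <- array(0, c(d[1L], pool$Tin, d[3L]))
  dA[, seq(1L, 2L * T2, by = 2L), ] <- dP * pool$mask
  dA[, seq(2L, 2L * T2, by = 2L), ] <- dP * (1 - pool$mask)
  dA
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Forward pass; returns caches needed for the backward pass.
cnn_forward <- function(model, X, training = FALSE) {
  cfg <- model$cfg
  p <- model$params
  B <- nrow(X)
  A <- array(X, c(B, ncol(X), 1L))
  caches <- vector("list", cfg$n_conv_blocks)
  for (b in seq_len(cfg$n_conv_blocks)) {
    Z <- conv1d_fw(A, p[[paste0("convW", b)]], p[[paste0("convb", b)]])
    R <- relu(Z)
    pl <- pool_fw(R)
    caches[[b]] <- list(A = A, Z = Z, pool = pl)
    A <- pl$P
  }
  Fl <- matrix(A, B, model$flat)
  Z1 <- Fl %*% p$W1 + matrix(p$b1, B, length(p$b1), byrow = TRUE)
  H1 <- relu(Z1)
  if (training && cfg$dropout > 0) {
    drop_mask <- matrix(
      (stats::runif(length(H1)) >= cfg$dropout) / (1 - cfg$dropout),
      nrow(H1), ncol(H1))
    H1d <- H1 * drop_mask
  } else {
    drop_mask <- NULL
    H1d <- H1
  }
  Z2 <- H1d %*% p$W2 + matrix(p$b2, B, length(p$b2), byrow = TRUE)
  H2 <- relu(Z2)
  logits <- H2 %*% p$Wo + matrix(p$bo, B, length(p$bo), byrow = TRUE)
  list(caches = caches, Fl = Fl, Z1 = Z1, H1 = H1, drop_mask = drop_mask,
       H1d = H1d, Z2 = Z2, H2 = H2, logits = logits,
       probs = softmax_rows(logits), pool_dim = dim(A))
}

# Cross-entropy loss and gradients for integer labels y in 1..K.
cnn_backward <- function(model, X, y, fw) {
  cfg <- model$cfg
  p <- model$params
  B <- nrow(X)
  K <- cfg$n_classes
  probs <- fw$probs
  Y <- matrix(0, B, K)
  Y[cbind(seq_len(B), y)] <- 1
  dlogits <- (probs - Y) / B
  g <- list()
  g$Wo <- crossprod(fw$H2, dlogits)
  g$bo <- colSums(dlogits)
  dH2 <- dlogits %*% t(p$Wo)
  dZ2 <- dH2 * (fw$Z2 > 0)
  g$W2 <- crossprod(fw$H1d, dZ2)
  g$b2 <- colSums(dZ2)
  dH1d <- dZ2 %*% t(p$W2)
  dH1 <- if (is.null(fw$drop_mask)) dH1d else dH1d * fw$drop_mask
  dZ1 <- dH1 * (fw$Z1 > 0)
  g$W1 <- crossprod(fw$Fl, dZ1)
  g$b1 <- colSums(dZ1)
  dFl <- dZ1 %*% t(p$W1)
  dA <- array(dFl, fw$pool_dim)
  for (b in rev(seq_len(cfg$n_conv_blocks))) {
    cc <- fw$caches[[b]]
    dR <- pool_bw(dA, cc$pool)
    dZ <- dR * (cc$Z > 0)
    cb <- conv1d_bw(cc$A, p[[paste0("convW", b)]], dZ)
    g[[paste0("convW", b)]] <- cb$dW
    g[[paste0("convb", b)]] <- cb$db
    dA <- cb$dA
  }
  g
}

cnn_loss <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}

#' Train the 1-D CNN
#'
#' Mini-batch Adam on integer-class cross-entropy. Fully deterministic
#' given the model's seed (weight init, shuffling and dropout all draw
#' from the seeded RNG stream).
#'
#' @param model A `cnn1d` from [build_classifier()].
#' @param X Numeric feature matrix (rows = samples), already on a
#'   comparable scale (see [train_eval()], which standardizes).
#' @param y Integer class labels in `1..n_classes`.
#' @param X_val,y_val Optional monitoring split; per-epoch loss/accuracy
#'   are recorded in `model$history`.
#' @param verbose Print per-epoch progress.
#' @return The trained `cnn1d`.
#' @export
train_cnn <- function(model, X, y, X_val = NULL, y_val = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(model, "cnn1d"))
  cfg <- model$cfg
  y <- as.integer(y)
  stopifnot(all(y >= 1L), all(y <= cfg$n_classes), nrow(X) == length(y))
  set.seed(cfg$seed + 1L)
  p <- model$params
  mom <- lapply(p, function(w) array(0, dim = dim(w) %||% length(w)))
  vel <- mom
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  n <- nrow(X)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (s in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      fw <- cnn_forward(model, Xb, training = TRUE)
      losses <- c(losses, cnn_loss(fw$probs, yb))
      g <- cnn_backward(model, Xb, yb, fw)
      step <- step + 1L
      for (nm in names(g)) {
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g[[nm]]
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g[[nm]]^2
        mh <- mom[[nm]] / (1 - b1^step)
        vh <- vel[[nm]] / (1 - b2^step)
        p[[nm]] <- p[[nm]] - cfg$lr * mh / (sqrt(vh) + eps)
        model$params <- p
      }
    }
    vl <- NA_real_; va <- NA_real_
    if (!is.null(X_val) && nrow(X_val) > 0L) {
      fwv <- cnn_forward(model, X_val, training = FALSE)
      vl <- cnn_loss(fwv$probs, as.integer(y_val))
      va <- mean(max.col(fwv$probs) == y_val)
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_loss = vl, val_acc = va))
    if (verbose) {
      cat(sprintf("epoch %2d  train loss %.4f  val loss %.4f  val acc %.3f\n",
                  ep, mean(losses), vl, va))
    }
  }
  model$trained <- TRUE
  model$history <- hist
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict classes or probabilities from a trained CNN
#'
#' @param object A trained `cnn1d`.
#' @param newdata Feature matrix or data frame (a `label` column, if
#'   present, is ignored). If the model carries standardization parameters
#'   (set by [train_eval()]) they are applied first.
#' @param type `"class"` (integer labels) or `"prob"` (softmax matrix).
#' @param ... Unused.
#' @return Integer vector or probability matrix.
#' @export
predict.cnn1d <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- prepare_feature_matrix(newdata)
  if (!is.null(object$center)) {
    X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  }
  probs <- cnn_forward(object, X, training = FALSE)$probs
  if (type == "prob") probs else max.col(probs)
}

prepare_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    features <- features[setdiff(names(features), "label")]
    features <- as.matrix(features)
  }
  storage.mode(features) <- "double"
  features
}

# ---- evaluation -------------------------------------------------------

# Stratified allocation of indices into train/val/test.
stratified_split <- function(y, fractions) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in sort(unique(y))) {
    ci <- which(y == cl)
    ci <- ci[sample.int(length(ci))]
    n <- length(ci)
    n_tr <- round(fractions[1L] * n)
    n_va <- round(fractions[2L] * n)
    n_te <- n - n_tr - n_va
    parts <- c(train = n_tr, val = n_va, test = n_te)
    empty <- names(parts)[fractions > 0 & parts == 0]
    if (length(empty) > 0L) {
      stop(sprintf(
        "class %s would be absent from the %s split; use more data or adjust fractions",
        cl, empty[1L]), call. = FALSE)
    }
    idx$train <- c(idx$train, ci[seq_len(n_tr)])
    idx$val <- c(idx$val, ci[n_tr + seq_len(n_va)])
    idx$test <- c(idx$test, ci[n_tr + n_va + seq_len(n_te)])
  }
  idx
}

#' Confusion matrix and macro-averaged classification metrics
#'
#' Sensitivity and specificity are macro-averaged one-vs-rest:
#' `TP / (TP + FN)` and `TN / (TN + FP)` per class, then averaged.
#'
#' @param truth Integer true labels.
#' @param pred Integer predicted labels.
#' @param n_classes Number of classes.
#' @return List with `confusion_matrix` (rows = truth), `accuracy`,
#'   `sensitivity`, `specificity`, all metrics in percent.
#' @export
confusion_metrics <- function(truth, pred, n_classes) {
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(truth = seq_len(n_classes),
                               pred = seq_len(n_classes)))
  for (k in seq_along(truth)) {
    cm[truth[k], pred[k]] <- cm[truth[k], pred[k]] + 1L
  }
  total <- sum(cm)
  sens <- spec <- numeric(n_classes)
  for (c_ in seq_len(n_classes)) {
    tp <- cm[c_, c_]
    fn <- sum(cm[c_, ]) - tp
    fp <- sum(cm[, c_]) - tp
    tn <- total - tp - fn - fp
    sens[c_] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec[c_] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  list(confusion_matrix = cm,
       accuracy = 100 * sum(diag(cm)) / total,
       sensitivity = 100 * mean(sens, na.rm = TRUE),
       specificity = 100 * mean(spec, na.rm = TRUE))
}

#' Train a classifier on a feature table and evaluate on a held-out split
#'
#' Splits the data stratified by class into train/validation/test,
#' standardizes features against the training split, trains the requested
#' architecture, and reports accuracy, macro sensitivity and macro
#' specificity (percent) with the confusion matrix on the test split.
#' Deterministic given `seed`.
#'
#' @param features Data frame from [extract_features_batch()] (feature
#'   columns plus optionally a `label` column) or a numeric matrix.
#' @param labels Integer labels; taken from `features$label` when `NULL`.
#' @param arch `"cnn"` (the 1-D CNN, default) or `"svm"`
#'   (radial-basis support vector machine via e1071).
#' @param split Fractions for train/validation/test, summing to 1.
#' @param cfg A [classifier_config()]; `n_classes` is overridden by the
#'   number of distinct labels.
#' @param seed Integer seed controlling the split, initialization and
#'   training.
#' @param verbose Print training progress.
#' @return An `eval_report`: accuracy/sensitivity/specificity (percent),
#'   `confusion_matrix`, split sizes, the fitted `model`, and training
#'   `history` for the CNN.
#' @export
train_eval <- function(features, labels = NULL,
                       arch = c("cnn", "svm"),
                       split = c(0.70, 0.15, 0.15),
                       cfg = classifier_config(), seed = 1L,
                       verbose = FALSE) {
  arch <- match.arg(arch)
  if (is.null(labels)) {
    if (is.data.frame(features) && "label" %in% names(features)) {
      labels <- features$label
    } else {
      stop("no 'labels' given and no 'label' column in 'features'",
           call. = FALSE)
    }
  }
  X <- prepare_feature_matrix(features)
  classes <- sort(unique(labels))
  y <- match(labels, classes)
  K <- length(classes)
  stopifnot(nrow(X) == length(y))

  set.seed(seed)
  idx <- stratified_split(y, split)
  ctr <- colMeans(X[idx$train, , drop = FALSE])
  scl <- apply(X[idx$train, , drop = FALSE], 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")

  if (arch == "cnn") {
    cfg$n_classes <- K
    cfg$seed <- as.integer(seed)
    model <- build_classifier(cfg, ncol(X))
    model <- train_cnn(model,
                       Xs[idx$train, , drop = FALSE], y[idx$train],
                       X_val = Xs[idx$val, , drop = FALSE],
                       y_val = y[idx$val], verbose = verbose)
    model$center <- ctr
    model$scale <- scl
    pred <- max.col(cnn_forward(model, Xs[idx$test, , drop = FALSE],
                                training = FALSE)$probs)
    history <- model$history
  } else {
    fit <- e1071::svm(x = Xs[idx$train, , drop = FALSE],
                      y = factor(y[idx$train], levels = seq_len(K)))
    pred <- as.integer(as.character(
      stats::predict(fit, Xs[idx$test, , drop = FALSE])))
    model <- fit
    history <- NULL
  }

  met <- confusion_metrics(y[idx$test], pred, K)
  structure(list(accuracy = met$accuracy,
                 sensitivity = met$sensitivity,
                 specificity = met$specificity,
                 confusion_matrix = met$confusion_matrix,
                 classes = classes,
                 split_sizes = vapply(idx, length, integer(1L)),
                 split_index = idx,
                 arch = arch, seed = seed,
                 model = model, history = history),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s | test n = %d\n", x$arch,
              x$split_sizes[["test"]]))
  cat(sprintf("  accuracy    %6.2f %%\n", x$accuracy))
  cat(sprintf("  sensitivity %6.2f %% (macro)\n", x$sensitivity))
  cat(sprintf("  specificity %6.2f %% (macro)\n", x$specificity))
  cat("  confusion matrix (rows = truth):\n")
  print(x$confusion_matrix)
  invisible(x)
}
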