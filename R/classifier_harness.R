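# Subject-grouped cross-validation harness: leave-k-subjects-out splits,
# inverse-frequency class weights, rotation / pixel-dropout augmentation,
# a small CNN trained with a weighted loss, and the multi-class metric
# suite (per-class precision/recall/F1, macro averages, summed
# row-normalized confusion matrix).

EMOTION_CLASSES <- c("A", "D", "F", "S", "N")

#' Labelled feature set
#'
#' @param blocks list of classifier input arrays (`H x W x depth`).
#' @param labels character vector of class labels in
#'   `c("A","D","F","S","N")` (amusement, disgust, fear, sexual arousal,
#'   neutral), one per block.
#' @param subject_ids identifier per block; drives the grouped CV.
#' @return An object of class `labeled_feature_set`.
#' @export
labeled_feature_set <- function(blocks, labels, subject_ids) {
  labels <- as.character(labels)
  subject_ids <- as.character(subject_ids)
  if (length(blocks) != length(labels) ||
      length(blocks) != length(subject_ids)) {
    stop("blocks, labels and subject_ids must have equal length")
  }
  bad <- setdiff(unique(labels), EMOTION_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  }
  structure(list(blocks = blocks, labels = labels,
                 subject_ids = subject_ids),
            class = "labeled_feature_set")
}

#' Leave-k-subjects-out cross-validation plan
#'
#' Subjects are shuffled deterministically under `seed` and partitioned
#' into consecutive groups of `group_size`; each fold tests one group and
#' trains on all remaining subjects, so no subject ever appears on both
#' sides of a fold.  110 subjects with groups of 5 give the 22-fold plan.
#'
#' @param subject_ids subject identifiers (duplicates allowed; the
#'   distinct set is partitioned).
#' @param group_size subjects per test fold.
#' @param seed shuffle seed.
#' @return An object of class `cv_plan`: list `folds` of
#'   `list(train, test)` subject sets.
#' @export
make_cv_splits <- function(subject_ids, group_size = 5L, seed = 1L) {
  subjects <- unique(as.character(subject_ids))
  n <- length(subjects)
  if (group_size > n) {
    stop("`group_size` = ", group_size, " exceeds the number of subjects (", n, ")")
  }
  if (n %% group_size != 0L) {
    warning("number of subjects (", n, ") is not divisible by group_size (",
            group_size, "); the last fold is smaller")
  }
  shuffled <- with_seed(seed, sample(subjects))
  groups <- split(shuffled, ceiling(seq_len(n) / group_size))
  folds <- lapply(groups, function(g) {
    list(train = setdiff(subjects, g), test = g)
  })
  names(folds) <- NULL
  structure(list(folds = folds, group_size = as.integer(group_size),
                 subjects = subjects),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %d folds, %d subjects, %d per test group\n",
              length(x$folds), length(x$subjects), x$group_size))
  invisible(x)
}

#' Inverse-frequency class weights
#'
#' `w_c = N_total / (n_classes * N_c)`: smaller classes receive larger
#' weights, and perfectly balanced labels give all weights 1 (the weights
#' average to 1 under balance).
#'
#' @param labels training labels; every class in `classes` must be
#'   present.
#' @param classes the class alphabet.
#' @return Named numeric weight per class.
#' @export
class_weights <- function(labels, classes = EMOTION_CLASSES) {
  counts <- table(factor(as.character(labels), levels = classes))
  missing <- names(counts)[counts == 0]
  if (length(missing) > 0L) {
    stop("class(es) absent from the training labels: ",
         paste(missing, collapse = ", "))
  }
  w <- length(labels) / (length(classes) * as.numeric(counts))
  names(w) <- classes
  w
}

rotate90 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]

#' Training-time augmentation of a classifier input block
#'
#' With equal probability the block is rotated by 0, 90, 180 or 270
#' degrees (square spatial dimensions required); independently, each
#' spatial pixel's full depth vector is zeroed with probability
#' `pixel_drop_p` ("closing a pixel in the time domain").
#'
#' @param block `H x W x depth` array with `H == W`.
#' @param pixel_drop_p per-pixel zeroing probability; the default 1/124
#'   zeroes about 405 of the 224 x 224 pixels in expectation.
#' @param seed optional seed; by default the caller's RNG stream is used
#'   (training draws many augmentations per epoch).
#' @return The augmented block.
#' @export
augment_block <- function(block, pixel_drop_p = 1 / 124, seed = NULL) {
  d <- dim(block)
  if (d[1] != d[2]) stop("augmentation requires square spatial dimensions")
  run <- function() {
    k <- sample.int(4L, 1L) - 1L
    out <- block
    if (k > 0L) {
      for (j in seq_len(d[3])) {
        m <- out[, , j]
        for (r in seq_len(k)) m <- rotate90(m)
        out[, , j] <- m
      }
    }
    if (pixel_drop_p > 0) {
      drop <- stats::runif(d[1] * d[2]) < pixel_drop_p
      if (any(drop)) {
        dm <- matrix(!drop, d[1], d[2])
        out <- out * array(rep(dm, d[3]), d)
      }
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Training hyperparameters
#'
#' @param epochs passes over the training set.
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param dropout dropout probability on the hidden layer.
#' @param augment logical; apply [augment_block()] to every training
#'   sample each epoch.
#' @param pixel_drop_p augmentation pixel-zeroing probability.
#' @return A named list.
#' @export
default_hyperparameters <- function(epochs = 25L, lr = 0.001,
                                    batch_size = 64L, dropout = 0.5,
                                    augment = TRUE, pixel_drop_p = 1 / 124) {
  list(epochs = as.integer(epochs), lr = lr,
       batch_size = as.integer(batch_size), dropout = dropout,
       augment = augment, pixel_drop_p = pixel_drop_p)
}

#' Build a classifier backbone
#'
#' The built-in `"tiny"` backbone is a small CNN that runs on a single
#' CPU: input pooling to a coarse grid, one 3 x 3 convolution with ReLU,
#' 2 x 2 average pooling, dropout, and a dense softmax layer, trained
#' with Adam on a class-weighted cross-entropy.  Any first layer depth is
#' accepted, so concatenated multi-feature inputs work unchanged.  Larger
#' compound-scaled backbones are supplied by the caller as plug-in
#' learners to [train_and_evaluate()].
#'
#' @param input_depth depth of the `H x W x depth` input blocks.
#' @param n_classes number of output classes.
#' @param backbone `"tiny"`.
#' @param input_side spatial side of the input blocks.
#' @param pool input pooling factor (224 / 8 = 28 grid).
#' @param conv_filters convolution filter count.
#' @return An untrained model of class `tiny_cnn`.
#' @export
build_model <- function(input_depth, n_classes = 5L, backbone = "tiny",
                        input_side = 224L, pool = 8L, conv_filters = 8L) {
  if (input_depth < 1L) stop("`input_depth` must be >= 1")
  if (!identical(backbone, "tiny")) {
    stop("unsupported backbone '", backbone,
         "'; built-in backbones: \"tiny\" (supply larger backbones as plug-in learners)")
  }
  s <- input_side %/% pool
  structure(list(input_depth = as.integer(input_depth),
                 n_classes = as.integer(n_classes),
                 input_side = as.integer(input_side),
                 pool = as.integer(pool), grid = as.integer(s),
                 conv_filters = as.integer(conv_filters),
                 params = NULL, classes = EMOTION_CLASSES[seq_len(n_classes)],
                 center = 0, scale = 1),
            class = "tiny_cnn")
}

# ---- tiny CNN internals -------------------------------------------------

# Average-pool an H x W x D block to grid x grid x D.
pool_block <- function(block, model) {
  d <- dim(block)
  g <- rep(seq_len(model$grid), each = model$pool, length.out = d[1])
  P <- pool_matrix(g)
  out <- array(0, c(model$grid, model$grid, d[3]))
  for (j in seq_len(d[3])) out[, , j] <- P %*% block[, , j] %*% t(P)
  out
}

# im2col index map for valid 3x3 convolution over an s x s x D grid:
# rows = output positions ((s-2)^2), cols = 9 * D input offsets.
im2col_index <- function(s, D) {
  oi <- as.matrix(expand.grid(i = seq_len(s - 2L), j = seq_len(s - 2L)))
  off <- as.matrix(expand.grid(di = 0:2, dj = 0:2, dc = seq_len(D) - 1L))
  idx <- matrix(0L, nrow(oi), nrow(off))
  for (k in seq_len(nrow(off))) {
    idx[, k] <- (oi[, 1] + off[k, 1]) + (oi[, 2] + off[k, 2] - 1L) * s +
      off[k, 3] * s * s
  }
  idx
}

tiny_cnn_init <- function(model, seed) {
  D <- model$input_depth; f <- model$conv_filters
  s <- model$grid; q <- (s - 2L) %/% 2L
  nh <- q * q * f
  with_seed(seed, list(
    Wc = matrix(stats::rnorm(9L * D * f, 0, sqrt(2 / (9 * D))), 9L * D, f),
    bc = rep(0, f),
    Wd = matrix(stats::rnorm(nh * model$n_classes, 0, sqrt(2 / nh)), nh,
                model$n_classes),
    bd = rep(0, model$n_classes)))
}

# Forward pass for a batch given as a B x (s*s*D) matrix of pooled,
# standardized inputs.  Returns intermediates needed for the backward pass.
tiny_cnn_forward <- function(par, model, Xb, idx, drop_mask = NULL) {
  B <- nrow(Xb)
  s <- model$grid; f <- model$conv_filters
  np <- (s - 2L)^2L
  cols <- Xb[, as.vector(idx), drop = FALSE]
  dim(cols) <- c(B * np, ncol(idx))  # (B*np) x 9D, batch-major per position
  Z <- cols %*% par$Wc
  Z <- sweep(Z, 2L, par$bc, `+`)
  A <- pmax(Z, 0)
  # 2x2 average pooling over the (s-2) x (s-2) conv grid
  q <- (s - 2L) %/% 2L
  AA <- array(A, c(B, s - 2L, s - 2L, f))
  Pq <- pool_matrix(rep(seq_len(q), each = 2L, length.out = s - 2L))
  Hmat <- matrix(0, B, q * q * f)
  for (j in seq_len(f)) {
    for (b in seq_len(B)) {
      Hmat[b, (j - 1L) * q * q + seq_len(q * q)] <-
        as.vector(Pq %*% AA[b, , , j] %*% t(Pq))
    }
  }
  if (!is.null(drop_mask)) Hmat <- Hmat * drop_mask
  logits <- sweep(Hmat %*% par$Wd, 2L, par$bd, `+`)
  list(cols = cols, Z = Z, A = A, H = Hmat, logits = logits, q = q)
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

#' Fit the tiny CNN
#'
#' Adam-trained class-weighted softmax cross-entropy.  Inputs are pooled
#' to the model grid and standardized by the training set's global mean
#' and standard deviation (stored in the model).  With `hp$augment` each
#' training sample is re-augmented every epoch.
#'
#' @param model an untrained `tiny_cnn` from [build_model()].
#' @param blocks list of input arrays.
#' @param labels training labels.
#' @param weights named per-class loss weights (default
#'   [class_weights()] of `labels`).
#' @param hp hyperparameters from [default_hyperparameters()].
#' @param seed seed controlling initialization, shuffling, dropout and
#'   augmentation.
#' @return The trained model.
#' @export
fit_model <- function(model, blocks, labels, weights = NULL,
                      hp = default_hyperparameters(), seed = 1L) {
  labels <- as.character(labels)
  y <- match(labels, model$classes)
  if (anyNA(y)) stop("labels outside the model's class set")
  weights <- weights %||% class_weights(labels, model$classes)
  par <- tiny_cnn_init(model, seed)
  idx <- im2col_index(model$grid, model$input_depth)
  N <- length(blocks)
  s <- model$grid; D <- model$input_depth; f <- model$conv_filters
  q <- (s - 2L) %/% 2L; np <- (s - 2L)^2L
  Pq <- pool_matrix(rep(seq_len(q), each = 2L, length.out = s - 2L))

  pooled0 <- lapply(blocks, pool_block, model = model)
  allv <- unlist(pooled0)
  model$center <- mean(allv)
  model$scale <- stats::sd(allv)
  if (!is.finite(model$scale) || model$scale == 0) model$scale <- 1

  adam <- lapply(par, function(p) list(m = p * 0, v = p * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  wvec <- as.numeric(weights[model$classes])

  with_seed(seed + 1L, {
    for (epoch in seq_len(hp$epochs)) {
      ord <- sample.int(N)
      for (start in seq(1L, N, by = hp$batch_size)) {
        take <- ord[start:min(start + hp$batch_size - 1L, N)]
        B <- length(take)
        Xb <- matrix(0, B, s * s * D)
        for (bi in seq_len(B)) {
          blk <- if (hp$augment) {
            pool_block(augment_block(blocks[[take[bi]]],
                                     pixel_drop_p = hp$pixel_drop_p),
                       model)
          } else pooled0[[take[bi]]]
          Xb[bi, ] <- (as.vector(blk) - model$center) / model$scale
        }
        yb <- y[take]
        drop_mask <- if (hp$dropout > 0) {
          matrix((stats::runif(B * q * q * f) >= hp$dropout) /
                   (1 - hp$dropout), B, q * q * f)
        } else NULL
        fw <- tiny_cnn_forward(par, model, Xb, idx, drop_mask)
        P <- softmax_rows(fw$logits)
        wrow <- wvec[yb]
        wsum <- sum(wrow)
        dL <- P
        dL[cbind(seq_len(B), yb)] <- dL[cbind(seq_len(B), yb)] - 1
        dL <- dL * (wrow / wsum)
        gWd <- crossprod(fw$H, dL)
        gbd <- colSums(dL)
        dH <- dL %*% t(par$Wd)
        if (!is.null(drop_mask)) dH <- dH * drop_mask
        # un-pool the 2x2 average back onto the conv grid
        dA <- matrix(0, B * np, f)
        for (j in seq_len(f)) {
          dHj <- dH[, (j - 1L) * q * q + seq_len(q * q), drop = FALSE]
          for (bi in seq_len(B)) {
            dAj <- t(Pq) %*% matrix(dHj[bi, ], q, q) %*% Pq
            dA[(seq_len(np) - 1L) * B + bi, j] <- as.vector(dAj)
          }
        }
        # fw$cols/Z rows are ordered batch-major within position blocks
        dZ <- dA * (fw$Z > 0)
        gWc <- crossprod(fw$cols, dZ)
        gbc <- colSums(dZ)
        grads <- list(Wc = gWc, bc = gbc, Wd = gWd, bd = gbd)
        step <- step + 1L
        for (nm in names(par)) {
          adam[[nm]]$m <- b1 * adam[[nm]]$m + (1 - b1) * grads[[nm]]
          adam[[nm]]$v <- b2 * adam[[nm]]$v + (1 - b2) * grads[[nm]]^2
          mh <- adam[[nm]]$m / (1 - b1^step)
          vh <- adam[[nm]]$v / (1 - b2^step)
          par[[nm]] <- par[[nm]] - hp$lr * mh / (sqrt(vh) + eps)
        }
      }
    }
  })
  model$params <- par
  model
}

#' Predict class labels with a trained tiny CNN
#'
#' @param object a trained `tiny_cnn`.
#' @param blocks list of input arrays.
#' @param ... unused.
#' @return Character vector of predicted labels.
#' @export
predict.tiny_cnn <- function(object, blocks, ...) {
  if (is.null(object$params)) stop("model has not been fitted")
  idx <- im2col_index(object$grid, object$input_depth)
  s <- object$grid; D <- object$input_depth
  Xb <- matrix(0, length(blocks), s * s * D)
  for (bi in seq_along(blocks)) {
    Xb[bi, ] <- (as.vector(pool_block(blocks[[bi]], object)) -
                   object$center) / object$scale
  }
  fw <- tiny_cnn_forward(object$params, object, Xb, idx, drop_mask = NULL)
  object$classes[apply(fw$logits, 1L, which.max)]
}

# ---- evaluation ---------------------------------------------------------

#' Train and evaluate over a subject-grouped CV plan
#'
#' Per fold: fit on the training subjects with class-weighted loss and
#' augmentation, predict the held-out subjects, and record a confusion
#' matrix; the fold matrices are aggregated by [confusion_metrics()].
#' Every fold retrains from a fresh initialization.
#'
#' @param data a [labeled_feature_set()].
#' @param plan a [make_cv_splits()] plan whose subjects are all present
#'   in `data`.
#' @param hp hyperparameters.
#' @param seed base seed; fold `i` trains with `seed + i`.
#' @param learner optional plug-in backbone: a function
#'   `(train_blocks, train_labels, weights, hp, seed)` returning a
#'   prediction function `blocks -> labels`.  Default trains the tiny
#'   CNN.
#' @return An `eval_report` (see [confusion_metrics()]) with
#'   `predictions` attached.
#' @export
train_and_evaluate <- function(data, plan, hp = default_hyperparameters(),
                               seed = 1L, learner = NULL) {
  if (!all(plan$subjects %in% data$subject_ids)) {
    stop("plan contains subjects absent from the data")
  }
  learner <- learner %||% function(blocks, labels, weights, hp, seed) {
    depth <- dim(blocks[[1]])[3]
    side <- dim(blocks[[1]])[1]
    model <- build_model(depth, n_classes = length(EMOTION_CLASSES),
                         input_side = side,
                         pool = max(1L, side %/% 28L))
    model <- fit_model(model, blocks, labels, weights, hp, seed)
    function(newblocks) predict(model, newblocks)
  }
  folds <- vector("list", length(plan$folds))
  preds_all <- list()
  for (i in seq_along(plan$folds)) {
    fold <- plan$folds[[i]]
    tr <- which(data$subject_ids %in% fold$train)
    te <- which(data$subject_ids %in% fold$test)
    if (length(tr) == 0L || length(te) == 0L) {
      stop("fold ", i, " has an empty train or test side")
    }
    if (length(intersect(data$subject_ids[tr], data$subject_ids[te])) > 0L) {
      stop("subject leakage in fold ", i)
    }
    w <- class_weights(data$labels[tr])  # errors if a class is absent
    predict_fun <- learner(data$blocks[tr], data$labels[tr], w, hp,
                           seed + i)
    pred <- as.character(predict_fun(data$blocks[te]))
    cm <- table(factor(data$labels[te], levels = EMOTION_CLASSES),
                factor(pred, levels = EMOTION_CLASSES))
    folds[[i]] <- unclass(as.matrix(cm))
    preds_all[[i]] <- data.frame(subject_id = data$subject_ids[te],
                                 truth = data$labels[te], pred = pred,
                                 fold = i, stringsAsFactors = FALSE)
  }
  report <- confusion_metrics(folds)
  report$predictions <- do.call(rbind, preds_all)
  report
}

#' Multi-class metric suite over CV fold confusion matrices
#'
#' Rows of each matrix are the true classes, columns the predictions.
#' Per fold and class: `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' F1 their harmonic mean, with the 0/0 convention that an undefined
#' ratio is 0 (flagged via `undefined_count`).  Macro metrics are
#' unweighted class means per fold, summarized by mean and SD across
#' folds.  The fold matrices are also summed and row-normalized.
#'
#' @param folds list of square count matrices (same dimension).
#' @return An object of class `eval_report`: `fold_matrices`,
#'   `summed_matrix`, `row_normalized` (rows summing to 1 where the row
#'   count is positive), `per_class` (data frame of per-fold per-class
#'   precision/recall/F1), `macro` (per-fold macro metrics), `accuracy`
#'   (overall trace/total), `macro_mean`, `macro_sd`,
#'   `undefined_count`.
#' @export
confusion_metrics <- function(folds) {
  if (length(folds) == 0L) stop("need at least one confusion matrix")
  k <- nrow(folds[[1]])
  classes <- rownames(folds[[1]]) %||% EMOTION_CLASSES[seq_len(k)]
  undef <- 0L
  per_class <- list()
  macro <- list()
  for (i in seq_along(folds)) {
    M <- folds[[i]]
    tp <- diag(M)
    fp <- colSums(M) - tp
    fn <- rowSums(M) - tp
    prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
    rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
    undef <- undef + sum(tp + fp == 0) + sum(tp + fn == 0)
    f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    per_class[[i]] <- data.frame(fold = i, class = classes,
                                 precision = as.numeric(prec),
                                 recall = as.numeric(rec),
                                 f1 = as.numeric(f1),
                                 stringsAsFactors = FALSE)
    macro[[i]] <- data.frame(fold = i,
                             accuracy = sum(tp) / max(sum(M), 1),
                             precision = mean(prec), recall = mean(rec),
                             f1 = mean(f1))
  }
  per_class <- do.call(rbind, per_class)
  macro <- do.call(rbind, macro)
  S <- Reduce(`+`, folds)
  rn <- S / ifelse(rowSums(S) > 0, rowSums(S), 1)
  structure(list(fold_matrices = folds, summed_matrix = S,
                 row_normalized = rn, per_class = per_class, macro = macro,
                 accuracy = sum(diag(S)) / sum(S),
                 macro_mean = colMeans(macro[, -1, drop = FALSE]),
                 macro_sd = apply(macro[, -1, drop = FALSE], 2L, stats::sd),
                 undefined_count = undef),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d folds, overall accuracy %.4f\n",
              length(x$fold_matrices), x$accuracy))
  cat("macro means:",
      paste(sprintf("%s=%.4f", names(x$macro_mean), x$macro_mean),
            collapse = "  "), "\n")
  cat("summed row-normalized confusion matrix:\n")
  print(round(x$row_normalized, 3))
  invisible(x)
}
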