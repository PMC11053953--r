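test_that("leave-5-out splits partition subjects into disjoint covering folds", {
  subj110 <- sprintf("s%03d", 1:110)
  plan <- make_cv_splits(subj110, group_size = 5, seed = 1)
  expect_length(plan$folds, 22L)
  tests <- lapply(plan$folds, `[[`, "test")
  expect_true(all(lengths(tests) == 5L))
  expect_setequal(unlist(tests), subj110)
  for (i in seq_along(tests)) {
    expect_length(intersect(plan$folds[[i]]$train, tests[[i]]), 0L)
    for (j in seq_along(tests)) {
      if (i != j) expect_length(intersect(tests[[i]], tests[[j]]), 0L)
    }
  }
  plan10 <- make_cv_splits(sprintf("p%d", 1:10), group_size = 5, seed = 2)
  expect_length(plan10$folds, 2L)
  expect_setequal(unlist(lapply(plan10$folds, `[[`, "test")),
                  sprintf("p%d", 1:10))
  expect_error(make_cv_splits(c("a", "b"), group_size = 5), "exceeds")
  expect_warning(make_cv_splits(sprintf("q%d", 1:7), group_size = 5,
                                seed = 1), "not divisible")
})

test_that("class weights are inverse-frequency and order-invariant", {
  balanced <- rep(c("A", "D", "F", "S", "N"), each = 4)
  expect_true(all(class_weights(balanced) == 1))
  labs <- c(rep("A", 10), rep("D", 10), rep("F", 5), rep("S", 10),
            rep("N", 15))
  w <- class_weights(labs)
  expect_equal(unname(w["F"]), 50 / (5 * 5))
  expect_equal(w, class_weights(sample(labs)))
  expect_error(class_weights(c("A", "D")), "absent.*F.*S.*N")
})

test_that("augmentation rotates by quarter turns and zeroes whole pixels", {
  set.seed(3)
  block <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  # with no pixel drop the result is one of the four rotations
  out <- augment_block(block, pixel_drop_p = 0, seed = 11)
  r0 <- block
  r90 <- r180 <- r270 <- block
  for (j in 1:3) {
    m <- block[, , j]
    m90 <- t(m)[, rev(seq_len(16))]
    r90[, , j] <- m90
    r180[, , j] <- t(m90)[, rev(seq_len(16))]
    r270[, , j] <- t(r180[, , j])[, rev(seq_len(16))]
  }
  expect_true(any(vapply(list(r0, r90, r180, r270),
                         function(r) isTRUE(all.equal(out, r)),
                         logical(1))))
  # rotating by 180 twice restores the block
  twice <- r180
  for (j in 1:3) twice[, , j] <- t(t(r180[, , j])[, rev(seq_len(16))])[, rev(seq_len(16))]
  expect_equal(twice, block)
  # dropped pixels lose their whole depth vector
  dropped <- augment_block(block, pixel_drop_p = 0.5, seed = 5)
  zeroed <- apply(dropped == 0, c(1, 2), all)
  for (j in 1:3) expect_true(all(dropped[, , j][zeroed] == 0))
})

test_that("the pixel-drop rate matches its binomial expectation", {
  block <- array(1, c(224, 224, 1))
  p <- 1 / 124
  counts <- vapply(1:200, function(s) {
    out <- augment_block(block, pixel_drop_p = p, seed = s)
    sum(out[, , 1] == 0)
  }, numeric(1))
  expect_equal(mean(counts), 224^2 * p, tolerance = 0.05)
})

test_that("the tiny CNN meets its shape contract for any input depth", {
  for (depth in c(5L, 10L)) {
    m <- build_model(depth, input_side = 28L, pool = 1L)
    m <- fit_model(m, replicate(6, array(rnorm(28 * 28 * depth),
                                         c(28, 28, depth)),
                                simplify = FALSE),
                   c("A", "D", "F", "S", "N", "A"),
                   hp = default_hyperparameters(epochs = 1, augment = FALSE),
                   seed = 1)
    pred <- predict(m, list(array(0, c(28, 28, depth))))
    expect_length(pred, 1L)
    expect_true(pred %in% c("A", "D", "F", "S", "N"))
  }
  expect_error(build_model(5, backbone = "resnet"), "unsupported backbone")
  expect_error(build_model(0), ">= 1")
})

test_that("the tiny CNN overfits a small memorizable set", {
  set.seed(9)
  labs <- rep(c("A", "D", "F", "S", "N"), length.out = 8)
  blocks <- lapply(seq_len(8), function(i) {
    base <- array(rnorm(28 * 28 * 2, sd = 0.5), c(28, 28, 2))
    base[(i * 3):(i * 3 + 2), 4:6, ] <- 6   # distinct landmark per sample
    base
  })
  m <- build_model(2, input_side = 28L, pool = 1L)
  m <- fit_model(m, blocks, labs,
                 hp = default_hyperparameters(epochs = 25, lr = 0.01,
                                              batch_size = 8, dropout = 0,
                                              augment = FALSE),
                 seed = 2)
  expect_equal(mean(predict(m, blocks) == labs), 1)
})

test_that("an injected perfect oracle yields a diagonal summed matrix", {
  classes <- c("A", "D", "F", "S", "N")
  n_subj <- 6
  blocks <- list(); labels <- character(0); subj <- character(0)
  for (i in 1:n_subj) for (cl in classes) {
    b <- array(0, c(8, 8, 1))
    b[1, 1, 1] <- match(cl, classes)   # label written into the block
    blocks[[length(blocks) + 1]] <- b
    labels <- c(labels, cl); subj <- c(subj, paste0("s", i))
  }
  data <- labeled_feature_set(blocks, labels, subj)
  plan <- make_cv_splits(unique(subj), group_size = 3, seed = 1)
  oracle <- function(trb, trl, w, hp, seed) {
    function(newblocks) {
      vapply(newblocks, function(b) classes[b[1, 1, 1]], character(1))
    }
  }
  rep <- train_and_evaluate(data, plan, seed = 1, learner = oracle)
  expect_equal(rep$accuracy, 1)
  expect_true(all(rep$per_class$f1 == 1))
  S <- rep$summed_matrix
  expect_equal(sum(diag(S)), sum(S))
})

test_that("a constant predictor has recall 1 on its class and prevalence accuracy", {
  classes <- c("A", "D", "F", "S", "N")
  blocks <- replicate(40, array(0, c(4, 4, 1)), simplify = FALSE)
  labels <- rep(classes, 8)
  subj <- rep(sprintf("s%d", 1:8), each = 5)
  data <- labeled_feature_set(blocks, labels, subj)
  plan <- make_cv_splits(unique(subj), group_size = 4, seed = 3)
  always_n <- function(trb, trl, w, hp, seed) {
    function(newblocks) rep("N", length(newblocks))
  }
  rep <- train_and_evaluate(data, plan, seed = 1, learner = always_n)
  rec <- rep$per_class
  expect_true(all(rec$recall[rec$class == "N"] == 1))
  expect_true(all(rec$recall[rec$class != "N"] == 0))
  expect_equal(rep$accuracy, mean(labels == "N"))
})

test_that("metrics match hand-computed values on a printed 2x2 matrix", {
  M <- matrix(c(3, 2, 1, 4), 2, 2)   # rows = truth, cols = prediction
  rownames(M) <- colnames(M) <- c("x", "y")
  rep <- confusion_metrics(list(M))
  p <- rep$per_class
  expect_equal(p$precision[p$class == "x"], 3 / 5)
  expect_equal(p$recall[p$class == "x"], 3 / 4)
  expect_equal(p$f1[p$class == "x"], 2 * 0.6 * 0.75 / (0.6 + 0.75))
  ident <- diag(c(7, 9)); rownames(ident) <- colnames(ident) <- c("x", "y")
  rep2 <- confusion_metrics(list(ident))
  expect_true(all(rep2$per_class[, c("precision", "recall", "f1")] == 1))
  expect_equal(rep2$accuracy, 1)
})

test_that("row-normalized summed matrices have unit row sums", {
  set.seed(8)
  folds <- lapply(1:5, function(i) matrix(rpois(25, 4), 5, 5))
  rep <- confusion_metrics(folds)
  expect_equal(rowSums(rep$row_normalized), rep(1, 5), ignore_attr = TRUE)
  expect_equal(rep$accuracy,
               sum(diag(rep$summed_matrix)) / sum(rep$summed_matrix))
})

test_that("accuracy agrees with an independent recount of stored predictions", {
  classes <- c("A", "D", "F", "S", "N")
  set.seed(12)
  blocks <- replicate(30, array(rnorm(16), c(4, 4, 1)), simplify = FALSE)
  labels <- sample(classes, 30, TRUE)
  labels[1:5] <- classes            # ensure all classes present everywhere
  labels[26:30] <- classes
  subj <- rep(c("a", "b"), each = 15)
  data <- labeled_feature_set(blocks, labels, subj)
  plan <- make_cv_splits(c("a", "b"), group_size = 1, seed = 1)
  noisy <- function(trb, trl, w, hp, seed) {
    function(newblocks) sample(classes, length(newblocks), TRUE)
  }
  rep <- train_and_evaluate(data, plan, seed = 4, learner = noisy)
  expect_equal(rep$accuracy,
               mean(rep$predictions$pred == rep$predictions$truth))
  # no subject leakage between train and test of any fold
  for (f in plan$folds) expect_length(intersect(f$train, f$test), 0L)
})

test_that("weighted loss lifts minority-class recall versus uniform weights", {
  classes <- c("A", "D", "F", "S", "N")
  make_set <- function(seed) {
    set.seed(seed)
    labs <- c(rep("A", 4), rep(c("D", "F", "S", "N"), each = 12))
    blocks <- lapply(labs, function(cl) {
      b <- array(rnorm(14 * 14 * 1, sd = 2.5), c(14, 14, 1))
      k <- match(cl, classes)
      b[(2 * k - 1):(2 * k), , 1] <- b[(2 * k - 1):(2 * k), , 1] + 2
      b
    })
    list(blocks = blocks, labels = labs)
  }
  hpu <- default_hyperparameters(epochs = 8, batch_size = 16, dropout = 0,
                                 augment = FALSE, lr = 0.01)
  recall_minority <- function(seed, weighted) {
    tr <- make_set(seed); te <- make_set(seed + 100)
    m <- build_model(1, input_side = 14L, pool = 1L)
    w <- if (weighted) class_weights(tr$labels) else
      stats::setNames(rep(1, 5), classes)
    m <- fit_model(m, tr$blocks, tr$labels, weights = w, hp = hpu,
                   seed = seed)
    pred <- predict(m, te$blocks)
    mean(pred[te$labels == "A"] == "A")
  }
  seeds <- 1:10
  rec_w <- vapply(seeds, recall_minority, numeric(1), weighted = TRUE)
  rec_u <- vapply(seeds, recall_minority, numeric(1), weighted = FALSE)
  expect_gt(mean(rec_w), mean(rec_u))
})
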