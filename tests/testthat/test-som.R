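# Kohonen map, participant holdout, classification metrics.

test_that("participant holdout hits the 70/30 row target when feasible", {
  # 1,350 rows over 40 participants with uneven counts
  set.seed(2)
  cnt <- rep(33:35, length.out = 40)
  cnt[1] <- cnt[1] + (1350 - sum(cnt))
  rows <- data.frame(participant_id = rep(sprintf("p%02d", 1:40), cnt))
  sp <- split_participant_holdout(rows, 0.7, seed = 9)
  expect_equal(sp$target_train, 945)
  expect_equal(sp$achieved_train, 945)
  expect_equal(nrow(sp$test), 405)
  expect_length(intersect(unique(sp$train$participant_id),
                          unique(sp$test$participant_id)), 0)
  # exact divisibility: 10 x 10 rows at 0.7
  rows2 <- data.frame(participant_id = rep(sprintf("q%d", 1:10), each = 10))
  sp2 <- split_participant_holdout(rows2, 0.7, seed = 1)
  expect_equal(nrow(sp2$train), 70)
  expect_length(unique(sp2$train$participant_id), 7)
  # infeasible extreme fraction warns
  rows3 <- data.frame(participant_id = rep(c("a", "b"), each = 50))
  expect_warning(sp3 <- split_participant_holdout(rows3, 0.999, seed = 1),
                 "not reachable")
  expect_equal(sort(c(nrow(sp3$train), nrow(sp3$test))), c(50, 50))
  expect_error(split_participant_holdout(
    data.frame(participant_id = rep("a", 5)), 0.7, 1), "participants")
})

test_that("codebook converges to a repeated training vector", {
  v <- c(3, -1, 2)
  x <- matrix(v, 50, 3, byrow = TRUE)
  cfg <- som_config(n_iterations = 10000, seed = 2)
  m <- train_som(x, labels = rep("a", 50), config = cfg, scale = FALSE)
  expect_lt(max(abs(sweep(m$codebook, 2, v))), 1e-3)
  expect_true(all(m$unit_labels[!is.na(m$unit_labels)] == "a"))
})

test_that("well-separated classes give contiguous regions and accuracy", {
  set.seed(1)
  k <- 200
  x <- rbind(matrix(rnorm(k * 6, 0), ncol = 6),
             matrix(rnorm(k * 6, 10), ncol = 6),
             matrix(rnorm(k * 6, -10), ncol = 6))
  lab <- rep(c("a", "b", "c"), each = k)
  m <- train_som(x, lab, som_config(seed = 4))
  expect_equal(mean(predict(m, x) == lab), 1)
  xt <- rbind(matrix(rnorm(180, 0), ncol = 6),
              matrix(rnorm(180, 10), ncol = 6),
              matrix(rnorm(180, -10), ncol = 6))
  expect_gte(mean(predict(m, xt) == rep(c("a", "b", "c"), each = 30)),
             0.95)
  # each class's units form one connected region on the grid
  for (cl in c("a", "b", "c")) {
    units <- which(m$unit_labels == cl)
    expect_gt(length(units), 0)
    # connected: every unit of the class is within one grid step of another
    if (length(units) > 1) {
      dd <- m$unit_dist[units, units]
      diag(dd) <- Inf
      expect_lt(max(apply(dd, 1, min)), 1.01)
    }
  }
  # determinism
  m2 <- train_som(x, lab, som_config(seed = 4))
  expect_identical(m$codebook, m2$codebook)
})

test_that("a single bubble update contracts the winner toward the sample", {
  set.seed(3)
  x <- matrix(rnorm(200 * 4), 200, 4)
  # lr ~ 0 run freezes the seeded initialization for comparison
  m0 <- train_som(x, config = som_config(n_iterations = 1, lr_start = 1e-12,
                                         lr_end = 0, radius_start = 1e-6,
                                         seed = 5))
  m1 <- train_som(x, config = som_config(n_iterations = 1, lr_start = 0.5,
                                         lr_end = 0, radius_start = 1e-6,
                                         seed = 5))
  moved <- which(rowSums(abs(m1$codebook - m0$codebook)) > 1e-9)
  expect_length(moved, 1)   # radius ~ 0: only the BMU moves
  w0 <- m0$codebook[moved, ]; w1 <- m1$codebook[moved, ]
  # invert the update rule to recover the drawn (standardized) sample
  x_hat <- w0 + (w1 - w0) / 0.5
  z <- sweep(sweep(x, 2, m1$center), 2, m1$scale, "/")
  gap <- min(colSums((t(z) - x_hat)^2))
  expect_lt(gap, 1e-12)     # x_hat is an actual training row
  expect_lt(sum((w1 - x_hat)^2), sum((w0 - x_hat)^2))
})

test_that("grid neighbors stay closer in codebook space than random pairs", {
  set.seed(6)
  th <- runif(800, 0, 2 * pi)
  x <- cbind(cos(th), sin(th)) + matrix(rnorm(1600, 0, 0.05), ncol = 2)
  m <- train_som(x, config = som_config(n_iterations = 5000, seed = 7))
  d_cb <- as.matrix(dist(m$codebook))
  adj <- m$unit_dist > 0 & m$unit_dist <= 1.01
  far <- m$unit_dist > 1.01
  expect_lt(mean(d_cb[adj]) / mean(d_cb[far]), 0.5)
})

test_that("prediction falls back to the nearest labeled unit", {
  set.seed(9)
  x <- matrix(rnorm(200 * 3), ncol = 3)
  m <- train_som(x, labels = rep(c("u", "v"), 100), som_config(seed = 1))
  m$unit_labels[2:36] <- NA  # only unit 1 labeled
  m$unit_labels[1] <- "u"
  expect_true(all(predict(m, x) == "u"))
  m$unit_labels[] <- NA
  expect_error(predict(m, x), "no labeled units")
  expect_error(predict(train_som(x, rep("a", 200), som_config(seed = 1)),
                       matrix(0, 2, 7)), "features")
})

test_that("classification metrics match brute-force counting", {
  # printed three-class case
  cm <- matrix(c(134, 0, 1, 0, 135, 0, 0, 0, 135), 3, byrow = TRUE,
               dimnames = list(c("badfiction", "fanfiction", "original"),
                               c("badfiction", "fanfiction", "original")))
  r <- classification_report(cm)
  expect_equal(round(unname(r$f1), 3), c(0.996, 1.000, 0.996))
  # perfect diagonal
  rp <- evaluate_classification(rep(text_types(), 5), rep(text_types(), 5))
  expect_true(all(rp$f1 == 1))
  expect_equal(rp$accuracy, 1)
  # uniform single-class predictions vs a brute-force oracle
  set.seed(10)
  truth <- sample(text_types(), 60, TRUE)
  pred <- rep("original", 60)
  r2 <- evaluate_classification(truth, pred)
  brute_tp <- sum(truth == "original")
  expect_equal(unname(r2$recall["original"]), 1)
  expect_equal(unname(r2$recall["badfiction"]), 0)
  expect_equal(unname(r2$precision["original"]), brute_tp / 60)
  expect_equal(r2$accuracy, brute_tp / 60)
  expect_equal(sum(r2$confusion), 60)
  expect_equal(as.integer(rowSums(r2$confusion)),
               as.integer(table(factor(truth,
                                       levels = rownames(r2$confusion)))))
  expect_error(evaluate_classification(character(), character()), "empty")
})
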