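test_that("ROC threshold selection matches hand-computed distances", {
  # perfect classifier: the (0, 1) point wins
  roc <- data.frame(threshold = c(0.9, 0.5, 0.1),
                    fpr = c(0, 0, 1), tpr = c(0.4, 1, 1))
  expect_equal(select_probability_threshold(roc), 0.5)
  # distances: (0,0)->1, (0.2,0.9)->0.2236, (1,1)->1
  roc2 <- data.frame(threshold = c(0.9, 0.5, 0.1),
                     fpr = c(0, 0.2, 1), tpr = c(0, 0.9, 1))
  expect_equal(select_probability_threshold(roc2), 0.5)
  # tie -> higher threshold
  roc3 <- data.frame(threshold = c(0.8, 0.3),
                     fpr = c(0, 0.6), tpr = c(0.4, 1))
  d <- sqrt(roc3$fpr^2 + (1 - roc3$tpr)^2)
  expect_equal(d[1], d[2])
  expect_equal(select_probability_threshold(roc3), 0.8)
  # invariance to row order
  expect_equal(select_probability_threshold(roc2[c(3, 1, 2), ]), 0.5)
})

test_that("ROC/AUC agree with brute force on random instances", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    sc <- round(runif(n), 2)
    lab <- sample(c("walk", "other"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("walk", "other")
    roc <- roc_curve(sc, lab)
    # brute-force AUC = P(score_pos > score_neg) + 0.5 P(tie)
    pos <- sc[lab == "walk"]; neg <- sc[lab != "walk"]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(attr(roc, "auc"), mean(cmp), tolerance = 1e-12)
    # brute-force best threshold
    ds <- sqrt(roc$fpr^2 + (1 - roc$tpr)^2)
    best <- max(roc$threshold[ds == min(ds)])
    expect_equal(select_probability_threshold(roc), best)
  }
})

test_that("LOSO is perfect on separable data and chance on shuffled labels", {
  set.seed(12)
  n <- 40
  d <- data.frame(subject = rep(sprintf("S%d", 1:5), each = n),
                  label = rep(rep(c("walk", "other"), each = n / 2), 5))
  d$f1 <- ifelse(d$label == "walk", 5, 0) + rnorm(nrow(d), sd = 0.3)
  d$f2 <- rnorm(nrow(d))
  cv <- loso_cross_validate(d, feature_cols = c("f1", "f2"))
  expect_equal(cv$metrics$accuracy, 1)
  expect_equal(cv$metrics$auc, 1)
  d$label <- sample(d$label)
  d$f1 <- rnorm(nrow(d))
  cv2 <- loso_cross_validate(d, feature_cols = c("f1", "f2"))
  expect_lt(abs(cv2$metrics$auc - 0.5), 0.1)
})

test_that("LOSO pooled accuracy tracks a known Bayes rate", {
  set.seed(77)
  # one informative feature, class means +/-1.645, unit SD:
  # Bayes accuracy = pnorm(1.645) ~ 0.95
  n_sub <- 12; n_per <- 40
  d <- data.frame(
    subject = rep(sprintf("S%02d", 1:n_sub), each = n_per),
    label = rep(rep(c("walk", "other"), each = n_per / 2), n_sub))
  d$f1 <- rnorm(nrow(d), ifelse(d$label == "walk", 1.645, -1.645), 1)
  cv <- loso_cross_validate(d, feature_cols = "f1")
  expect_lt(abs(cv$metrics$accuracy - 0.95), 0.03)
})

test_that("held-out subjects cannot poison feature selection or scaling", {
  d <- fixture_activity
  cv1 <- loso_cross_validate(d, feature_cols = fixture_feature_cols)
  poisoned <- d
  victim <- unique(d$subject)[2]
  poisoned[poisoned$subject == victim, fixture_feature_cols] <-
    poisoned[poisoned$subject == victim, fixture_feature_cols] * 1000 + 50
  cv2 <- loso_cross_validate(poisoned, feature_cols = fixture_feature_cols)
  k <- which(vapply(cv1$folds, `[[`, character(1), "subject") == victim)
  expect_identical(cv2$folds[[k]]$selected_features,
                   cv1$folds[[k]]$selected_features)
  expect_identical(cv2$folds[[k]]$center, cv1$folds[[k]]$center)
  expect_identical(cv2$folds[[k]]$scale, cv1$folds[[k]]$scale)
  expect_identical(cv2$folds[[k]]$sv_coef, cv1$folds[[k]]$sv_coef)
  expect_identical(cv2$folds[[k]]$b, cv1$folds[[k]]$b)
})

test_that("bout aggregation enforces the run and posterior rules", {
  # [W, W, N, W] with posteriors [0.9, 0.85, 0.95, 0.99] -> one 8 s bout
  bw <- build_walking_bouts(c(TRUE, TRUE, FALSE, TRUE),
                            c(0.9, 0.85, 0.95, 0.99))
  expect_length(bw$bouts, 1)
  expect_equal(bw$bouts[[1]]$window_indices, 1:2)
  expect_equal(bw$walking_time_s, 8)
  # [W, W] with a posterior below 0.8 -> no bout
  bw2 <- build_walking_bouts(c(TRUE, TRUE), c(0.9, 0.7))
  expect_length(bw2$bouts, 0)
  expect_equal(bw2$walking_time_s, 0)
  # ten walking windows merge into one 40 s bout
  bw3 <- build_walking_bouts(rep(TRUE, 10), rep(0.9, 10))
  expect_length(bw3$bouts, 1)
  expect_equal(bw3$walking_time_s, 40)
  # clipped window poisons its bout
  bw4 <- build_walking_bouts(rep(TRUE, 4), rep(0.9, 4),
                             clipped = c(FALSE, TRUE, FALSE, FALSE))
  expect_length(bw4$bouts, 0)
})

test_that("bout construction is idempotent and accounts walking time", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    lab <- runif(n) > 0.4
    post <- runif(n)
    bw <- build_walking_bouts(lab, post)
    n_kept <- sum(vapply(bw$bouts, function(b) length(b$window_indices),
                         integer(1)))
    expect_equal(bw$walking_time_s, 4 * n_kept)
    for (b in bw$bouts) {
      expect_true(all(diff(b$window_indices) == 1))
      expect_gte(length(b$window_indices), 2)
      expect_true(all(b$posteriors >= 0.8))
      expect_true(all(lab[b$window_indices]))
    }
  }
})
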