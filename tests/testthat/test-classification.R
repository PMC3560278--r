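sep_clouds <- function(n = 10, p = 5, gap = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * p, -gap / 2), n),
             matrix(rnorm(n * p, gap / 2), n))
  colnames(X) <- sprintf("f%02d", seq_len(p))
  list(x = X, y = rep(c("good", "bad"), each = n))
}

test_that("linearly separable clouds train to perfect accuracy", {
  d <- sep_clouds()
  m <- train_classifier(d$x, d$y)
  expect_equal(m$training_accuracy, 1)
  expect_equal(predict(m, d$x), d$y)
  # a vector identical to a good training vector classifies as good
  expect_equal(predict(m, d$x[1, , drop = FALSE]), "good")
})

test_that("featureless data predicts the majority class", {
  X <- matrix(1, 10, 3)
  y <- rep(c("good", "bad"), c(6, 4))
  m <- train_classifier(X, y)
  expect_equal(m$training_accuracy, 0.6)
})

test_that("training rejects degenerate inputs", {
  X <- matrix(rnorm(20), 10)
  expect_error(train_classifier(X, rep("good", 10)), "two classes")
  expect_error(train_classifier(X, c("good", rep("bad", 9))),
               "at least two")
  expect_error(train_classifier(X, rep(c("good", "bad"), 4)), "length")
})

test_that("stored-parameter prediction agrees with a direct libsvm refit", {
  d <- sep_clouds(n = 15, gap = 2, seed = 2)
  for (kern in c("linear", "radial")) {
    m <- train_classifier(d$x, d$y, kernel = kern, cost = 2)
    # independent route: refit with e1071 on identically standardised data
    mu <- colMeans(d$x); sg <- apply(d$x, 2, sd)
    Xs <- scale(d$x, mu, sg)
    fit <- e1071::svm(Xs, factor(d$y, levels = c("bad", "good")),
                      kernel = kern, cost = 2, gamma = 1 / ncol(d$x),
                      scale = FALSE)
    expect_equal(predict(m, d$x),
                 as.character(predict(fit, Xs)))
  }
})

test_that("prediction is batch-consistent and dimension-checked", {
  d <- sep_clouds(seed = 3)
  m <- train_classifier(d$x, d$y)
  batch <- predict(m, d$x)
  single <- vapply(seq_len(nrow(d$x)),
                   function(i) predict(m, d$x[i, , drop = FALSE]),
                   character(1))
  expect_equal(batch, single)
  expect_error(predict(m, d$x[, 1:3]), "dimension")
})

test_that("evaluation reports distinguish rates in Table form", {
  perfect <- confusion_report(rep(c("good", "bad"), each = 10),
                              rep(c("good", "bad"), each = 10))
  expect_equal(unname(perfect$rates), rbind(c(100, 0), c(0, 100)))
  degenerate <- confusion_report(rep(c("good", "bad"), each = 10),
                                 rep("good", 20))
  expect_equal(unname(degenerate$rates), rbind(c(100, 0), c(100, 0)))
  hand <- confusion_report(rep(c("good", "bad"), each = 10),
                           c(rep("good", 9), "bad",
                             rep("bad", 8), "good", "good"))
  expect_equal(unname(hand$rates), rbind(c(90, 10), c(20, 80)))
  expect_equal(unname(rowSums(hand$confusion)), c(10, 10))
  expect_true(all(abs(rowSums(hand$rates) - 100) <= 0.1))
  expect_error(confusion_report(character(0), character(0)), "non-empty")
})

test_that("standardisation never leaks test statistics into training", {
  set.seed(5)
  X <- matrix(rnorm(200), 20)
  y <- rep(c("good", "bad"), 10)
  tr <- 1:12
  m_clean <- train_classifier(X[tr, ], y[tr])
  m_leaky <- train_classifier(X, y)
  dv_clean <- decision_values(m_clean, X[-tr, ])
  dv_leaky <- decision_values(m_leaky, X[-tr, ])
  expect_false(isTRUE(all.equal(dv_clean, dv_leaky)))
  # the clean model's scaler depends on training rows only
  expect_equal(m_clean$mu, unname(colMeans(X[tr, ])))
})

test_that("cross-validation is stratified, seeded, and honest about chance", {
  d <- sep_clouds(n = 20, seed = 6)
  cv <- cross_validate(d$x, d$y, k_folds = 5, seed = 1)
  expect_true(all(cv$per_fold$accuracy == 100))
  cv2 <- cross_validate(d$x, d$y, k_folds = 5, seed = 1)
  expect_identical(cv$folds, cv2$folds)
  # every fold holds out both classes
  for (f in 1:5) expect_setequal(unique(d$y[cv$folds == f]),
                                 c("good", "bad"))

  set.seed(7)
  y_null <- sample(d$y)
  cv_null <- cross_validate(d$x, y_null, k_folds = 5, seed = 2)
  se <- 100 * sqrt(0.25 / length(y_null))
  expect_lt(abs(cv_null$accuracy - 50), 3 * se + 1e-9)
  few <- c(1:3, 21:23)
  expect_error(cross_validate(d$x[few, ], d$y[few], k_folds = 5), "folds")
})

test_that("a small end-to-end pipeline beats the majority baseline", {
  bm <- run_scatter_benchmark(n_good = 10, n_bad = 10, seed = 1,
                              good_params = small_params("good"),
                              bad_params = small_params("bad"),
                              k = 100)
  acc <- sum(diag(bm$report$confusion)) / bm$n_test
  expect_gte(acc - bm$majority_accuracy, 0.3)
})
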