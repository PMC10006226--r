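test_that("ROC endpoints, perfect and inverted scores behave canonically", {
  truth <- c(0, 0, 1, 1)
  expect_equal(roc_auc(c(0, 0, 1, 1), truth)$auc, 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), truth)$auc, 0)
  r <- roc_auc(stats::runif(10), rep(c(0, 1), 5))
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "positive and.*negative")
  expect_error(roc_auc(1:3, c(0, 1, 2)), "binary")
})

test_that("trapezoidal AUC equals the rank-statistic U / (n1 n2)", {
  set.seed(111)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) next
    scores <- round(stats::rnorm(n), sample(0:2, 1))  # provoke ties
    auc <- roc_auc(scores, truth)$auc
    u <- mann_whitney_u(scores[truth == 1], scores[truth == 0])$U
    expect_lt(abs(auc - u / (sum(truth == 1) * sum(truth == 0))), 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(222)
  truth <- rbinom(50, 1, 0.5); truth[1:2] <- c(0, 1)
  scores <- stats::rnorm(50)
  base <- roc_auc(scores, truth)$auc
  expect_equal(roc_auc(exp(scores), truth)$auc, base)
  expect_equal(roc_auc(rank(scores), truth)$auc, base)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(333)
  truth <- rbinom(80, 1, 0.5); truth[1:2] <- c(0, 1)
  scores <- stats::rnorm(80) + truth
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, truth)$auc, ref, tolerance = 1e-12)
})

test_that("a perfectly separating feature gives accuracy and AUC 1", {
  df <- data.frame(group = rep(c(0L, 1L), each = 25),
                   ASM = rep(c(0, 100), each = 25))
  reports <- train_and_evaluate(df, seed = 3)
  for (r in reports) {
    expect_equal(r$accuracy, 1)
    expect_equal(r$auc, 1)
    expect_identical(r$n_train, 40L)
    expect_identical(r$n_test, 10L)
  }
})

test_that("classifier reports are reproducible for a fixed seed", {
  set.seed(444)
  df <- data.frame(group = rep(c(0L, 1L), each = 40),
                   ASM = stats::rnorm(80, rep(c(0, 1), each = 40)),
                   CON = stats::rnorm(80))
  a <- train_and_evaluate(df, seed = 11)
  b <- train_and_evaluate(df, seed = 11)
  for (m in names(a)) {
    expect_identical(a[[m]]$accuracy, b[[m]]$accuracy)
    expect_identical(a[[m]]$auc, b[[m]]$auc)
    expect_identical(a[[m]]$roc, b[[m]]$roc)
  }
  expect_error(train_and_evaluate(df[df$group == 0L, ], seed = 1),
               "both classes")
  expect_error(train_and_evaluate(df[c(1:10, 41:80), ], seed = 1),
               "at least 20")
})

test_that("undefined feature values are imputed and do not break training", {
  set.seed(555)
  df <- data.frame(group = rep(c(0L, 1L), each = 30),
                   ASM = stats::rnorm(60, rep(c(0, 2), each = 30)),
                   COR = stats::rnorm(60))
  df$COR[sample(60, 10)] <- NA
  reports <- train_and_evaluate(df, seed = 5)
  for (r in reports) expect_true(is.finite(r$auc))
})

test_that("rater evaluation reproduces confusion arithmetic", {
  perfect <- evaluate_rater(rep(c(0, 1), each = 10), rep(c(0, 1), each = 10))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$auc, 1)

  all0 <- evaluate_rater(rep(0, 20), rep(c(0, 1), each = 10))
  expect_equal(all0$accuracy, 0.5)
  expect_equal(all0$sensitivity, 0)
  expect_equal(all0$specificity, 1)
  expect_equal(all0$auc, 0.5)

  expect_error(evaluate_rater(c(0, 2), c(0, 1)), "binary")
  expect_error(evaluate_rater(c(0, 1, 0), c(0, 1)), "equal length")

  # reconstruction from printed rates inverts the forward arithmetic
  ev <- evaluate_rater(rep(c(1, 0, 0, 1), c(30, 20, 40, 10)),
                       rep(c(1, 1, 0, 0), c(30, 20, 40, 10)))
  ev2 <- rater_from_rates(ev$accuracy, ev$sensitivity, 50, 50)
  expect_identical(ev2$tp, ev$tp)
  expect_identical(ev2$tn, ev$tn)
  expect_equal(ev2$auc, ev$auc)
  # two-segment ROC through the operating point
  expect_equal(ev$points$fpr, c(0, 1 - ev$specificity, 1))
  expect_equal(ev$points$tpr, c(0, ev$sensitivity, 1))
})
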