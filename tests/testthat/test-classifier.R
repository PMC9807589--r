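test_that("single-class and tied classifiers follow the tie-break rule", {
  X <- random_realizations(40, 3, seed = 6)
  clf1 <- train_classifier(list(class_data("only", X)), criterion = "linear")
  pred <- classify(clf1, random_realizations(5, 3, seed = 7))
  expect_true(all(pred$predicted == "only"))

  # identical training data for every class: exact tie, smallest label wins
  clf3 <- train_classifier(list(class_data("c", X), class_data("a", X),
                                class_data("b", X)), criterion = "linear")
  pred3 <- classify(clf3, random_realizations(8, 3, seed = 8))
  expect_true(all(pred3$predicted == "a"))
})

test_that("widely separated classes are recovered on held-out draws", {
  bench <- make_benchmark("gaussian_shift", K = 2, I = 6, L_train = 200,
                          L_test = 250, seed = 5, delta = 10)
  for (cr in c("linear", "nonlinear")) {
    clf <- train_classifier(bench$train, criterion = cr)
    acc <- evaluate_accuracy(clf, bench$test)
    expect_gte(acc$overall, 99)
  }
})

test_that("unknown threshold extremes behave as documented", {
  sets <- two_class_sets(L = 50, I = 4)
  clf <- train_classifier(sets, criterion = "linear")
  probe <- sets[[1]]$X[1:5, ]
  expect_true(all(!classify(clf, probe, unknown_threshold = -1e6)$unknown))
  res_hi <- classify(clf, probe, unknown_threshold = 1e6)
  expect_true(all(res_hi$unknown))
  expect_true(all(res_hi$predicted == "unknown"))
  # trained-in threshold flags far outliers
  clf_u <- train_classifier(sets, criterion = "linear", unknown_quantile = 0.01)
  far <- matrix(50, 1, 4)
  expect_true(classify(clf_u, far)$unknown)
})

test_that("accuracy evaluation counts per class and rejects unseen labels", {
  sets <- two_class_sets(L = 60, I = 4)
  clf <- train_classifier(sets, criterion = "linear")
  acc_self <- evaluate_accuracy(clf, sets[1])
  expect_equal(unname(acc_self$per_class), 100)

  # permuted labels on a separated benchmark: complement of near-perfect
  swapped <- list(class_data("a", sets[[2]]$X), class_data("b", sets[[1]]$X))
  acc_sw <- evaluate_accuracy(clf, swapped)
  expect_lte(acc_sw$overall, 1)

  expect_error(evaluate_accuracy(clf, list(class_data("zz", sets[[1]]$X))),
               class = "canondx_invalid_input")
})

test_that("predictions are invariant to shared per-feature affine maps", {
  bench <- make_benchmark("quadratic_coupling", I = 6, L_train = 120,
                          L_test = 60, seed = 3)
  shift <- c(10, -5, 0.3, 100, -2, 7)
  scl <- c(0.01, 5, 2, 0.5, 40, 1)
  remap <- function(s) class_data(s$label,
                                  sweep(sweep(s$X, 2, scl, `*`), 2, shift, `+`))
  for (cr in c("linear", "nonlinear")) {
    clf <- train_classifier(bench$train, criterion = cr)
    clf2 <- train_classifier(lapply(bench$train, remap), criterion = cr)
    Xt <- do.call(rbind, lapply(bench$test, `[[`, "X"))
    p1 <- classify(clf, Xt)$predicted
    p2 <- classify(clf2, remap(class_data("t", Xt))$X)$predicted
    expect_identical(p1, p2)
  }
})

test_that("training rejects degenerate or inconsistent inputs", {
  Xconst <- matrix(rep(c(1, 2, 3, 4), each = 30), 30, 4)
  good <- class_data("g", random_realizations(30, 4, seed = 2))
  err <- tryCatch(train_classifier(list(class_data("flat", Xconst), good)),
                  error = identity)
  expect_s3_class(err, "canondx_training_error")
  expect_match(conditionMessage(err), "flat")
  expect_match(conditionMessage(err), "block")

  expect_error(train_classifier(list(
    class_data("a", matrix(rnorm(40), 10, 4)),
    class_data("b", matrix(rnorm(30), 10, 3)))),
    class = "canondx_invalid_input")
  expect_error(train_classifier(list(class_data("a", matrix(rnorm(4), 1, 4)))),
               class = "canondx_invalid_input")
  expect_error(train_classifier(list(good, good)),
               class = "canondx_invalid_input")
  clf <- train_classifier(list(good), criterion = "linear")
  expect_error(classify(clf, c(1, 2)), class = "canondx_invalid_input")
})

test_that("a multi-class study-shaped configuration trains with full decision sets", {
  # K classes, nonlinear order 4: every class ends with one decision density
  # per feature index, each fed by its own training coefficients
  bench <- make_benchmark("gaussian_shift", K = 3, I = 8, L_train = 150,
                          L_test = 10, seed = 9, delta = 1)
  clf <- train_classifier(bench$train, criterion = "nonlinear", N = 4)
  for (cl in clf$classes) {
    expect_length(cl$densities, 8)
    expect_true(all(vapply(cl$densities,
                           function(d) length(d$samples) == 150, logical(1))))
  }
})
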