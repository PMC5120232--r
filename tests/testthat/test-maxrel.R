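test_that("3-state discretization matches hand arithmetic", {
  expect_identical(as.character(discretize(c(5, 5, 5))),
                   rep("mid", 3))  # zero spread
  # mean 5, population sd 5, cuts at 2.5 / 7.5
  expect_identical(as.character(discretize(c(0, 0, 10, 10))),
                   c("low", "low", "high", "high"))
  # mean 5, population sd ~4.082, cuts at ~2.96 / ~7.04
  expect_identical(as.character(discretize(c(0, 5, 10))),
                   c("low", "mid", "high"))
})

test_that("discretization validates inputs and supports 2 states", {
  expect_error(discretize(numeric(0)), "empty input")
  expect_error(discretize(c(1, NA)), "finite")
  expect_error(discretization_rule(1), ">= 2")
  expect_error(discretization_rule(5), "2- or 3-state")
  expect_error(discretization_rule(3, alpha = -1), "positive")
  two <- discretization_rule(2)
  expect_identical(as.character(discretize(c(0, 0, 10, 10), two)),
                   c("low", "low", "high", "high"))
})

test_that("mutual information matches closed forms", {
  # independence -> 0 exactly
  expect_identical(mutual_information(c(1, 1, 0, 0), c("a", "b", "a", "b")), 0)
  # fully dependent balanced pair -> H(1/2) = 1 bit
  expect_equal(mutual_information(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1,
               tolerance = 1e-12)
  # fully dependent at class balance 1/3 -> H(1/3)
  expect_equal(mutual_information(c(1, 1, 0, 0, 0, 0), c(1, 1, 0, 0, 0, 0)),
               h2(1 / 3), tolerance = 1e-12)
  expect_error(mutual_information(c(1, 0), c(1, 0, 1)), "length mismatch")
})

test_that("MI closed form holds across class balances (property)", {
  for (k in 1:5) {
    lab <- c(rep(1, k), rep(0, 10 - k))
    expect_equal(mutual_information(lab, lab), h2(k / 10), tolerance = 1e-12)
  }
})

test_that("MI is symmetric, relabel-invariant and entropy-bounded", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(10:80, 1)
    x <- sample(0:1, n, replace = TRUE)
    y <- sample(letters[1:3], n, replace = TRUE)
    if (length(unique(x)) < 2L) x[1:2] <- 0:1
    mi <- mutual_information(x, y)
    expect_equal(mi, mutual_information(y, x), tolerance = 1e-12)
    # relabeling the states cannot change MI
    y2 <- c(a = "z", b = "q", c = "w")[y]
    expect_equal(mi, mutual_information(x, y2), tolerance = 1e-12)
    hx <- h2(mean(x))
    py <- as.vector(table(y)) / n
    hy <- -sum(py[py > 0] * log2(py[py > 0]))
    expect_true(mi >= 0 && mi <= min(hx, hy) + 1e-12)
  }
})

test_that("maxrel sorts by non-increasing MI with stable ties", {
  lab <- c(1, 1, 1, 0, 0, 0, 0, 0)
  x <- cbind(f_const = rep(2, 8),              # MI 0
             f_signal = c(9, 9, 9, 0, 0, 0, 0, 0),  # fully informative
             f_partial = c(9, 9, 0, 0, 0, 0, 0, 9)) # partially informative
  fit <- maxrel(x, lab)
  expect_identical(fit$ranking$feature_id,
                   c("f_signal", "f_partial", "f_const"))
  expect_identical(fit$ranking$rank, 1:3)
  expect_true(all(diff(fit$ranking$mi) <= 0))
  expect_equal(fit$ranking$mi[1], h2(3 / 8), tolerance = 1e-12)

  # identical columns tie and keep original column order
  x2 <- cbind(aa = x[, 2], bb = x[, 2])
  fit2 <- maxrel(x2, lab)
  expect_identical(fit2$ranking$feature_id, c("aa", "bb"))
})

test_that("maxrel validates labels and conserves the feature multiset", {
  x <- matrix(rnorm(40), ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  expect_error(maxrel(x, rep(1, 10)), "single class")
  expect_error(maxrel(x, c(rep(0, 9), 2)), "binary")
  expect_error(maxrel(x, c(0, 1)), "one element per row")

  set.seed(4)
  lab <- sample(0:1, 10, replace = TRUE)
  lab[1:2] <- 0:1
  fit <- maxrel(x, lab)
  expect_setequal(fit$ranking$feature_id, colnames(x))
  expect_identical(fit$ranking$rank, 1:4)
})

test_that("selection keeps the inclusive >= tau prefix with global ranks", {
  fx <- read_ranked_list(fixture_path())
  sel <- select_features(fx, tau = 0.01)
  expect_identical(nrow(sel$selected), 22L)
  expect_identical(sel$selected$rank, 1:22)
  expect_true(all(sel$selected$mi >= 0.01))

  # all below threshold -> empty but valid
  low <- data.frame(rank = 1:2, feature_id = c("x", "y"),
                    category = c("GO", "KEGG"), mi = c(0.009, 0.005))
  expect_identical(nrow(select_features(low, tau = 0.01)$selected), 0L)
  empty <- low[0, ]
  expect_identical(nrow(select_features(empty, tau = 0.01)$selected), 0L)
  expect_error(select_features(fx, tau = -1), "non-negative")
  # unsorted lists are rejected
  bad <- data.frame(rank = 1:2, feature_id = c("x", "y"),
                    category = "GO", mi = c(0.005, 0.009))
  expect_error(select_features(bad), "not sorted")
})

test_that("partition splits by category preserving global rank order", {
  sel <- select_features(read_ranked_list(fixture_path()), tau = 0.01)
  tabs <- partition_by_category(sel)
  expect_identical(nrow(tabs$kegg), 17L)
  expect_identical(nrow(tabs$go), 5L)
  expect_identical(tabs$go$rank, c(2L, 15L, 17L, 19L, 21L))
  expect_true(all(diff(tabs$kegg$rank) > 0))
  expect_setequal(c(tabs$kegg$rank, tabs$go$rank), sel$selected$rank)

  # empty selection -> two empty tables
  empty_sel <- select_features(sel$selected[0, ], tau = 0.01)
  tabs0 <- partition_by_category(empty_sel)
  expect_identical(nrow(tabs0$kegg), 0L)
  expect_identical(nrow(tabs0$go), 0L)

  # unknown category tag errors
  bad <- data.frame(rank = 1L, feature_id = "x", category = "REACTOME",
                    mi = 0.5)
  expect_error(partition_by_category(select_features(bad, 0.1)),
               "unknown feature category")
})
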