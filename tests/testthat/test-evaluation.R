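makeTable <- function(post, truth) {
  colnames(post) <- labels6
  df <- data.frame(individual = seq_len(nrow(post)))
  for (g in labels6) df[[paste0("P_", g)]] <- post[, g]
  df$map_class <- labels6[max.col(post)]
  list(table = df, truth = truth)
}

test_that("calibration bins report per-class proportions correct", {
  # every posterior 1 on the true class: top bin perfect, others empty
  truth <- rep(labels6, each = 5)
  post <- matrix(0, 30, 6); post[cbind(1:30, rep(1:6, each = 5))] <- 1
  tb <- makeTable(post, truth)
  cal <- calibrationTable(tb$table, tb$truth, bins = 10)
  top <- cal[cal$class != "all" & cal$midpoint > 0.9, ]
  expect_true(all(top$proportion == 1))
  expect_true(all(top$count == 5))
  low <- cal[cal$class != "all" & cal$midpoint > 0.15 & cal$midpoint < 0.85, ]
  expect_true(all(low$count == 0))
  expect_true(all(is.na(low$proportion)))
  # posteriors equal to the uniform prior: the 1/6 bin is ~1/6 correct
  post2 <- matrix(1 / 6, 60, 6)
  truth2 <- rep(labels6, each = 10)
  cal2 <- calibrationTable(makeTable(post2, truth2)$table, truth2,
                           bins = 20)
  binWith <- cal2[cal2$class == "all" & cal2$count > 0, ]
  expect_identical(nrow(binWith), 1L)
  expect_equal(binWith$proportion, 1 / 6, tolerance = 1e-12)
  expect_equal(binWith$meanPosterior, 1 / 6, tolerance = 1e-12)
  expect_error(calibrationTable(tb$table, tb$truth, bins = c(0, 0.5, 0.9)),
               "partition")
})

test_that("a perfectly calibrated table stays within binomial noise", {
  # build posteriors, then resample truth from the stated probabilities:
  # calibration is exact by construction
  set.seed(111)
  n <- 6000
  raw <- matrix(rgamma(n * 6, 0.4), n, 6)
  post <- raw / rowSums(raw)
  truth <- labels6[vapply(seq_len(n), function(i)
    sample.int(6, 1, prob = post[i, ]), integer(1))]
  cal <- calibrationTable(makeTable(post, truth)$table, truth, bins = 10)
  use <- cal[cal$class == "all" & cal$count >= 200, ]
  z <- (use$proportion - use$meanPosterior) /
    sqrt(use$meanPosterior * (1 - use$meanPosterior) / use$count)
  expect_true(all(abs(z) < 3.5))
})

test_that("power at a threshold counts true-class posteriors", {
  post <- rbind(c(0.95, 0.01, 0.01, 0.01, 0.01, 0.01),
                c(0.50, 0.30, 0.05, 0.05, 0.05, 0.05),
                c(0.05, 0.92, 0.01, 0.005, 0.01, 0.005),
                c(0.10, 0.85, 0.01, 0.01, 0.02, 0.01))
  truth <- c("a", "a", "b", "b")
  pw <- powerAtThreshold(makeTable(post, truth)$table, truth, t = 0.9)
  expect_equal(pw$power[pw$class == "a"], 0.5)
  expect_equal(pw$power[pw$class == "b"], 0.5)
  expect_equal(pw$argmax[pw$class == "a"], 1)
  pw0 <- powerAtThreshold(makeTable(post, truth)$table, truth, t = 0)
  expect_true(all(pw0$power[pw0$class %in% c("a", "b")] == 1))
  pw1 <- powerAtThreshold(makeTable(post, truth)$table, truth, t = 1)
  expect_true(all(pw1$power[pw1$class %in% c("a", "b")] == 0))
})

test_that("ROC points and AUC behave at the extremes", {
  set.seed(121)
  # posteriors independent of truth: AUC ~ 0.5
  n <- 3000
  raw <- matrix(rgamma(n * 6, 1), n, 6)
  post <- raw / rowSums(raw)
  truth <- sample(labels6, n, replace = TRUE)
  auc <- rocAuc(makeTable(post, truth)$table, truth, "c")
  expect_lt(abs(auc - 0.5), 0.05)
  # perfectly separating posteriors: AUC = 1
  truth2 <- rep(c("a", "b"), each = 10)
  post2 <- matrix(0.05, 20, 6)
  post2[1:10, 1] <- 0.9; post2[11:20, 2] <- 0.9
  expect_equal(rocAuc(makeTable(post2, truth2)$table, truth2, "a"), 1)
  # hand-computed points on a 6-row table
  post3 <- matrix(0.1, 6, 6)
  post3[, 1] <- c(0.9, 0.6, 0.3, 0.8, 0.2, 0.1)
  truth3 <- c("a", "a", "a", "b", "b", "b")
  roc <- rocPoints(makeTable(post3, truth3)$table, truth3, "a",
                   thresholds = c(0.25, 0.5, 0.75))
  expect_equal(roc$power, c(3, 2, 1) / 3)
  expect_equal(roc$typeI, c(1, 1, 1) / 3)
  expect_true(all(diff(roc$power) <= 0) && all(diff(roc$typeI) <= 0))
  expect_error(rocPoints(makeTable(post3, truth3)$table, truth3, "f"),
               "no individuals")
})

test_that("metrics are invariant to row permutation", {
  set.seed(131)
  n <- 500
  raw <- matrix(rgamma(n * 6, 1), n, 6)
  post <- raw / rowSums(raw)
  truth <- sample(labels6, n, replace = TRUE)
  perm <- sample.int(n)
  t1 <- makeTable(post, truth)$table
  t2 <- makeTable(post[perm, ], truth[perm])$table
  expect_equal(rocAuc(t1, truth, "d"), rocAuc(t2, truth[perm], "d"))
  c1 <- calibrationTable(t1, truth); c2 <- calibrationTable(t2, truth[perm])
  expect_equal(c1, c2)
  expect_equal(powerAtThreshold(t1, truth), powerAtThreshold(t2,
                                                             truth[perm]))
})
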