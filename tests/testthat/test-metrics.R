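test_that("confusion counts match a hand count on random vectors", {
  set.seed(3)
  for (rep in 1:20) {
    n <- 20
    calls <- sample(c("damaging", "tolerated"), n, TRUE)
    truths <- sample(c("pathogenic", "benign"), n, TRUE)
    mask <- sample(c(TRUE, FALSE), n, TRUE, prob = c(0.8, 0.2))
    cm <- confusion(calls, truths, mask)
    tp <- fp <- tn <- fn <- 0L
    for (i in seq_len(n)) {
      if (!mask[i]) next
      if (calls[i] == "damaging") {
        if (truths[i] == "pathogenic") tp <- tp + 1L else fp <- fp + 1L
      } else {
        if (truths[i] == "benign") tn <- tn + 1L else fn <- fn + 1L
      }
    }
    expect_identical(unclass(cm)[c("tp", "fp", "tn", "fn")],
                     list(tp = tp, fp = fp, tn = tn, fn = fn))
  }
  expect_equal(confusion(character(0), character(0), logical(0))$tp, 0L)
  expect_error(confusion("damaging", c("benign", "benign")), "equal length")
})

test_that("benchmark confusion matrices reproduce the published per-gene metrics", {
  # per-gene best combinations, matrices implied by class sizes + printed rates
  q1 <- confusion_matrix(tp = 94, fp = 0, tn = 8, fn = 7)     # 101/8
  expect_equal(round(sensitivity(q1), 1), 93.1)
  expect_equal(specificity(q1), 100)
  expect_equal(round(as.numeric(mcc(q1)), 2), 0.70)

  h2 <- confusion_matrix(tp = 75, fp = 1, tn = 7, fn = 7)     # 82/8
  expect_equal(round(accuracy(h2), 1), 91.1)
  expect_equal(round(sensitivity(h2), 1), 91.5)
  expect_equal(round(specificity(h2), 1), 87.5)
  expect_equal(round(as.numeric(mcc(h2)), 2), 0.62)

  s5 <- confusion_matrix(tp = 86, fp = 7, tn = 7, fn = 13)    # 99/14
  expect_equal(round(sensitivity(s5), 1), 86.9)
  expect_equal(round(specificity(s5), 1), 50.0)
  expect_equal(round(as.numeric(mcc(s5)), 2), 0.32)

  pooled <- confusion_matrix(tp = 234, fp = 6, tn = 24, fn = 48)  # 282/30
  expect_equal(round(accuracy(pooled), 1), 82.7)
  expect_equal(round(sensitivity(pooled), 1), 83.0)
  expect_equal(round(specificity(pooled), 1), 80.0)
  expect_equal(round(as.numeric(mcc(pooled)), 2), 0.44)
})

test_that("metric edge cases: extremes and zero denominators", {
  expect_equal(as.numeric(mcc(confusion_matrix(10, 0, 10, 0))), 1)
  expect_equal(as.numeric(mcc(confusion_matrix(0, 10, 0, 10))), -1)
  expect_equal(sensitivity(confusion_matrix(0, 0, 5, 5)), 0)

  no_pos <- confusion_matrix(tp = 0, fp = 2, tn = 3, fn = 0)
  expect_true(is.na(sensitivity(no_pos)))
  expect_false(is.na(specificity(no_pos)))

  # constant predictions: MCC degenerate, conventional 0 with flag
  all_dam <- confusion_matrix(tp = 5, fp = 3, tn = 0, fn = 0)
  expect_equal(as.numeric(mcc(all_dam)), 0)
  expect_true(attr(mcc(all_dam), "degenerate"))
})

test_that("mcc equals the Pearson correlation of the binary vectors", {
  set.seed(7)
  for (rep in 1:500) {
    counts <- as.integer(rmultinom(1, sample(4:40, 1), runif(4, 0.05, 1)))
    cm <- confusion_matrix(tp = counts[1], fp = counts[2],
                           tn = counts[3], fn = counts[4])
    pred <- rep(c(1, 1, 0, 0), counts)
    truth <- rep(c(1, 0, 0, 1), counts)
    r <- suppressWarnings(stats::cor(pred, truth))
    m <- as.numeric(mcc(cm))
    if (is.na(r)) {
      expect_true(isTRUE(attr(mcc(cm), "degenerate")))
    } else {
      expect_equal(m, r, tolerance = 1e-12)
    }
  }
})

test_that("mcc is invariant under swapping the two classes", {
  set.seed(8)
  for (rep in 1:50) {
    c4 <- sample(0:30, 4, TRUE)
    a <- confusion_matrix(c4[1], c4[2], c4[3], c4[4])
    b <- confusion_matrix(c4[3], c4[4], c4[1], c4[2])   # TP<->TN, FP<->FN
    expect_equal(as.numeric(mcc(a)), as.numeric(mcc(b)))
  }
})

test_that("accuracy is the count-exact blend of sensitivity and specificity", {
  set.seed(9)
  for (rep in 1:50) {
    c4 <- sample(1:30, 4, TRUE)
    cm <- confusion_matrix(c4[1], c4[2], c4[3], c4[4])
    n <- sum(unlist(cm))
    blended <- (sensitivity(cm) * (cm$tp + cm$fn) +
                specificity(cm) * (cm$tn + cm$fp)) / n
    expect_equal(accuracy(cm), blended)
  }
})
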