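test_that("confusion matrix counts true/predicted pairs", {
  perfect <- confusion(rep(0:4, each = 3), rep(0:4, each = 3))
  expect_equal(unclass(perfect), diag(3L, 5), ignore_attr = TRUE)
  swapped <- confusion(c(0L, 1L), c(1L, 0L), k = 2)
  expect_equal(as.integer(swapped), c(0L, 1L, 1L, 0L))
  expect_error(confusion(c(0, 5), c(0, 1)), "0..4")
  expect_error(confusion(0:1, 0L), "equal length")
  # row sums are the per-class test counts
  set.seed(1)
  yt <- rep(0:4, each = 40)
  cm <- confusion(yt, sample(yt))
  expect_equal(as.numeric(rowSums(cm)), rep(40, 5))
})

test_that("per-class metrics match a brute-force one-vs-rest tally", {
  cm <- confusion(c(0,0,0, 0,1,1,1, 2,2,2,2),
                  c(0,0,1, 2,1,1,1, 0,2,2,2), k = 3)
  rep_ <- per_class_metrics(cm)
  # independent tally: loop over classes, count TP/FP/FN/TN directly
  m <- unclass(cm)
  for (k in 1:3) {
    tp <- m[k, k]
    fp <- sum(m[-k, k])
    fn <- sum(m[k, -k])
    tn <- sum(m[-k, -k])
    p <- tp / (tp + fp); s <- tp / (tp + fn)
    expect_equal(rep_$per_class$precision[k], 100 * p)
    expect_equal(rep_$per_class$sensitivity[k], 100 * s)
    expect_equal(rep_$per_class$accuracy[k], 100 * s)  # table convention
    expect_equal(rep_$per_class$f1[k], 2 * p * s / (p + s))
    expect_equal(rep_$per_class$ovr_accuracy[k], 100 * (tp + tn) / sum(m))
  }
  expect_equal(rep_$overall_accuracy_global, 100 * sum(diag(m)) / sum(m))
})

test_that("perfect and degenerate matrices give the expected extremes", {
  cm <- confusion(rep(0:4, each = 2), rep(0:4, each = 2))
  rep_ <- per_class_metrics(cm)
  expect_equal(rep_$per_class$precision, rep(100, 5))
  expect_equal(rep_$per_class$f1, rep(1, 5))
  expect_equal(rep_$overall$accuracy, 100)
  # an empty predicted class triggers the zero-division warning path,
  # once for the precision and once for the F1
  w <- capture_warnings(
    rep0 <- per_class_metrics(confusion(c(0L, 1L), c(0L, 0L), k = 2)))
  expect_match(w, "zero denominator|F1 undefined", all = TRUE)
  expect_equal(rep0$per_class$precision[2], 0)
  expect_equal(rep0$per_class$f1[2], 0)
})

test_that("F1 is the harmonic mean of the published precision/sensitivity pair", {
  p <- 0.9744; s <- 0.95
  expect_equal(round(2 * p * s / (p + s), 4), 0.9620)
})

test_that("macro overall row averages the per-class values", {
  f1s <- c(0.9024, 0.9620, 0.9487, 0.9157, 0.9487)
  precs <- c(88.10, 97.44, 97.37, 88.37, 97.37)
  df <- data.frame(class = letters[1:5], accuracy = precs, precision = precs,
                   sensitivity = precs, f1 = f1s)
  ov <- macro_overall(df)
  expect_equal(ov$f1, 0.9355)
  expect_equal(ov$precision, 93.73)
  # single-class degenerate case: overall equals that class's values
  ov1 <- macro_overall(df[2, ])
  expect_equal(ov1$f1, 0.9620)
})

test_that("permuting the class order permutes rows but fixes the overall row", {
  set.seed(2)
  yt <- sample(0:4, 300, replace = TRUE)
  yp <- ifelse(runif(300) < 0.7, yt, sample(0:4, 300, replace = TRUE))
  perm <- c(3L, 0L, 4L, 2L, 1L)
  r1 <- per_class_metrics(confusion(yt, yp))
  r2 <- per_class_metrics(confusion(perm[yt + 1], perm[yp + 1]))
  expect_equal(r2$overall, r1$overall)
  # new class j carries the metrics of the old class mapped onto it
  expect_equal(r2$per_class$f1, r1$per_class$f1[match(0:4, perm)])
})

test_that("every published overall row re-derives from its per-class rows", {
  ref <- reference_tables()
  for (mod in unique(ref$model)) {
    block <- ref[ref$model == mod, ]
    all_row <- block[block$class == "All", ]
    pc <- block[block$class != "All", ]
    ov <- macro_overall(pc)
    expect_equal(ov$accuracy, all_row$accuracy, tolerance = 0.011)
    expect_equal(ov$precision, all_row$precision, tolerance = 0.011)
    expect_equal(ov$sensitivity, all_row$sensitivity, tolerance = 0.011)
    expect_equal(ov$f1, all_row$f1, tolerance = 0.00015)
    # harmonic-mean identity holds for every per-class row
    p <- pc$precision / 100; s <- pc$sensitivity / 100
    expect_equal(pc$f1, 2 * p * s / (p + s), tolerance = 2e-4)
  }
})

test_that("metrics CSV writer reproduces the results-table shape", {
  set.seed(3)
  yt <- rep(0:4, each = 8)
  yp <- ifelse(runif(40) < 0.8, yt, sample(0:4, 40, replace = TRUE))
  rep_ <- per_class_metrics(confusion(yt, yp))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(list(`nm-thba-elm` = rep_), path)
  out <- read.csv(path)
  expect_identical(names(out),
                   c("Model", "Class", "Accuracy", "Precision", "Sensitivity",
                     "F1"))
  expect_identical(out$Class, c("All", pesticide_classes))
  expect_equal(out$F1[1], round(rep_$overall$f1, 4))
})
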