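make_planted <- function(n_per_class = 50, p = 10, effect = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n_per_class)
  x <- matrix(rnorm(2 * n_per_class * p), ncol = p)
  x[, 1] <- x[, 1] + effect * y
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}

test_that("stratified split preserves class proportions and is exact", {
  recs <- data.frame(id = 1:200, label = rep(c("positive", "negative"), 100))
  sp <- stratified_split(recs, 0.8, seed = 1)
  expect_equal(nrow(sp$train), 160)
  expect_equal(nrow(sp$validation), 40)
  expect_equal(sum(sp$train$label == "positive"), 80)
  expect_equal(sum(sp$validation$label == "positive"), 20)
  expect_length(intersect(sp$train$id, sp$validation$id), 0)
  expect_setequal(c(sp$train$id, sp$validation$id), recs$id)

  # same seed twice -> identical partition
  sp2 <- stratified_split(recs, 0.8, seed = 1)
  expect_identical(sp$train$id, sp2$train$id)

  # floor rounding at the real dataset sizes
  big <- data.frame(id = 1:2959,
                    label = rep(c("positive", "negative"), c(269, 2690)))
  spb <- stratified_split(big, 0.8, seed = 1)
  expect_equal(sum(spb$train$label == "positive"), 215)
  expect_equal(sum(spb$train$label == "negative"), 2152)

  tiny <- data.frame(id = 1:8, label = rep(c("positive", "negative"), 4))
  expect_error(stratified_split(tiny), ">= 5")
})

test_that("5-fold CV partitions each class evenly and exhaustively", {
  y <- rep(c(0L, 1L), c(23, 37))
  f <- b3ppkit:::fold_ids(y, 5, seed = 2)
  expect_setequal(unique(f), 1:5)
  for (cl in 0:1) {
    sizes <- table(f[y == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  # every peptide in exactly one fold
  expect_length(f, length(y))
  # pure function of seed
  expect_identical(f, b3ppkit:::fold_ids(y, 5, seed = 2))
})

test_that("CV on separable data reaches perfect accuracy and AUROC", {
  d <- make_planted(n_per_class = 30, effect = 8)
  cv <- five_fold_cv(d$x, d$y, model = "rf", seed = 1)
  expect_equal(unname(cv$mean_internal["Acc"]), 100)
  expect_equal(unname(cv$mean_internal["AUROC"]), 1.0)
  expect_equal(unname(colMeans(cv$per_fold[, -1])["Acc"]),
               unname(cv$mean_internal["Acc"]))
})

test_that("all seven classifier families emit probabilities in [0,1]", {
  d <- make_planted(n_per_class = 30, effect = 2)
  probe <- make_planted(n_per_class = 10, effect = 2, seed = 99)$x
  for (mod in c("rf", "dt", "lr", "knn", "gnb", "xgb", "svc")) {
    m <- train_classifier(d$x, d$y, mod, seed = 1)
    s1 <- predict(m, probe)
    expect_length(s1, nrow(probe))
    expect_true(all(s1 >= 0 & s1 <= 1), info = mod)
    # determinism given the seed
    m2 <- train_classifier(d$x, d$y, mod, seed = 1)
    expect_equal(s1, predict(m2, probe), info = mod)
  }
  # RF memorizes separable training data
  m <- train_classifier(d$x, d$y, "rf", seed = 1)
  acc <- mean((predict(m, d$x) >= 0.5) == d$y)
  expect_equal(acc, 1)
  expect_error(train_classifier(d$x, sample(3, nrow(d$x), TRUE), "rf"))
})

test_that("confusion metrics follow their closed forms", {
  perfect <- compute_metrics(tp = 10, fp = 0, tn = 10, fn = 0)
  expect_equal(unname(perfect), c(100, 100, 100, 1))

  hand <- compute_metrics(tp = 3, fp = 2, tn = 2, fn = 1)
  expect_equal(unname(hand["Sens"]), 75)
  expect_equal(unname(hand["Spec"]), 50)
  expect_equal(unname(hand["Acc"]), 62.5)
  expect_equal(unname(hand["MCC"]),
               (3 * 2 - 2 * 1) / sqrt(5 * 4 * 4 * 3), tolerance = 1e-12)

  # every prediction wrong: perfect anticorrelation, MCC = -1
  degenerate <- compute_metrics(tp = 0, fp = 10, tn = 0, fn = 10)
  expect_equal(unname(degenerate), c(0, 0, 0, -1))
  # a truly degenerate table (an undefined MCC denominator) maps to 0
  onesided <- compute_metrics(tp = 5, fp = 5, tn = 0, fn = 0)
  expect_equal(unname(onesided["MCC"]), 0)
  expect_error(compute_metrics(0, 0, 0, 0), "no evaluated")
})

test_that("metrics satisfy their identities on random confusion tables", {
  set.seed(13)
  for (i in 1:200) {
    cts <- as.list(sample(0:40, 4, TRUE))
    names(cts) <- c("TP", "FP", "TN", "FN")
    if (sum(unlist(cts)) == 0) next
    m <- compute_metrics(cts)
    P <- cts$TP + cts$FN
    N <- cts$TN + cts$FP
    if (P > 0 && N > 0) {
      expect_equal(unname(m["Acc"]),
                   unname((m["Sens"] * P + m["Spec"] * N) / (P + N)),
                   tolerance = 1e-9)
    }
    expect_gte(m["MCC"], -1)
    expect_lte(m["MCC"], 1)
    if (cts$FP == 0 && cts$FN == 0 && cts$TP > 0 && cts$TN > 0) {
      expect_equal(unname(m["MCC"]), 1)
    }
  }
})

test_that("AUROC handles perfect, reversed, tied and random scores", {
  y <- rep(c(0, 1), each = 20)
  expect_equal(auroc(y, y), 1.0)
  expect_equal(auroc(1 - y, y), 0.0)
  expect_equal(auroc(rep(0.3, 40), y), 0.5)

  # invariant under strictly monotone transforms
  set.seed(14)
  s <- runif(40)
  expect_equal(auroc(s, y), auroc(qlogis(s), y))
  expect_equal(auroc(s, y), auroc(s^3, y))

  # agreement with an independent ROC implementation
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))

  # Mann-Whitney null
  nulls <- vapply(1:10, function(i) {
    set.seed(500 + i)
    auroc(runif(2000), rep(c(0, 1), 1000))
  }, numeric(1))
  expect_true(all(abs(nulls - 0.5) < 0.05))

  expect_error(auroc(s, rep(1, 40)), "both classes")
})

test_that("evaluate_pipeline separates planted signal and not noise", {
  d <- make_planted(n_per_class = 100, effect = 6)
  rep1 <- evaluate_pipeline(d$x, d$y, model = "rf", seed = 1)
  expect_gte(unname(rep1$mean_internal["AUROC"]), 0.95)
  expect_gte(unname(rep1$external["AUROC"]), 0.95)
  expect_equal(unname(rep1$mean_internal),
               unname(colMeans(rep1$per_fold[, -1])))

  # permutation null with a fast learner
  nulls <- vapply(1:10, function(s) {
    yp <- b3ppkit:::with_seed(700 + s, sample(d$y))
    r <- evaluate_pipeline(d$x, yp, model = "lr", seed = s)
    unname(r$external["AUROC"])
  }, numeric(1))
  expect_true(all(nulls >= 0.25 & nulls <= 0.75))
  expect_lt(abs(mean(nulls) - 0.5), 0.1)
})

test_that("bundles survive a save/load round trip", {
  b <- small_bundle()
  path <- tempfile(fileext = ".rds")
  bundle_save(b, path)
  b2 <- bundle_load(path)
  probe <- peptide_set("q", "RRYYGGKKRRYY")
  expect_identical(predict(b, probe)$score, predict(b2, probe)$score)
})
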