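test_that("physicochemical features are pinned and deterministic", {
  f <- extract_features("AAAA")
  expect_equal(unname(f["comp_A"]), 1)
  expect_equal(unname(f["cysteine_fraction"]), 0)
  expect_lt(abs(f[["net_charge_pH7"]]), 0.01)      # termini nearly cancel
  expect_gt(extract_features("KKKK")[["net_charge_pH7"]],
            extract_features("DDDD")[["net_charge_pH7"]])
  all20 <- "ACDEFGHIKLMNPQRSTVWY"
  f20 <- extract_features(all20)
  expect_true(all(abs(f20[paste0("comp_", strsplit(all20, "")[[1]])] - 0.05) < 1e-12))
  # hand-sum from the pinned mass table: 20 residues minus 19 waters
  expect_equal(f20[["molecular_weight"]],
               sum(ampevo:::AA_MASS) - 19 * ampevo:::WATER_MASS)
  expect_error(extract_features("ACDB"), "non-standard")
  # net charge at the reported pI is ~0
  counts <- table(factor(strsplit("ACKRDEH", "")[[1]], levels = ampevo:::AA20))
  expect_lt(abs(ampevo:::net_charge_at_ph(setNames(as.numeric(counts), ampevo:::AA20),
                                          extract_features("ACKRDEH")[["isoelectric_point"]])),
            1e-6)
})

test_that("length matching reproduces attainable histograms and reduces KS distance", {
  # pool with identical length multiset: exact match
  pos <- c(12, 20, 20, 35, 50)
  pool <- c(50, 20, 12, 35, 20, 100, 150)
  idx <- match_length_distribution(pos, pool, seed = 1)
  expect_equal(sort(pool[idx]), sort(pos))
  # concentrated positives land in the right bin
  pos30 <- rep(30, 40)
  set.seed(2); pool2 <- sample(10:200, 400, replace = TRUE)
  idx2 <- match_length_distribution(pos30, pool2, seed = 3)
  expect_length(idx2, 40)
  expect_true(all(pool2[idx2] == 30 | sum(pool2 == 30) < 40))
  # KS improvement over the raw pool on a random instance
  set.seed(4)
  posr <- round(rnorm(100, 40, 8)); posr <- pmax(posr, 10)
  poolr <- sample(10:200, 1000, replace = TRUE)
  idx3 <- match_length_distribution(posr, poolr, seed = 5)
  ks <- function(a, b) suppressWarnings(stats::ks.test(a, b)$statistic)
  expect_lte(ks(poolr[idx3], posr), ks(poolr, posr))
  expect_error(match_length_distribution(posr, numeric(0)), "empty")
})

test_that("classifier training is deterministic and separates separable data", {
  set.seed(1)
  X <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 4), 50))
  colnames(X) <- c("f1", "f2")
  y <- rep(c(FALSE, TRUE), each = 50)
  m <- train_amp_classifier(X, y)
  pr <- predict(m, X, threshold = 0.5)
  expect_equal(mean(pr$call == y), 1)   # 100% training accuracy, separable
  m2 <- train_amp_classifier(X, y)
  expect_identical(predict(m, X)$probability, predict(m2, X)$probability)
  expect_error(train_amp_classifier(X, rep(TRUE, 100)), "both classes")
  # non-separable case agrees with unpenalised glm to first decimals
  set.seed(2)
  Xo <- matrix(rnorm(400), 200); colnames(Xo) <- c("a", "b")
  yo <- rbinom(200, 1, ampevo:::sigmoid(Xo[, 1]))
  mo <- train_amp_classifier(Xo, yo, lambda = 1e-6)
  go <- glm(yo ~ scale(Xo), family = binomial)
  expect_equal(unname(coef(mo)), unname(coef(go)), tolerance = 1e-3)
})

test_that("probability calls are strictly greater-than the threshold", {
  # intercept-only models with exactly known probabilities
  mk <- function(p) structure(list(coefficients = c("(Intercept)" = qlogis(p), f = 0),
                                   center = c(f = 0), scale = c(f = 1),
                                   features = "f", lambda = 0),
                              class = "amp_classifier")
  X <- matrix(0, 1, 1, dimnames = list(NULL, "f"))
  expect_false(predict(mk(0.69), X, threshold = 0.70)$call)
  expect_false(predict(mk(0.70), X, threshold = 0.70)$call)   # strict >
  expect_true(predict(mk(0.71), X, threshold = 0.70)$call)
  expect_error(predict(mk(0.5), X, threshold = 1), "threshold")
})

test_that("classifier JSON round-trip preserves predictions", {
  set.seed(3)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- X[, 1] + X[, 2] > 0
  m <- train_amp_classifier(X, y)
  m2 <- amp_classifier_from_list(amp_classifier_to_list(m))
  expect_equal(predict(m, X)$probability, predict(m2, X)$probability)
})

test_that("confusion metrics satisfy their defining identities", {
  perfect <- confusion_metrics(tp = 50, tn = 50, fp = 0, fn = 0)
  expect_equal(unname(perfect[c("sensitivity", "specificity", "ppv", "npv",
                                "f1", "balanced_accuracy")]), rep(100, 6))
  expect_equal(unname(perfect[c("prevalence", "detection_rate",
                                "detection_prevalence")]), rep(50, 6)[1:3])
  hand <- confusion_metrics(tp = 3, fp = 1, fn = 1, tn = 5)
  expect_equal(unname(round(hand[c("sensitivity", "specificity", "precision",
                                   "f1", "balanced_accuracy")], 2)),
               c(75, 83.33, 75, 75, 79.17))
  expect_warning(und <- confusion_metrics(tp = 0, fp = 0, fn = 2, tn = 3),
                 "undefined")
  expect_true(is.nan(und[["ppv"]]))
  # invariants over random tables
  set.seed(7)
  for (i in 1:50) {
    cnt <- rmultinom(1, 200, runif(4, 0.05, 1))
    m <- confusion_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_lte(m[["detection_rate"]], m[["detection_prevalence"]] + 1e-12)
    expect_lte(m[["detection_rate"]], m[["prevalence"]] + 1e-12)
    expect_gte(m[["f1"]], min(m[["precision"]], m[["recall"]]) - 1e-9)
    expect_lte(m[["f1"]], max(m[["precision"]], m[["recall"]]) + 1e-9)
    expect_equal(m[["balanced_accuracy"]],
                 (m[["sensitivity"]] + m[["specificity"]]) / 2)
  }
})
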