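test_that("batch model coefficients are the per-batch QC means, grand mean unweighted", {
  qc <- matrix(c(10, 10, 12, 12), 4, 1, dimnames = list(NULL, "L1"))
  m <- fit_batch_model(qc, c("A", "A", "B", "B"))
  expect_equal(unname(m$batch_means[, "L1"]), c(10, 12))
  expect_equal(unname(m$grand_mean["L1"]), 11)

  corr <- apply_batch_correction(matrix(20, 1, 1, dimnames = list(NULL, "L1")),
                                 m, "B")
  expect_equal(unname(corr[1, 1]), 19)   # 20 - 12 + 11
})

test_that("categorical OLS identity: batch means equal lm coefficients", {
  set.seed(21)
  y <- matrix(rnorm(60, 100, 10), 60, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  batches <- rep(c("B1", "B2", "B3"), each = 20)
  m <- fit_batch_model(y, batches)
  for (j in 1:3) {
    fit <- lm(y[, j] ~ 0 + factor(batches))
    expect_equal(unname(m$batch_means[, j]), unname(coef(fit)),
                 tolerance = 1e-10)
  }
})

test_that("correction fixes QC batch means at the grand mean and is idempotent", {
  set.seed(22)
  sim <- simulate_cohort(small_config(seed = 22, batch_offset_sd = 0.15))
  qp <- run_quant_correct(sim)
  man <- qp$manifest
  qcid <- man$injection_id[man$role == "QC"]
  qcb <- man$batch[man$role == "QC"]

  post <- qp$corrected[qcid, , drop = FALSE]
  for (b in unique(qcb)) {
    bm <- colMeans(post[qcb == b, , drop = FALSE])
    expect_equal(bm, qp$model$grand_mean, tolerance = 1e-10)
  }
  # overall QC mean per lipid is preserved by the recentering
  pre_qc <- qp$conc[qcid, , drop = FALSE]
  expect_equal(colMeans(post), colMeans(pre_qc), tolerance = 1e-8)

  # idempotence: fit + apply on already-corrected data changes nothing
  m2 <- fit_batch_model(post, qcb)
  nb <- man$injection_id[man$role != "blank"]
  twice <- apply_batch_correction(qp$corrected, m2, man$batch[man$role != "blank"])
  expect_equal(unclass(twice), unclass(qp$corrected), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("single batch is a warned no-op and unknown labels error", {
  qc <- matrix(rnorm(10, 50), 5, 2, dimnames = list(NULL, c("x", "y")))
  expect_warning(m <- fit_batch_model(qc, rep("only", 5)), "no-op")
  corr <- apply_batch_correction(qc, m, rep("only", 5))
  expect_equal(corr, qc, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(apply_batch_correction(qc, m, rep("other", 5)), "other")
})

test_that("all-missing batches are imputed at the grand mean with a flag", {
  qc <- matrix(c(10, 10, NA, NA, 14, 14), 6, 1, dimnames = list(NULL, "L"))
  m <- fit_batch_model(qc, rep(c("A", "B", "C"), each = 2))
  expect_true(m$imputed["B", "L"])
  expect_equal(unname(m$batch_means["B", "L"]), 12)  # grand mean of A, C
  # a single QC value is not enough for a batch mean
  qc2 <- matrix(c(10, 10, 99, 14, 14), 5, 1, dimnames = list(NULL, "L"))
  m2 <- fit_batch_model(qc2, c("A", "A", "B", "C", "C"))
  expect_true(m2$imputed["B", "L"])
})

test_that("log2-scale correction removes multiplicative offsets exactly on QCs", {
  set.seed(23)
  level <- rep(100, 6)
  fold <- rep(c(1, 2, 0.5), each = 2)
  qc <- matrix(level * fold, 6, 1, dimnames = list(NULL, "L"))
  batches <- rep(c("A", "B", "C"), each = 2)
  m <- fit_batch_model(qc, batches, scale = "log2")
  corr <- apply_batch_correction(qc, m, batches)
  expect_equal(unname(corr[, 1]), rep(100, 6), tolerance = 1e-10)
})

test_that("CV computation matches closed forms and flags undefined cases", {
  expect_equal(as.numeric(qc_cv(matrix(c(10, 10, 10), 3, 1,
                                       dimnames = list(NULL, "L")))), 0)
  cv2 <- qc_cv(matrix(c(9, 11), 2, 1, dimnames = list(NULL, "L")))
  expect_equal(as.numeric(cv2), 100 * sqrt(2) / 10, tolerance = 1e-10)  # 14.14%

  # lognormal closed form: theoretical CV 20%
  set.seed(24)
  sdlog <- sqrt(log(1 + 0.2^2))
  x <- matrix(rlnorm(1000, 5, sdlog), 1000, 1, dimnames = list(NULL, "L"))
  expect_lt(abs(as.numeric(qc_cv(x)) - 20), 2)

  neg <- matrix(c(-5, 1, 2), 3, 1, dimnames = list(NULL, "L"))
  expect_true(is.na(as.numeric(qc_cv(neg))))
  expect_equal(attr(qc_cv(neg), "undefined"), "L")

  pb <- qc_cv(matrix(1:8, 4, 2, dimnames = list(NULL, c("a", "b"))),
              grouping = "per_batch", batches = c("A", "A", "B", "B"))
  expect_equal(dim(pb), c(2, 2))
})

test_that("retention filter applies the threshold with study-sample rescue", {
  cv <- c(l1 = 10, l2 = 25, l3 = 35)
  r <- retention_filter(cv, threshold = 30)
  expect_equal(r$retained, c(TRUE, TRUE, FALSE))
  expect_equal(r$reason[3], "cv_above_threshold")

  # high QC CV but robust in study samples: kept with rescue flag
  r2 <- retention_filter(c(ps = 45), threshold = 30,
                         study_detection_rate = c(ps = 0.99))
  expect_true(r2$retained)
  expect_true(r2$rescue_flag)
  expect_equal(r2$reason, "rescued_robust_in_study")

  # undefined CV (below detection in reference plasma) can still be rescued
  r3 <- retention_filter(c(ps = NA), study_detection_rate = c(ps = 0.95))
  expect_true(r3$retained)

  # degenerate threshold keeps nothing without rescue
  r4 <- retention_filter(cv, threshold = 0)
  expect_false(any(r4$retained))
})

test_that("with zero injected offsets the correction only moves values by QC noise", {
  cfg <- small_config(seed = 25, batch_offset_sd = 0)
  sim <- simulate_cohort(cfg)
  qp <- run_quant_correct(sim)
  nb <- qp$manifest$injection_id[qp$manifest$role != "blank"]
  shift <- abs(unclass(qp$corrected) - unclass(qp$conc)[nb, ])
  # the shift per lipid is |batch mean - grand mean|, bounded by a few SEs
  # of the batch means (analytical CV up to 25%, >= 3 QCs per batch)
  qcid <- qp$manifest$injection_id[qp$manifest$role == "QC"]
  qc_sd <- apply(unclass(qp$conc)[qcid, , drop = FALSE], 2, sd)
  max_shift <- apply(shift, 2, max)
  expect_true(all(max_shift < 6 * qc_sd / sqrt(3)))
})

test_that("run-order terms are not supported on drift-free QC data", {
  set.seed(26)
  qc <- matrix(rnorm(26 * 10, 100, 5), 26, 10,
               dimnames = list(NULL, paste0("L", 1:10)))
  batches <- rep(c("A", "B"), each = 13)
  ord <- c(1:13, 1:13)
  chk <- run_order_check(qc, batches, ord)
  expect_lt(chk$fraction_significant, 0.3)
  expect_equal(length(chk$p_values), 10)
})
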