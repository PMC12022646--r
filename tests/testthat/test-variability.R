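make_manifest <- function(n_part, n_tp, sexes = rep(c("F", "M"), length.out = n_part)) {
  ids <- sprintf("P%02d", seq_len(n_part))
  data.frame(injection_id = sprintf("I%03d", seq_len(n_part * n_tp)),
             participant_id = rep(ids, each = n_tp),
             timepoint = rep(seq_len(n_tp), n_part),
             sex = rep(sexes, each = n_tp),
             age = 52.7, batch = 1, well = "A1",
             order = seq_len(n_part * n_tp), role = "study",
             stringsAsFactors = FALSE)
}

test_that("subject CVs separate degenerate within/between structure", {
  man <- make_manifest(4, 3)
  # constant over time, participants differ
  X <- matrix(rep(c(10, 20, 30, 40), each = 3), 12, 1,
              dimnames = list(man$injection_id, "L"))
  cvs <- subject_cvs(X, man)
  expect_equal(cvs$within_cv, 0)
  expect_gt(cvs$between_cv, 0)

  # all values identical
  X2 <- matrix(10, 12, 1, dimnames = list(man$injection_id, "L"))
  cvs2 <- subject_cvs(X2, man)
  expect_equal(cvs2$within_cv, 0)
  expect_equal(cvs2$between_cv, 0)
})

test_that("subject CVs match a plain-loop oracle on random data", {
  set.seed(31)
  man <- make_manifest(8, 3)
  X <- matrix(rlnorm(24 * 4, 3, 0.4), 24, 4,
              dimnames = list(man$injection_id, paste0("L", 1:4)))
  X[2, 2] <- NA
  cvs <- subject_cvs(X, man)
  for (j in 1:4) {
    per <- sapply(unique(man$participant_id), function(p) {
      v <- X[man$injection_id[man$participant_id == p], j]
      v <- v[!is.na(v)]
      if (length(v) < 2) return(c(NA, NA))
      c(100 * sd(v) / mean(v), mean(v))
    })
    expect_equal(cvs$within_cv[j], mean(per[1, ], na.rm = TRUE),
                 tolerance = 1e-10)
    pm <- sapply(unique(man$participant_id), function(p) {
      v <- X[man$injection_id[man$participant_id == p], j]
      mean(v[!is.na(v)])
    })
    expect_equal(cvs$between_cv[j], 100 * sd(pm) / mean(pm), tolerance = 1e-10)
  }
})

test_that("equal variance components give the predicted within/between CV relation", {
  # with sigma_b = sigma_w on the log scale, between CVs (participant means
  # of T points) exceed within CVs by about sqrt(1 + 1/T), inflated further
  # by the small-sample bias of the per-participant SD
  set.seed(32)
  ratios <- replicate(10, {
    man <- make_manifest(150, 3)
    s <- 0.2
    b <- rnorm(150, 0, s)
    y <- 2^(5 + rep(b, each = 3) + rnorm(450, 0, s))
    X <- matrix(y, 450, 1, dimnames = list(man$injection_id, "L"))
    cvs <- subject_cvs(X, man)
    cvs$between_cv / cvs$within_cv
  })
  c4 <- sqrt(2 / 2) * gamma(3 / 2) / gamma(1)   # E[s]/sigma at n = 3
  expected <- sqrt(1 + 1 / 3) / c4
  expect_lt(abs(mean(ratios) - expected), 0.25)
})

test_that("ICC hits its limits and matches the ANOVA moment estimator", {
  set.seed(33)
  man <- make_manifest(50, 3)
  s_b <- 0.3
  icc_true <- 0.5
  b <- rnorm(50, 0, s_b)
  y <- 2^(8 + rep(b, each = 3) + rnorm(150, 0, s_b))  # equal components
  X <- cbind(L1 = y, L2 = 2^(6 + rep(b, each = 3) + rnorm(150, 0, 0.01)))
  rownames(X) <- man$injection_id
  res <- icc(X, man)

  # near-noiseless lipid: ICC -> 1
  expect_gt(res$icc[2], 0.95)

  # balanced one-way ANOVA moment estimator agrees within 0.02
  for (j in 1:2) {
    yt <- log2(X[, j] + 1)
    gm <- tapply(yt, man$participant_id, mean)
    msb <- 3 * var(gm)
    msw <- mean(tapply(yt, man$participant_id, var))
    sb <- max((msb - msw) / 3, 0)
    expect_lt(abs(res$icc[j] - sb / (sb + msw)), 0.02)
  }

  # permuted participant labels destroy the structure: ICC ~ 0
  man_perm <- man
  man_perm$participant_id <- sample(man$participant_id)
  res_perm <- icc(X, man_perm)
  expect_lt(res_perm$icc[1], 0.1)

  # estimability floor
  expect_error(icc(X[1:6, , drop = FALSE], man[1:6, ]), "participants")
})

test_that("individuality distances behave in degenerate and null cases", {
  man <- make_manifest(10, 3)
  set.seed(34)
  profile <- matrix(rnorm(10 * 6), 10, 6)
  X <- profile[rep(1:10, each = 3), ]  # identical triplets, no noise
  dimnames(X) <- list(man$injection_id, paste0("L", 1:6))
  d <- suppressWarnings(individuality_distances(X, man, 10, seed = 1))
  expect_equal(d$within_mean, 0, tolerance = 1e-12)
  expect_gt(d$between_mean, 0)

  # pure i.i.d. noise: within ~ between, comfortably non-significant
  X2 <- matrix(rnorm(30 * 20), 30, 20,
               dimnames = list(man$injection_id, paste0("L", 1:20)))
  d2 <- individuality_distances(X2, man, 10, seed = 1)
  expect_gt(d2$p, 0.001)
  expect_lt(abs(d2$within_mean / d2$between_mean - 1), 0.2)
})

test_that("distance summary is invariant to column order and global scaling", {
  set.seed(35)
  man <- make_manifest(8, 3)
  X <- matrix(rnorm(24 * 12, 10), 24, 12,
              dimnames = list(man$injection_id, paste0("L", 1:12)))
  d0 <- individuality_distances(X, man, 8, seed = 7)
  d1 <- individuality_distances(X[, sample(12)], man, 8, seed = 7)
  d2 <- individuality_distances(X * 1000, man, 8, seed = 7)
  expect_equal(d1$within_mean, d0$within_mean, tolerance = 1e-9)
  expect_equal(d2$between_mean, d0$between_mean, tolerance = 1e-9)
  expect_equal(d1$p, d0$p, tolerance = 1e-9)

  # requesting more participants than available warns and degrades
  expect_warning(individuality_distances(X, man, 15, seed = 1),
                 "complete triplets")
})

test_that("dendrograms export as parseable Newick trees", {
  set.seed(36)
  man <- make_manifest(6, 3)
  X <- matrix(rnorm(18 * 8), 18, 8,
              dimnames = list(man$injection_id, paste0("L", 1:8)))
  d <- individuality_distances(X, man, 6, seed = 1)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(d, path)
  tree <- ape::read.tree(path)
  expect_equal(length(tree$tip.label), 18)
})

test_that("PCA matches an eigendecomposition oracle and handles rank-1 input", {
  set.seed(37)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("L", 1:6)))
  p <- pca_overview(X)
  S <- scale(X)
  eig <- eigen(crossprod(S) / (nrow(S) - 1))
  expect_equal(p$explained_variance, eig$values / sum(eig$values),
               tolerance = 1e-9)
  for (k in 1:3) {   # loadings match up to sign
    expect_equal(abs(p$loadings[, k]), abs(eig$vectors[, k]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }

  # rank-1 matrix: PC1 explains everything
  r1 <- outer(rnorm(20), c(1, 2, 3)) + 100
  colnames(r1) <- c("a", "b", "c")
  p1 <- pca_overview(r1)
  expect_equal(p1$explained_variance[1], 1, tolerance = 1e-9)

  # two well-separated groups split on PC1
  g <- rbind(matrix(rnorm(60, 0), 20, 3), matrix(rnorm(60, 8), 20, 3))
  colnames(g) <- c("a", "b", "c")
  pg <- pca_overview(g)
  expect_gt(abs(mean(pg$scores[1:20, 1]) - mean(pg$scores[21:40, 1])), 2)

  # constant columns dropped with a warning
  gc <- cbind(g, d = 5)
  expect_warning(pca_overview(gc), "constant")
})
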