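#' Within- and between-subject coefficients of variation
#'
#' For each lipid, the within-subject CV is the arithmetic mean (the
#' median is also reported) over participants of the CV across that
#' participant's time points (participants with fewer than two non-missing
#' values are excluded); the between-subject CV is the CV of the
#' participant means. Both on the concentration scale, in percent.
#'
#' @param mat matrix or [abundance_matrix()] with study injections in the
#'   rows (row names = injection ids).
#' @param manifest manifest data frame (see [randomize_plates()]).
#' @return data frame: `lipid`, `within_cv`, `within_cv_median`,
#'   `between_cv`, `n_participants_within`, `n_participants`. Lipids with
#'   no usable data keep their row with NAs (flagged downstream).
#' @export
subject_cvs <- function(mat, manifest) {
  values <- if (inherits(mat, "abundance_matrix")) unclass_matrix(mat) else mat
  study <- manifest[manifest$role == "study", ]
  keep <- intersect(study$injection_id, rownames(values))
  if (length(keep) < 4) stop("need >= 2 time points for >= 2 participants")
  X <- values[keep, , drop = FALSE]
  part <- study$participant_id[match(keep, study$injection_id)]
  ok <- !is.na(X)
  X0 <- ifelse(ok, X, 0)
  n <- rowsum(ok + 0, part)
  s1 <- rowsum(X0, part)
  s2 <- rowsum(X0^2, part)
  pm <- s1 / n
  pm[n < 1] <- NA
  pv <- (s2 - n * pm^2) / (n - 1)
  pv[n < 2] <- NA
  pv[pv < 0] <- 0   # numerical guard
  pcv <- 100 * sqrt(pv) / pm
  pcv[!is.finite(pcv) | pm <= 0] <- NA
  between <- apply(pm, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) <= 0) return(NA_real_)
    100 * sd(v) / mean(v)
  })
  data.frame(
    lipid = colnames(X),
    within_cv = suppressWarnings(apply(pcv, 2, mean, na.rm = TRUE)),
    within_cv_median = suppressWarnings(apply(pcv, 2, median, na.rm = TRUE)),
    between_cv = between,
    n_participants_within = apply(pcv, 2, function(v) sum(!is.na(v))),
    n_participants = apply(pm, 2, function(v) sum(!is.na(v))),
    row.names = NULL, stringsAsFactors = FALSE)
}

## Fit or refit a lmer template with a new response; returns list(fit, ok,
## message). Refitting reuses the factorized random-effect structure and is
## much faster than a fresh fit when the model frame is unchanged.
refit_or_fit <- function(template, y, formula, data) {
  res <- tryCatch({
    fit <- suppressMessages(if (is.null(template)) {
      data$.y <- y
      lmer(formula, data = data, REML = TRUE,
           control = lmerControl(calc.derivs = FALSE))
    } else {
      refit(template, newresp = y)
    })
    list(fit = fit, ok = TRUE, message = "")
  }, error = function(e) list(fit = NULL, ok = FALSE,
                              message = conditionMessage(e)))
  if (res$ok) {
    msgs <- unlist(res$fit@optinfo$conv$lme4$messages)
    if (length(msgs)) res$message <- paste(msgs, collapse = "; ")
  }
  res
}

#' Intraclass correlation per lipid
#'
#' Fits, per lipid, the mixed model `log2(conc + 1) ~ sex +
#' (1 | participant)` by REML and reports the intraclass correlation
#' ICC = sigma2_intercept / (sigma2_intercept + sigma2_residual), clipped
#' to `[0, 1]` — the fraction of total (sex-adjusted) variance explained
#' by stable between-participant differences. Non-convergence yields a
#' missing ICC with a diagnostic, never a silent zero.
#'
#' @param mat matrix or [abundance_matrix()] (typically batch-corrected
#'   concentrations) with study injections in the rows.
#' @param manifest manifest data frame.
#' @param min_participants estimability floor (default 10 participants
#'   with >= 2 observations).
#' @return data frame: `lipid`, `icc`, `sigma2_b`, `sigma2_w`,
#'   `n_participants`, `converged`, `message`.
#' @export
icc <- function(mat, manifest, min_participants = 10) {
  values <- if (inherits(mat, "abundance_matrix")) unclass_matrix(mat) else mat
  study <- manifest[manifest$role == "study", ]
  keep <- intersect(study$injection_id, rownames(values))
  X <- values[keep, , drop = FALSE]
  meta <- study[match(keep, study$injection_id), ]
  tab <- table(meta$participant_id)
  if (sum(tab >= 2) < min_participants) {
    stop(sprintf("need >= 2 observations for >= %d participants", min_participants))
  }
  data <- data.frame(participant = factor(meta$participant_id),
                     female = as.numeric(meta$sex == "F"))
  form <- .y ~ female + (1 | participant)
  template <- NULL
  out <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    y <- transform_response(X[, j])
    if (all(is.na(y)) || sd(y, na.rm = TRUE) == 0) {
      out[[j]] <- data.frame(icc = NA_real_, sigma2_b = NA_real_,
                             sigma2_w = NA_real_, converged = FALSE,
                             message = "constant or all-missing response")
      next
    }
    if (anyNA(y)) {
      sub <- data[!is.na(y), , drop = FALSE]
      sub$.y <- y[!is.na(y)]
      res <- tryCatch(
        list(fit = suppressMessages(
          lmer(form, data = sub, REML = TRUE,
               control = lmerControl(calc.derivs = FALSE))),
          ok = TRUE, message = ""),
        error = function(e) list(fit = NULL, ok = FALSE,
                                 message = conditionMessage(e)))
    } else {
      res <- refit_or_fit(template, y, form, data)
      if (res$ok && is.null(template)) template <- res$fit
    }
    if (!res$ok) {
      out[[j]] <- data.frame(icc = NA_real_, sigma2_b = NA_real_,
                             sigma2_w = NA_real_, converged = FALSE,
                             message = res$message)
      next
    }
    vc <- as.data.frame(VarCorr(res$fit))
    s2b <- vc$vcov[vc$grp == "participant"][1]
    s2w <- vc$vcov[vc$grp == "Residual"][1]
    out[[j]] <- data.frame(
      icc = min(max(s2b / (s2b + s2w), 0), 1),
      sigma2_b = s2b, sigma2_w = s2w,
      converged = !nzchar(res$message), message = res$message)
  }
  res <- do.call(rbind, out)
  data.frame(lipid = colnames(X), res,
             n_participants = length(tab), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Distance-based individuality analysis
#'
#' Randomly samples participants with complete time-point triplets,
#' mean-centres and unit-variance scales each lipid, and compares the mean
#' pairwise distance between a participant's own repeated samples with the
#' distance between samples of different participants. The test contrasts
#' the per-participant mean within-distance against the pooled
#' between-participant distances with a two-sided Welch t-test (one
#' within-value per participant, avoiding pseudo-replication on the within
#' side). Hierarchical clustering (average linkage by default) of the same
#' distance matrix is returned as a tree.
#'
#' @param mat matrix or [abundance_matrix()] with study injections in rows.
#' @param manifest manifest data frame.
#' @param n_sampled_participants number of participants to sample
#'   (default 20; fewer are used, with a warning, if fewer have complete
#'   triplets).
#' @param seed optional RNG seed for the participant sample.
#' @param metric distance metric for [stats::dist()] (default Euclidean).
#' @param linkage linkage for [stats::hclust()] (default `"average"`).
#' @return object of class `distance_summary`: `within_mean`,
#'   `between_mean`, `t`, `df`, `p`, `per_participant_within`,
#'   `participants`, `hclust`, `phylo` (an `ape` tree for Newick export).
#' @export
individuality_distances <- function(mat, manifest,
                                    n_sampled_participants = 20,
                                    seed = NULL,
                                    metric = "euclidean",
                                    linkage = "average") {
  values <- if (inherits(mat, "abundance_matrix")) unclass_matrix(mat) else mat
  study <- manifest[manifest$role == "study", ]
  study <- study[study$injection_id %in% rownames(values), ]
  n_tp <- max(study$timepoint, na.rm = TRUE)
  tab <- table(study$participant_id)
  complete <- names(tab)[tab == n_tp]
  if (!length(complete)) stop("no participants with complete time-point sets")
  if (length(complete) < n_sampled_participants) {
    warning(sprintf("only %d participants with complete triplets (requested %d)",
                    length(complete), n_sampled_participants))
    n_sampled_participants <- length(complete)
  }
  if (!is.null(seed)) set.seed(seed)
  sampled <- sort(sample(complete, n_sampled_participants))
  rows <- study[study$participant_id %in% sampled, ]
  X <- values[rows$injection_id, , drop = FALSE]
  has_na <- apply(X, 2, anyNA)
  if (any(has_na)) {
    warning(sprintf("dropping %d lipid(s) with missing values", sum(has_na)))
    X <- X[, !has_na, drop = FALSE]
  }
  const <- apply(X, 2, sd) == 0
  if (any(const)) {
    warning(sprintf("dropping %d constant lipid column(s) before scaling",
                    sum(const)))
    X <- X[, !const, drop = FALSE]
  }
  Xs <- scale(X)   # mean-centred, UV-scaled
  d <- dist(Xs, method = metric)
  dm <- as.matrix(d)
  part <- rows$participant_id
  same <- outer(part, part, `==`)
  ut <- upper.tri(dm)
  within_d <- dm[ut & same]
  between_d <- dm[ut & !same]
  per_part <- vapply(sampled, function(p) {
    idx <- which(part == p)
    mean(dm[idx, idx][upper.tri(dm[idx, idx])])
  }, numeric(1))
  tt <- t.test(per_part, between_d, alternative = "two.sided")
  hc <- hclust(d, method = linkage)
  hc$labels <- sprintf("%s_T%d_%s", part, rows$timepoint, rows$sex)
  structure(list(within_mean = mean(within_d),
                 between_mean = mean(between_d),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 per_participant_within = per_part,
                 participants = sampled,
                 n_lipids = ncol(Xs),
                 hclust = hc, phylo = as.phylo(hc)),
            class = "distance_summary")
}

#' @exportS3Method base::print
print.distance_summary <- function(x, ...) {
  cat(sprintf("distance_summary: %d participants, %d lipids\n",
              length(x$participants), x$n_lipids))
  cat(sprintf("  mean within-participant distance : %.3f\n", x$within_mean))
  cat(sprintf("  mean between-participant distance: %.3f\n", x$between_mean))
  cat(sprintf("  Welch t = %.2f, df = %.1f, two-sided p = %.3g\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' Export the individuality dendrogram as Newick
#'
#' @param x a [individuality_distances()] result.
#' @param path output file.
#' @export
write_dendrogram <- function(x, path) {
  stopifnot(inherits(x, "distance_summary"))
  write.tree(x$phylo, file = path)
  invisible(path)
}

#' PCA overview of lipid profiles
#'
#' Principal component analysis on the mean-centred, unit-variance-scaled
#' matrix (rows with missing values and constant columns are dropped with
#' a warning).
#'
#' @param mat matrix or [abundance_matrix()].
#' @return list with `scores`, `loadings` and `explained_variance`
#'   (fractions, summing to <= 1 over the returned components).
#' @export
pca_overview <- function(mat) {
  values <- if (inherits(mat, "abundance_matrix")) unclass_matrix(mat) else mat
  cc <- complete.cases(values)
  if (!all(cc)) {
    warning(sprintf("dropping %d row(s) with missing values", sum(!cc)))
    values <- values[cc, , drop = FALSE]
  }
  if (nrow(values) <= 2) stop("need more rows than 2 components")
  const <- apply(values, 2, sd) == 0
  if (any(const)) {
    warning(sprintf("dropping %d constant column(s) before scaling", sum(const)))
    values <- values[, !const, drop = FALSE]
  }
  pr <- prcomp(scale(values), center = FALSE, scale. = FALSE)
  list(scores = pr$x, loadings = pr$rotation,
       explained_variance = pr$sdev^2 / sum(pr$sdev^2))
}
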