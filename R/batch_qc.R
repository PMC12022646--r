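#' Fit the QC-anchored batch model
#'
#' Estimates, per lipid, the batch-wise signal level from reference (QC)
#' injections only, via the linear model `lipid ~ batch` with batch as a
#' categorical factor — whose coefficients are identically the per-batch
#' QC means. The grand mean is the unweighted mean of the batch
#' estimates. Batches where a lipid is entirely missing get the grand
#' mean of the remaining batches imputed, with a flag.
#'
#' @param qc an [abundance_matrix()] (state `concentration` or
#'   `isotope_corrected`; a bare matrix is accepted) holding QC rows only.
#' @param batches batch label per QC row.
#' @param scale `"linear"` (model the reported concentrations, default and
#'   paper-faithful) or `"log2"` (multiplicative drift: model log2 values;
#'   non-positive values are dropped per cell).
#' @return object of class `batch_model`: list with `batch_means`
#'   (batches x lipids), `grand_mean` (per lipid), `scale`, `batches`,
#'   `imputed` (logical matrix of imputed cells), `n_qc` per batch.
#' @export
fit_batch_model <- function(qc, batches, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  values <- if (inherits(qc, "abundance_matrix")) unclass_matrix(qc) else qc
  if (!nrow(values)) stop("no QC rows supplied")
  if (length(batches) != nrow(values)) {
    stop("`batches` must have one label per QC row")
  }
  batches <- as.character(batches)
  levels <- unique(batches)
  if (length(levels) < 2) {
    warning("single batch: correction will be a no-op (identity model)")
  }
  if (scale == "log2") {
    values[values <= 0] <- NA
    values <- log2(values)
  }
  bm <- matrix(NA_real_, length(levels), ncol(values),
               dimnames = list(levels, colnames(values)))
  for (b in levels) {
    rows <- values[batches == b, , drop = FALSE]
    m <- colMeans(rows, na.rm = TRUE)
    m[colSums(!is.na(rows)) < 2] <- NA   # a batch mean needs >= 2 QCs
    bm[b, ] <- m
  }
  bm[is.nan(bm)] <- NA
  imputed <- is.na(bm)
  grand <- colMeans(bm, na.rm = TRUE)
  if (any(imputed)) {
    bm[imputed] <- matrix(grand, nrow(bm), ncol(bm), byrow = TRUE)[imputed]
  }
  structure(list(batch_means = bm, grand_mean = grand, scale = scale,
                 batches = levels, imputed = imputed,
                 n_qc = table(factor(batches, levels = levels))),
            class = "batch_model")
}

#' @exportS3Method base::print
print.batch_model <- function(x, ...) {
  cat(sprintf("batch_model: %d batches x %d lipids [%s scale]%s\n",
              length(x$batches), ncol(x$batch_means), x$scale,
              if (any(x$imputed)) sprintf(", %d imputed batch means",
                                          sum(x$imputed)) else ""))
  invisible(x)
}

#' Apply between-batch drift correction
#'
#' Subtracts each lipid's estimated batch mean from all samples (study and
#' QC alike) of that batch and recentres by adding the grand mean of the
#' batch estimates. After correction the per-lipid QC batch means are all
#' equal to the grand mean — the defining fixed point of the method — and
#' applying fit + apply a second time changes nothing. Negative corrected
#' concentrations are retained, not clipped (clipping would bias CVs), but
#' counted in the `n_negative` attribute.
#'
#' @param mat an [abundance_matrix()] in state `concentration` (or a bare
#'   matrix).
#' @param model a [fit_batch_model()] result.
#' @param batches batch label per row of `mat`.
#' @return corrected matrix; `abundance_matrix` input advances to state
#'   `batch_corrected`.
#' @export
apply_batch_correction <- function(mat, model, batches) {
  stopifnot(inherits(model, "batch_model"))
  is_am <- inherits(mat, "abundance_matrix")
  values <- if (is_am) unclass_matrix(mat) else mat
  batches <- as.character(batches)
  if (length(batches) != nrow(values)) {
    stop("`batches` must have one label per row")
  }
  unknown <- setdiff(unique(batches), model$batches)
  if (length(unknown)) {
    stop("batch label(s) without a model estimate: ",
         paste(unknown, collapse = ", "))
  }
  cols <- colnames(values)
  if (!all(cols %in% colnames(model$batch_means))) {
    stop("model does not cover all lipid columns")
  }
  bm <- model$batch_means[batches, cols, drop = FALSE]
  gm <- matrix(model$grand_mean[cols], nrow(values), length(cols), byrow = TRUE)
  if (model$scale == "log2") {
    lv <- values
    lv[lv <= 0] <- NA
    corrected <- 2^(log2(lv) - bm + gm)
    corrected[values == 0] <- 0   # true zeros stay zero
  } else {
    corrected <- values - bm + gm
  }
  n_negative <- sum(corrected < 0, na.rm = TRUE)
  if (is_am) {
    out <- advance_state(abundance_matrix(corrected, state = am_state(mat),
                                          units = am_units(mat),
                                          provenance = am_provenance(mat)),
                         "batch_corrected",
                         sprintf("apply_batch_correction(scale=%s)", model$scale))
  } else {
    out <- corrected
  }
  attr(out, "n_negative") <- n_negative
  out
}

#' Coefficient of variation of QC injections
#'
#' CV = 100 * sample SD / mean on the concentration scale, per lipid,
#' either over all supplied QC rows (`"overall"`, the between-batch
#' reproducibility when computed post-correction) or within each batch
#' (`"per_batch"`). Missing values are excluded pairwise; groups with
#' fewer than two non-missing values, or a non-positive mean, yield NA
#' (flagged via the `undefined` attribute).
#'
#' @param mat matrix or [abundance_matrix()] of QC rows.
#' @param grouping `"overall"` or `"per_batch"`.
#' @param batches batch labels (required for `"per_batch"`).
#' @return named CV vector (percent), or a batches x lipids matrix for
#'   `"per_batch"`.
#' @export
qc_cv <- function(mat, grouping = c("overall", "per_batch"), batches = NULL) {
  grouping <- match.arg(grouping)
  values <- if (inherits(mat, "abundance_matrix")) unclass_matrix(mat) else mat
  cv_one <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    m <- mean(v)
    if (m <= 0) return(NA_real_)
    100 * sd(v) / m
  }
  if (grouping == "overall") {
    out <- apply(values, 2, cv_one)
    attr(out, "undefined") <- names(out)[is.na(out)]
    return(out)
  }
  if (is.null(batches)) stop("`batches` required for per-batch CVs")
  batches <- as.character(batches)
  levels <- unique(batches)
  out <- matrix(NA_real_, length(levels), ncol(values),
                dimnames = list(levels, colnames(values)))
  for (b in levels) {
    out[b, ] <- apply(values[batches == b, , drop = FALSE], 2, cv_one)
  }
  out
}

#' CV-based retention filter with study-sample rescue
#'
#' Retains lipids whose post-correction between-batch QC CV is below the
#' threshold (default 30%). Species failing the QC filter can still be
#' rescued when they are robustly detected in the study samples
#' themselves (detection rate at or above `rescue_rate`) — the situation
#' of lipids near the detection limit in reference plasma yet well
#' measured in the cohort matrix. Every decision carries its reason.
#'
#' @param cv named per-lipid CV vector (percent), computed post-correction.
#' @param threshold retention threshold in percent (default 30).
#' @param study_detection_rate optional named per-lipid fraction of study
#'   samples in which the species is detected (non-missing and > 0).
#' @param rescue_rate minimum detection rate for rescue (default 0.8).
#' @return data frame of class `retention_decision`: `lipid`,
#'   `between_batch_cv`, `retained`, `rescue_flag`, `reason`.
#' @export
retention_filter <- function(cv, threshold = 30,
                             study_detection_rate = NULL,
                             rescue_rate = 0.8) {
  lipids <- names(cv)
  if (is.null(lipids)) stop("`cv` must be a named vector")
  pass <- !is.na(cv) & cv < threshold
  det <- if (is.null(study_detection_rate)) rep(NA_real_, length(cv)) else
    study_detection_rate[lipids]
  rescue <- !pass & !is.na(det) & det >= rescue_rate
  reason <- ifelse(pass, "cv_below_threshold",
            ifelse(rescue, "rescued_robust_in_study",
            ifelse(is.na(cv), "cv_undefined", "cv_above_threshold")))
  data.frame(lipid = lipids, between_batch_cv = unname(cv),
             retained = pass | rescue, rescue_flag = rescue,
             reason = reason, row.names = NULL,
             stringsAsFactors = FALSE) -> out
  class(out) <- c("retention_decision", "data.frame")
  out
}

#' Nested-model check for run-order drift terms
#'
#' Reproduces the decision procedure of testing whether adding a
#' within-run injection-order covariate to the per-lipid `lipid ~ batch`
#' QC model is supported: per lipid, an F-test compares
#' `lm(y ~ batch)` against `lm(y ~ batch + order)`. A small fraction of
#' significant lipids (at `alpha`) indicates run-order terms are not
#' needed, so the batch-only model is kept.
#'
#' @param qc matrix or [abundance_matrix()] of QC rows.
#' @param batches batch label per QC row.
#' @param order injection order per QC row.
#' @param alpha significance level for the summary fraction.
#' @return list with per-lipid `p_values` and the `fraction_significant`.
#' @export
run_order_check <- function(qc, batches, order, alpha = 0.05) {
  values <- if (inherits(qc, "abundance_matrix")) unclass_matrix(qc) else qc
  batches <- factor(batches)
  p <- apply(values, 2, function(y) {
    ok <- !is.na(y)
    if (sum(ok) < nlevels(batches) + 2) return(NA_real_)
    m0 <- lm(y[ok] ~ batches[ok])
    m1 <- lm(y[ok] ~ batches[ok] + order[ok])
    a <- anova(m0, m1)
    a$`Pr(>F)`[2]
  })
  list(p_values = p,
       fraction_significant = mean(p < alpha, na.rm = TRUE))
}
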