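# Depth-adjusted differential accessibility. The model is a logistic
# regression of cell-population membership on per-peak normalized
# accessibility with log sequencing depth as a covariate:
#   full:  logit P(nucleus in target) ~ b0 + b1 * a + b2 * log(depth)
#   null:  logit P(nucleus in target) ~ b0 + b2 * log(depth)
# with a = log1p(1e4 * count / depth). The p-value is the likelihood-ratio
# chi-square with one degree of freedom. The null fit does not depend on the
# peak, so it is fitted once per comparison.

LOG2FC_PSEUDOCOUNT <- 1
SPECIFIC_ADJ_P <- 0.05
SPECIFIC_LOG2FC <- log2(1.5)

# Internal: LR test of y ~ a + logd against y ~ logd for each row of `anorm`
# (the log-normalized accessibility) with `araw` (the 1e4-scaled linear
# accessibility) used for fold changes.
lr_test_core <- function(anorm, araw, y, logd, group) {
  n <- length(y)
  ctrl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  x_null <- cbind(1, logd)
  fit_null <- suppressWarnings(
    stats::glm.fit(x_null, y, family = stats::binomial(), control = ctrl)
  )
  dev_null <- fit_null$deviance

  npk <- nrow(anorm)
  p <- numeric(npk)
  stat <- numeric(npk)
  converged <- logical(npk)
  for (i in seq_len(npk)) {
    ai <- anorm[i, ]
    if (max(ai) == min(ai)) {     # degenerate predictor (e.g. all zeros)
      stat[i] <- 0
      p[i] <- 1
      converged[i] <- TRUE
      next
    }
    fit <- suppressWarnings(
      stats::glm.fit(cbind(x_null, ai), y, family = stats::binomial(),
                     control = ctrl)
    )
    # a deviance at its numerical floor is complete separation, not a
    # failed fit: the LR statistic (= null deviance) is finite and valid
    if (!isTRUE(fit$converged) && fit$deviance > 1e-6) {
      stat[i] <- NA_real_
      p[i] <- 1
      converged[i] <- FALSE
      next
    }
    stat[i] <- max(dev_null - fit$deviance, 0)
    p[i] <- stats::pchisq(stat[i], df = 1, lower.tail = FALSE)
    converged[i] <- TRUE
  }

  mt <- Matrix::rowMeans(araw[, y == 1, drop = FALSE])
  mo <- Matrix::rowMeans(araw[, y == 0, drop = FALSE])
  log2fc <- log2((mt + LOG2FC_PSEUDOCOUNT) / (mo + LOG2FC_PSEUDOCOUNT))
  adj <- bh_adjust(p)
  data.frame(
    peak_id = rownames(anorm),
    group = group,
    log2fc = log2fc,
    p_value = p,
    adj_p = adj,
    specific = adj <= SPECIFIC_ADJ_P & log2fc >= SPECIFIC_LOG2FC,
    converged = converged,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# Internal: normalized accessibility matrices for a count matrix.
accessibility_predictors <- function(x) {
  m <- x$counts
  colidx <- rep(seq_len(ncol(m)), diff(m@p))
  araw <- m
  araw@x <- 1e4 * m@x / x$depth[colidx]
  anorm <- araw
  anorm@x <- log1p(araw@x)
  list(anorm = as.matrix(anorm), araw = araw)
}

#' Differential accessibility: one cell type against the rest
#'
#' Likelihood-ratio test per peak of target-population membership on
#' depth-normalized accessibility, with log depth as covariate in both the
#' full and the null model. The fold change is computed on the linear
#' `1e4 * count / depth` scale with a pseudocount of 1, and p-values are
#' BH-adjusted across peaks within the comparison. A peak is flagged
#' `specific` if `adj_p <= 0.05` and `log2fc >= log2(1.5)`. Non-converged
#' fits are reported with `p_value = 1` and `converged = FALSE`.
#'
#' @param x A [count_matrix] (one stage).
#' @param target Cell-type label to compare against all other nuclei.
#' @return A data.frame with columns `peak_id`, `group`, `log2fc`,
#'   `p_value`, `adj_p`, `specific`, `converged`.
#' @export
lr_differential_test <- function(x, target) {
  y <- as.numeric(x$labels == target)
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    validation_error("need at least 2 nuclei on each side of the comparison")
  }
  if (any(x$depth == 0)) {
    validation_error("zero-depth nucleus; run qc_filter first")
  }
  pred <- accessibility_predictors(x)
  lr_test_core(pred$anorm, pred$araw, y, log(x$depth), target)
}

#' Differential accessibility between two stages within one cell type
#'
#' Restricts both matrices to their shared peak universe and the given cell
#' type, then runs the same likelihood-ratio test with stage membership as
#' the outcome. `log2fc` is oriented stage-A over stage-B, so peaks specific
#' to stage A satisfy the `specific` flag; rerun with the matrices swapped
#' for stage-B-specific peaks.
#'
#' @param x_a,x_b [count_matrix] objects for the two stages.
#' @param celltype Cell-type label tested.
#' @param stage_labels Length-2 character labels used for the `group` column.
#' @return A data.frame as in [lr_differential_test].
#' @export
stage_specific_test <- function(x_a, x_b, celltype,
                                stage_labels = c("stage_a", "stage_b")) {
  shared <- intersect(x_a$peaks$id, x_b$peaks$id)
  if (length(shared) == 0) {
    validation_error("empty intersection of peak universes")
  }
  a <- subset_count_matrix(x_a, nuclei = x_a$labels == celltype,
                           peaks = shared)
  b <- subset_count_matrix(x_b, nuclei = x_b$labels == celltype,
                           peaks = shared)
  if (n_nuclei(a) < 2 || n_nuclei(b) < 2) {
    validation_error("need at least 2 nuclei of '", celltype,
                     "' in each stage")
  }
  counts <- cbind(a$counts, b$counts)
  colnames(counts) <- c(paste0(stage_labels[1], ":", a$barcodes),
                        paste0(stage_labels[2], ":", b$barcodes))
  merged <- count_matrix(
    counts, a$peaks, colnames(counts),
    rep(stage_labels, c(n_nuclei(a), n_nuclei(b)))
  )
  y <- as.numeric(merged$labels == stage_labels[1])
  pred <- accessibility_predictors(merged)
  lr_test_core(pred$anorm, pred$araw, y, log(merged$depth), stage_labels[1])
}

#' Peak ids flagged specific in a differential result
#' @param da A data.frame from [lr_differential_test].
#' @return Character vector of specific peak ids.
#' @export
specific_peaks <- function(da) da$peak_id[da$specific]
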