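# Training targets, dataset balancing, evaluation metrics and
# refinement-selection logic.

#' Normalized ligand RMSD training target
#'
#' `LRMSD_norm = 1 / (1 + (LRMSD / 4)^2)`: 1 for a perfect decoy, 0.5 at
#' the 4 Angstrom correctness threshold, tending to 0 for distant poses.
#' Strictly decreasing in LRMSD.
#'
#' @param lrmsd LRMSD values in Angstrom (>= 0).
#' @return Values in (0, 1].
#' @export
ipr_normalize_lrmsd <- function(lrmsd) {
  if (any(lrmsd < 0)) stopf("LRMSD must be non-negative")
  1 / (1 + (lrmsd / 4.0)^2)
}

#' Assign a normalized-LRMSD value to a classification bin
#'
#' Bins are evenly spread over \[0, 1\] and right-closed:
#' bin i covers `(i/n, (i+1)/n]`, so a perfect decoy (norm 1) lands in the
#' top bin and, with two bins, the boundary coincides with the 4 Angstrom
#' correctness threshold (4.0 Angstrom exactly falls in the lower bin,
#' matching the strict LRMSD < 4 definition of a correct decoy).
#'
#' @param lrmsd_norm Values in (0, 1].
#' @param n_bins Number of bins (2-4).
#' @return Integer bin indices in `0:(n_bins - 1)`.
#' @export
ipr_assign_bin <- function(lrmsd_norm, n_bins) {
  if (!n_bins %in% 2:4) stopf("n_bins must be 2, 3 or 4")
  if (any(lrmsd_norm <= 0 | lrmsd_norm > 1))
    stopf("lrmsd_norm must lie in (0, 1]")
  as.integer(ceiling(lrmsd_norm * n_bins) - 1L)
}

#' Balance a labeled decoy table for training
#'
#' Two-stage, seeded down-sampling: (1) within each target, the majority
#' correctness class (correct = LRMSD < 4 Angstrom) is down-sampled to the
#' minority count, so every target contributes equally many correct and
#' incorrect decoys; (2) each homology group's total is capped at the
#' median group total, removing whole correct/incorrect pairs so the
#' per-target class balance from stage 1 is preserved. The output order is
#' deterministically shuffled. Labels are never modified.
#'
#' @param decoys data.frame with columns `target_id`, `group_id`, `lrmsd`
#'   (plus any others, carried through).
#' @param seed RNG seed for the down-sampling.
#' @return The balanced subset of `decoys`.
#' @export
ipr_balance <- function(decoys, seed = 1L) {
  if (nrow(decoys) == 0L) stopf("empty decoy table")
  multi <- tapply(decoys$group_id, decoys$target_id,
                  function(g) length(unique(g)))
  if (any(multi > 1L))
    stopf("target(s) mapped to more than one homology group: %s",
          paste(names(multi)[multi > 1L], collapse = ", "))
  with_seed(seed, {
    correct <- decoys$lrmsd < 4.0
    keep <- unlist(lapply(split(seq_len(nrow(decoys)), decoys$target_id), function(ix) {
      pos <- ix[correct[ix]]; neg <- ix[!correct[ix]]
      k <- min(length(pos), length(neg))
      c(if (length(pos) > k) sample(pos, k) else pos,
        if (length(neg) > k) sample(neg, k) else neg)
    }), use.names = FALSE)
    d <- decoys[sort(keep), , drop = FALSE]
    # pair each correct decoy with an incorrect one within its target, so
    # the group cap can drop pair units without unbalancing any target
    resample <- function(x) x[sample.int(length(x))]
    pair_of <- integer(nrow(d))
    for (ix in split(seq_len(nrow(d)), d$target_id)) {
      pos <- resample(ix[d$lrmsd[ix] < 4.0])
      neg <- resample(ix[d$lrmsd[ix] >= 4.0])
      pair_of[pos] <- seq_along(pos)
      pair_of[neg] <- seq_along(neg)
    }
    pair_key <- paste(d$target_id, pair_of)
    sizes <- table(d$group_id)
    cap <- stats::median(sizes)
    keep2 <- unlist(lapply(split(seq_len(nrow(d)), d$group_id), function(ix) {
      if (length(ix) <= cap) return(ix)
      units <- unique(pair_key[ix])
      kept_units <- sample(units, floor(cap / 2))
      ix[pair_key[ix] %in% kept_units]
    }), use.names = FALSE)
    d <- d[sort(keep2), , drop = FALSE]
    d[sample(nrow(d)), , drop = FALSE]
  })
}

#' ROC curve and AUC for decoy correctness
#'
#' Sweeps the unique scores as thresholds (equal scores grouped at one
#' threshold), predicting "correct" where score >= threshold.
#' `FPR = FP / N` and `TPR = TP / P`; the series starts at (0, 0) and ends
#' at (1, 1) and the AUC is computed by the trapezoid rule.
#'
#' @param scores Numeric decoy scores (higher = predicted better).
#' @param labels Logical (or 0/1) correctness labels.
#' @return Object of class `ipr_roc`: list with `thresholds`, `fpr`, `tpr`,
#'   `auc`.
#' @export
ipr_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  P <- sum(labels); N <- sum(!labels)
  if (P == 0L || N == 0L)
    stopf("ROC undefined: need at least one correct and one incorrect decoy")
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  cum_tp <- cumsum(labels[ord])
  cum_fp <- cumsum(!labels[ord])
  last <- cumsum(as.numeric(table(factor(-scores[ord], levels = unique(-scores[ord])))))
  tpr <- c(0, cum_tp[last] / P)
  fpr <- c(0, cum_fp[last] / N)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  structure(list(thresholds = c(Inf, thr), fpr = fpr, tpr = tpr, auc = auc),
            class = "ipr_roc")
}

#' @export
print.ipr_roc <- function(x, ...) {
  cat(sprintf("<ipr_roc> %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' @export
plot.ipr_roc <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Precision-recall series
#'
#' Same threshold sweep as [ipr_roc()]. With a single-class input the
#' undefined quantity is reported as `NA` (precision when there are no
#' positives predicted never occurs because thresholds are attained
#' scores; recall is `NA` when there are no true positives in the data).
#'
#' @inheritParams ipr_roc
#' @return data.frame with `threshold`, `precision`, `recall`.
#' @export
ipr_precision_recall <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels)
  rows <- lapply(thr, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels)
    data.frame(threshold = t,
               precision = tp / sum(pred),
               recall = if (P > 0L) tp / P else NA_real_)
  })
  do.call(rbind, rows)
}

#' Spearman rank correlation
#'
#' Average-rank tie convention (plain `cor(..., method = "spearman")` with
#' an input-length check).
#'
#' @param x,y Numeric vectors, length >= 2.
#' @return rho in \[-1, 1\].
#' @export
ipr_spearman <- function(x, y) {
  if (length(x) < 2L || length(x) != length(y))
    stopf("ipr_spearman needs two vectors of equal length >= 2")
  cor(x, y, method = "spearman")
}

#' Select decoys for refinement
#'
#' Either the `top_n` highest-scoring decoys (ties broken by decoy id) or
#' all decoys with score >= `value` (`cutoff` mode, boundary inclusive; the
#' reference operating point for refinement selection is a score cutoff
#' of 0.47).
#'
#' @param scores data.frame with columns `decoy_id` and `score`.
#' @param mode `"top_n"` or `"cutoff"`.
#' @param value Number of decoys (top_n) or score threshold (cutoff).
#' @return The selected rows, ordered by decreasing score (ties by id),
#'   with a `rank` column.
#' @export
ipr_select <- function(scores, mode = c("top_n", "cutoff"), value) {
  mode <- match.arg(mode)
  ord <- order(-scores$score, scores$decoy_id)
  s <- scores[ord, , drop = FALSE]
  s$rank <- seq_len(nrow(s))
  if (mode == "top_n") {
    if (!is_count(value)) stopf("top_n requires a positive integer")
    s <- s[seq_len(min(value, nrow(s))), , drop = FALSE]
  } else {
    s <- s[s$score >= value, , drop = FALSE]
  }
  rownames(s) <- NULL
  s
}

#' Split targets into folds with disjoint homology groups
#'
#' All targets sharing a `group_id` land in the same fold; groups are
#' shuffled (seeded) and assigned greedily to the fold with the largest
#' remaining deficit relative to `fractions`.
#'
#' @param targets data.frame with columns `target_id`, `group_id` (one row
#'   per target).
#' @param fractions Named numeric vector of fold proportions, summing to 1.
#' @param seed RNG seed.
#' @return `targets` with an added `split` column.
#' @export
ipr_grouped_split <- function(targets,
                              fractions = c(train = 0.7, validation = 0.15, test = 0.15),
                              seed = 1L) {
  targets <- unique(targets[, c("target_id", "group_id")])
  with_seed(seed, {
    groups <- sample(unique(targets$group_id))
    quota <- fractions * nrow(targets)
    assigned <- stats::setNames(numeric(length(fractions)), names(fractions))
    gsplit <- character(length(groups)); names(gsplit) <- groups
    for (g in groups) {
      deficit <- quota - assigned
      fold <- names(which.max(deficit))
      gsplit[g] <- fold
      assigned[fold] <- assigned[fold] + sum(targets$group_id == g)
    }
    targets$split <- unname(gsplit[targets$group_id])
  })
  targets
}
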