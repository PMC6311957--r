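#' Label genes high/low by FPKM quartile
#'
#' Genes are sorted by FPKM descending (ties broken by gene id for
#' determinism); the top 25% (`ceiling(n / 4)` genes) are labelled
#' `high`, the bottom 25% `low`, and the middle half is excluded. The two
#' classes have equal size by construction, so a majority-class baseline
#' scores a balanced accuracy of 0.5.
#'
#' @param expr Named numeric FPKM vector (>= 4 genes, not all equal).
#' @return List of class `ExpressionLabels`: `labels` (named factor with
#'   levels `high`, `low` over the retained genes), `fpkm_high_min`,
#'   `fpkm_low_max`, `n_high`, `n_low`.
#' @export
quartile_labels <- function(expr) {
  n <- length(expr)
  if (n < 4L) stop("need at least 4 genes for quartile labelling")
  if (length(unique(expr)) == 1L) {
    stop("all FPKM values equal: quartiles are degenerate")
  }
  ord <- order(-expr, names(expr))
  k <- as.integer(ceiling(n / 4))
  hi <- ord[seq_len(k)]
  lo <- ord[seq.int(n - k + 1L, n)]
  labels <- factor(c(rep("high", k), rep("low", k)),
                   levels = c("high", "low"))
  names(labels) <- c(names(expr)[hi], names(expr)[lo])
  structure(list(labels = labels,
                 fpkm_high_min = min(expr[hi]),
                 fpkm_low_max = max(expr[lo]),
                 n_high = k, n_low = k),
            class = "ExpressionLabels")
}

#' Balanced classification metrics
#'
#' Sensitivity `Sn = TP / (TP + FN)`, specificity `Sp = TN / (TN + FP)`,
#' and the balanced accuracy `Acc = (Sn + Sp) / 2`.
#'
#' @param tp,tn,fp,fn Confusion-matrix counts; both classes must be
#'   represented (`TP + FN > 0`, `TN + FP > 0`).
#' @return One-row data.frame `tp`, `tn`, `fp`, `fn`, `sn`, `sp`, `acc`.
#' @export
evaluate_metrics <- function(tp, tn, fp, fn) {
  if (tp + fn == 0) stop("no positive examples (TP + FN = 0)")
  if (tn + fp == 0) stop("no negative examples (TN + FP = 0)")
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  data.frame(tp = tp, tn = tn, fp = fp, fn = fn,
             sn = sn, sp = sp, acc = (sn + sp) / 2)
}

# Stratified k-fold assignment: within each class, genes are shuffled and
# dealt round-robin, so every fold sees both classes.
.make_folds <- function(labels, k, seed) {
  .with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in levels(labels)) {
      i <- which(labels == cls)
      i <- i[sample.int(length(i))]
      fold[i] <- rep_len(seq_len(k), length(i))
    }
    fold
  })
}

# z-score columns of train/test using training statistics only (no
# leakage); constant training columns are left centered, not divided.
.scale_train_test <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  sd <- apply(train_x, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(train = sweep(sweep(train_x, 2, mu), 2, sd, "/"),
       test = sweep(sweep(test_x, 2, mu), 2, sd, "/"))
}

#' SVM classification scan over feature sets
#'
#' For each feature set (a subset of factors), trains a soft-margin
#' radial-kernel SVM (libSVM via e1071) to separate high from low
#' expressed genes from their TFAS values, under stratified k-fold
#' cross-validation. Features are transformed `log(1 + A)` and z-scored
#' with training-fold statistics only; the per-fold confusion counts are
#' pooled per fold into [evaluate_metrics()] and the k fold metrics are
#' averaged.
#'
#' @param tfas TFAS matrix from [tfas_matrix()]; rownames must cover the
#'   labelled genes.
#' @param labels An `ExpressionLabels` from [quartile_labels()].
#' @param feature_sets Named list of character vectors of factor names;
#'   default: every single factor on its own.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param cost,gamma libSVM soft-margin cost and RBF width; `gamma =
#'   NULL` uses `1 / n_features`.
#' @param transform Apply the `log1p` + z-score transform (`TRUE`) or use
#'   raw TFAS features.
#' @return data.frame, one row per feature set: `feature_set`,
#'   `n_features`, `sn`, `sp`, `acc` (fold averages).
#' @export
svm_scan <- function(tfas, labels, feature_sets = NULL, folds = 5L,
                     seed = 1L, cost = 1, gamma = NULL, transform = TRUE) {
  stopifnot(inherits(labels, "ExpressionLabels"))
  lab <- labels$labels
  miss <- setdiff(names(lab), rownames(tfas))
  if (length(miss)) {
    stop("labelled gene(s) missing from TFAS matrix: ",
         paste(utils::head(miss, 3), collapse = ", "))
  }
  if (is.null(feature_sets)) {
    feature_sets <- stats::setNames(as.list(colnames(tfas)), colnames(tfas))
  }
  for (fs in feature_sets) {
    if (!length(fs)) stop("empty feature set")
    bad <- setdiff(fs, colnames(tfas))
    if (length(bad)) stop("unknown factor(s) in feature set: ",
                          paste(bad, collapse = ", "))
  }
  x_all <- tfas[names(lab), , drop = FALSE]
  if (transform) x_all <- log1p(x_all)
  fold <- .make_folds(lab, folds, seed)
  rows <- lapply(seq_along(feature_sets), function(si) {
    fs <- feature_sets[[si]]
    metrics <- lapply(seq_len(folds), function(fi) {
      tr <- fold != fi
      sc <- .scale_train_test(x_all[tr, fs, drop = FALSE],
                              x_all[!tr, fs, drop = FALSE])
      fit <- e1071::svm(sc$train, lab[tr], kernel = "radial", cost = cost,
                        gamma = if (is.null(gamma)) 1 / length(fs) else gamma,
                        scale = FALSE)
      pred <- stats::predict(fit, sc$test)
      truth <- lab[!tr]
      evaluate_metrics(tp = sum(pred == "high" & truth == "high"),
                       tn = sum(pred == "low" & truth == "low"),
                       fp = sum(pred == "high" & truth == "low"),
                       fn = sum(pred == "low" & truth == "high"))
    })
    m <- do.call(rbind, metrics)
    data.frame(feature_set = names(feature_sets)[si] %||%
                 paste(fs, collapse = "+"),
               n_features = length(fs),
               sn = mean(m$sn), sp = mean(m$sp), acc = mean(m$acc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || !nzchar(a)) b else a

#' Prediction difference index between two cell lines
#'
#' `D_Acc = (Acc^G - Acc^K) / (Acc^G + Acc^K)` for a factor's single-
#' predictor classification accuracies in the two cell lines;
#' antisymmetric under swapping them.
#'
#' @param acc_g,acc_k Balanced accuracies in `[0, 1]` with
#'   `acc_g + acc_k > 0`.
#' @return Index in `[-1, 1]`.
#' @export
prediction_difference <- function(acc_g, acc_k) {
  stopifnot(all(acc_g >= 0), all(acc_k >= 0))
  if (any(acc_g + acc_k == 0)) stop("both accuracies are zero")
  (acc_g - acc_k) / (acc_g + acc_k)
}

#' Correlate prediction dynamics with binding dynamics
#'
#' Pearson correlation between the per-factor prediction difference
#' index `D_Acc` and the binding total difference index `D_signal`,
#' aligned by factor.
#'
#' @param d_acc,d_signal Numeric vectors aligned by factor (length >= 3).
#' @return Pearson correlation, or `NA` if either vector is constant.
#' @export
correlate_dynamics <- function(d_acc, d_signal) {
  if (length(d_acc) != length(d_signal)) stop("inputs are not aligned")
  stopifnot(length(d_acc) >= 3L)
  pair_pcc(d_acc, d_signal)
}
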