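# Multiclass evaluation: one-vs-rest per-class metrics, confusion matrices
# in counts and row-percent views, ROC curves by threshold sweep, and
# stratified k-fold planning.

#' Per-class and aggregate classification metrics
#'
#' Every class is scored one-vs-rest: accuracy `(TP+TN)/N`, precision,
#' recall (sensitivity), F1, specificity `TN/(TN+FP)`, and the
#' complementary error rates `FPR = 1 - specificity`,
#' `FNR = 1 - sensitivity`. Aggregates are macro averages; overall
#' accuracy is the confusion-matrix trace over the total. When `probs` is
#' supplied, one-vs-rest ROC curves and AUCs are computed by threshold
#' sweep.
#'
#' @param y_true,y_pred integer (1-based) or character labels
#' @param probs optional `n x K` matrix of class probabilities
#' @param class_names class vocabulary; inferred when omitted
#' @return a `metrics_report`: `per_class` data frame, `macro` list,
#'   `accuracy`, `confusion` (counts), `confusion_percent` (rows sum to
#'   100), and `roc` (per-class list of points + `auc`) when probabilities
#'   were given
#' @export
compute_metrics <- function(y_true, y_pred, probs = NULL, class_names = NULL) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  if (is.null(class_names)) {
    class_names <- if (is.numeric(y_true)) {
      as.character(seq_len(max(y_true, y_pred)))
    } else sort(unique(c(y_true, y_pred)))
  }
  to_idx <- function(y) {
    if (is.numeric(y)) as.integer(y) else match(y, class_names)
  }
  yt <- to_idx(y_true); yp <- to_idx(y_pred)
  K <- length(class_names)
  if (any(is.na(yt) | is.na(yp) | yt < 1L | yt > K | yp < 1L | yp > K)) {
    stop("labels outside the class set")
  }
  n <- length(yt)
  conf <- matrix(0L, K, K, dimnames = list(true = class_names,
                                           predicted = class_names))
  for (i in seq_len(n)) conf[yt[i], yp[i]] <- conf[yt[i], yp[i]] + 1L
  rs <- rowSums(conf)
  conf_pct <- sweep(conf, 1, ifelse(rs == 0, 1, rs), "/") * 100

  per <- lapply(seq_len(K), function(k) {
    tp <- conf[k, k]
    fn <- rs[k] - tp
    fp <- sum(conf[, k]) - tp
    tn <- n - tp - fn - fp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = class_names[k], n = rs[k],
               accuracy = (tp + tn) / n, precision = prec,
               recall = rec, sensitivity = rec, f1 = f1,
               specificity = spec, fpr = 1 - spec, fnr = 1 - rec)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL

  roc <- NULL
  if (!is.null(probs)) {
    probs <- as.matrix(probs)
    stopifnot(nrow(probs) == n, ncol(probs) == K)
    roc <- lapply(seq_len(K), function(k) {
      roc_curve(probs[, k], yt == k)
    })
    names(roc) <- class_names
  }
  structure(list(
    per_class = per,
    macro = list(precision = mean(per$precision), recall = mean(per$recall),
                 f1 = mean(per$f1), specificity = mean(per$specificity),
                 fpr = mean(per$fpr), fnr = mean(per$fnr)),
    accuracy = sum(diag(conf)) / n,
    confusion = conf, confusion_percent = conf_pct,
    roc = roc, n = n, class_names = class_names
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d, accuracy = %.4f, macro F1 = %.4f\n",
              x$n, x$accuracy, x$macro$f1))
  print(x$per_class, digits = 3)
  invisible(x)
}

#' One-vs-rest ROC curve by threshold sweep
#'
#' @param scores numeric scores for the positive class
#' @param positive logical vector, `TRUE` for positives
#' @return list with a `points` data frame (`threshold`, `fpr`, `tpr`;
#'   monotone non-decreasing) and the trapezoidal `auc`
#' @export
roc_curve <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  P <- sum(positive); Nn <- sum(!positive)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- positive[o]
  tp <- cumsum(p); fp <- cumsum(!p)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied score
  tpr <- c(0, tp[keep] / max(1L, P))
  fpr <- c(0, fp[keep] / max(1L, Nn))
  thr <- c(Inf, s[keep])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Stratified k-fold plan
#'
#' Samples of each class are shuffled and dealt round-robin across folds,
#' so per-fold class counts differ from perfect proportionality by at most
#' one sample. Errors if any class has fewer than `k` samples.
#'
#' @param labels integer or character class labels
#' @param k number of folds
#' @param seed RNG seed recorded in the plan
#' @return a `fold_plan`: integer `assignments` (fold id per sample), `k`,
#'   `seed`
#' @export
fold_plan <- function(labels, k = 10L, seed = 1L) {
  k <- as.integer(k)
  tab <- table(labels)
  small <- names(tab)[tab < k]
  if (length(small) > 0L) {
    stop("class(es) with fewer than k = ", k, " samples: ",
         paste(small, collapse = ", "))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  assignments <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    assignments[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(list(assignments = assignments, k = k, seed = seed,
                 stratified = TRUE),
            class = "fold_plan")
}
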