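#' Build a labeled triplet dataset from a catalogue and a network
#'
#' Positives are the size-3 catalogue complexes whose members form a single
#' connected component in the network (heterotrimers failing the
#' connectivity restriction are dropped). The negative pool consists of all
#' connected 3-subsets of catalogue complexes of size greater than three
#' that do not themselves appear as size-3 catalogue complexes; `n_negatives`
#' of them are sampled uniformly without replacement.
#'
#' @param cat a [complex_catalogue]
#' @param net a [ppi_network]
#' @param n_negatives number of negative examples to sample
#' @param seed integer seed driving the negative sample
#' @return data.frame with columns `key` (canonical triplet key) and
#'   `label` (+1/-1); attribute `n_negative_pool` records the pool size
#' @export
build_dataset <- function(cat, net, n_negatives = 100, seed = 1) {
  pos_members <- catalogue_by_size(cat, size = 3)$complexes
  pos_keys <- vapply(pos_members, triplet_key, "")
  connected <- vapply(pos_members, function(m) is_connected_triplet(net, m),
                      TRUE)
  pos_keys <- sort(unique(pos_keys[connected]))

  all_pos_keys <- vapply(pos_members, triplet_key, "")
  big <- catalogue_by_size(cat, min_size = 4)$complexes
  pool <- unlist(lapply(big, function(members) {
    subs <- utils::combn(members, 3, simplify = FALSE)
    keep <- vapply(subs, function(s) is_connected_triplet(net, s), TRUE)
    vapply(subs[keep], triplet_key, "")
  }))
  pool <- sort(setdiff(unique(pool), all_pos_keys))
  if (length(pool) < n_negatives) {
    stop(sprintf(
      "negative pool has %d connected 3-subsets but %d negatives requested",
      length(pool), n_negatives))
  }
  neg_keys <- withr::with_seed(seed, sample(pool, n_negatives))
  out <- data.frame(key = c(pos_keys, neg_keys),
                    label = c(rep(1, length(pos_keys)),
                              rep(-1, length(neg_keys))),
                    stringsAsFactors = FALSE)
  attr(out, "n_negative_pool") <- length(pool)
  out
}

# stratified fold assignment: permute within each class, deal out fold ids
stratified_folds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

# fit + predict one fold with the requested method
fit_predict_method <- function(method, train_keys, train_labels, test_keys,
                               net, dom, alpha, cost, ctx) {
  if (method == "single-phase") {
    m <- fit_single_phase(train_keys, train_labels, net, dom, alpha, cost,
                          ctx = ctx)
    predict_single_phase(m, test_keys)
  } else {
    second <- if (method == "two-phase-sb") "sparse-bayes" else "max-margin"
    m <- fit_two_phase(train_keys, train_labels, net, dom, alpha, cost,
                       second_classifier = second, ctx = ctx)
    predict_two_phase(m, test_keys)
  }
}

#' Repeated stratified cross-validation of the triplet classifiers
#'
#' Emulates the evaluation protocol of the heterotrimer prediction
#' experiments: per repeat, a fresh uniform sample of negatives is drawn
#' from the 3-subsets of larger catalogue complexes (positives are fixed),
#' the dataset is split into stratified folds, each fold is held out once,
#' metrics are computed per fold and averaged over folds, and finally
#' averaged over repeats. All randomness derives from `seed`.
#'
#' @param net a [ppi_network]
#' @param dom a [domain_annotation]
#' @param cat a [complex_catalogue]
#' @param methods character vector from `"two-phase-mm"` (SVM+SVM),
#'   `"two-phase-sb"` (SVM+RVM), `"single-phase"` (SVM on phase-1 features)
#' @param alpha domain-kernel mixing constant (scalar or vector; each value
#'   evaluated)
#' @param cost soft-margin cost
#' @param folds number of cross-validation folds
#' @param repeats number of repeats with freshly sampled negatives
#' @param n_negatives negatives per dataset
#' @param seed master seed
#' @param pool_folds if `TRUE`, pool confusion counts over folds before
#'   computing metrics (per repeat) instead of averaging per-fold metrics
#' @param ctx optional precomputed [triplet_context()]
#' @return data.frame: one row per method x alpha with averaged `accuracy`,
#'   `precision`, `recall`, `f_measure`; attribute `detail` holds the
#'   per-repeat, per-fold records
#' @export
cross_validate <- function(net, dom, cat,
                           methods = c("two-phase-mm", "two-phase-sb",
                                       "single-phase"),
                           alpha = 0.5, cost = 1, folds = 10, repeats = 10,
                           n_negatives = 100, seed = 1, pool_folds = FALSE,
                           ctx = NULL) {
  stopifnot(folds >= 2)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(ctx) && any(methods != "single-phase")) {
    ctx <- triplet_context(net, dom)
  }
  detail <- list()
  summary_rows <- list()
  for (a in alpha) {
    per_method <- lapply(methods, function(m) NULL)
    names(per_method) <- methods
    for (r in seq_len(repeats)) {
      rep_seed <- seed + 7919L * (r - 1L)
      ds <- build_dataset(cat, net, n_negatives = n_negatives,
                          seed = rep_seed)
      if (length(unique(ds$label)) < 2L) {
        stop("dataset must contain both classes")
      }
      fold <- stratified_folds(ds$label, folds, seed = rep_seed + 1L)
      if (any(tapply(ds$label == 1, fold, sum) == 0)) {
        warning("a fold received no positive examples despite stratification")
      }
      for (m in methods) {
        fold_metrics <- matrix(NA_real_, nrow = folds, ncol = 4)
        pooled <- confusion_counts()
        for (k in seq_len(folds)) {
          tr <- fold != k
          pred <- fit_predict_method(m, ds$key[tr], ds$label[tr],
                                     ds$key[!tr], net, dom, a, cost, ctx)
          cc <- count_confusion(pred$label, ds$label[!tr])
          fold_metrics[k, ] <- confusion_metrics(cc)
          pooled <- confusion_counts(pooled$tp + cc$tp, pooled$fp + cc$fp,
                                     pooled$tn + cc$tn, pooled$fn + cc$fn)
          detail[[length(detail) + 1L]] <- data.frame(
            method = m, alpha = a, repeat_ = r, fold = k,
            tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn)
        }
        rep_metrics <- if (pool_folds) confusion_metrics(pooled)
        else colMeans(fold_metrics)
        per_method[[m]] <- rbind(per_method[[m]], rep_metrics)
      }
    }
    for (m in methods) {
      avg <- colMeans(per_method[[m]])
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        method = m, alpha = a,
        accuracy = avg[1], precision = avg[2], recall = avg[3],
        f_measure = avg[4], row.names = NULL)
    }
  }
  out <- do.call(rbind, summary_rows)
  attr(out, "detail") <- do.call(rbind, detail)
  out
}
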