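#' Precomputed triplet context for a network
#'
#' Enumerates every connected triplet of the network once and caches the
#' quantities both learning phases reuse across folds: phase-1 feature
#' vectors, domain-composition signatures, and a protein -> triplet index so
#' neighboring sets N(x) are unions of per-member lookups.
#'
#' @param net a [ppi_network]
#' @param dom a [domain_annotation]
#' @return object of class `triplet_context` with fields `keys`, `F1`
#'   (feature matrix), `sig` (signatures), `by_protein` (environment:
#'   protein -> integer indices into `keys`), `net`, `dom`
#' @export
triplet_context <- function(net, dom) {
  keys <- enumerate_connected_triplets(net)
  F1 <- phase1_matrix(net, dom, keys)
  sig <- unname(triplet_signatures(dom, keys))
  by_protein <- new.env(parent = emptyenv())
  members <- triplet_members(keys)
  for (i in seq_along(members)) {
    for (p in members[[i]]) {
      cur <- if (exists(p, envir = by_protein, inherits = FALSE))
        get(p, envir = by_protein) else integer(0)
      assign(p, c(cur, i), envir = by_protein)
    }
  }
  structure(list(keys = keys, F1 = F1, sig = sig, by_protein = by_protein,
                 net = net, dom = dom),
            class = "triplet_context")
}

#' @export
print.triplet_context <- function(x, ...) {
  cat(sprintf("Triplet context: %d connected triplets\n", length(x$keys)))
  invisible(x)
}

# indices (into ctx$keys) of N(x) for the triplet at index i
context_neighbor_idx <- function(ctx, i) {
  m <- triplet_members(ctx$keys[i])[[1]]
  idx <- unlist(lapply(m, function(p) {
    if (exists(p, envir = ctx$by_protein, inherits = FALSE))
      get(p, envir = ctx$by_protein) else integer(0)
  }))
  sort(unique(idx[idx != i]))
}

#' Phase-2 features from discriminant values
#'
#' Summarises the phase-1 discriminant of a triplet and of its neighboring
#' triplets into four features: the triplet's own value, the mean of the
#' strictly positive neighbor values, the mean of the strictly negative
#' neighbor values, and the mean over all neighbors. Averaging positives and
#' negatives separately dampens outlying discriminants. Empty sets yield 0
#' (zeros among neighbor values count toward neither the positive nor the
#' negative mean).
#'
#' @param y_own discriminant value of the triplet itself
#' @param y_neighbors numeric vector of discriminants over exactly the
#'   members of N(x) (possibly empty)
#' @return named numeric vector `c(f2s, f2p, f2n, f2a)`
#' @export
phase2_features <- function(y_own, y_neighbors = numeric(0)) {
  pos <- y_neighbors[y_neighbors > 0]
  neg <- y_neighbors[y_neighbors < 0]
  c(f2s = y_own,
    f2p = if (length(pos) > 0) mean(pos) else 0,
    f2n = if (length(neg) > 0) mean(neg) else 0,
    f2a = if (length(y_neighbors) > 0) mean(y_neighbors) else 0)
}

#' Assemble the 11-dimensional phase-2 vector
#'
#' Fixed concatenation order: F1..F7, f2s, f2p, f2n, f2a.
#'
#' @param f1 numeric vector of length 7 (phase-1 features)
#' @param f2 numeric vector of length 4 (discriminant features)
#' @return numeric vector of length 11
#' @export
assemble_phase2 <- function(f1, f2) {
  stopifnot(length(f1) == 7L, length(f2) == 4L)
  out <- c(f1, f2)
  names(out) <- c(paste0("F", 1:7), "f2s", "f2p", "f2n", "f2a")
  out
}

# discriminant values of the phase-1 model for the context triplets `idx`
phase1_discriminants <- function(ctx, model, tr_idx, alpha, idx) {
  if (length(idx) == 0L) return(numeric(0))
  kc <- combined_gram(ctx$F1[idx, , drop = FALSE], ctx$sig[idx], alpha,
                      ctx$F1[tr_idx, , drop = FALSE], ctx$sig[tr_idx])
  discriminant(model, kc)
}

# phase-2 feature rows for context triplets `idx`, given a positional memo
# vector of discriminants covering idx and all its neighbors
phase2_rows <- function(ctx, idx, nb_list, y_memo) {
  t(vapply(seq_along(idx), function(j) {
    i <- idx[j]
    assemble_phase2(ctx$F1[i, ],
                    phase2_features(y_memo[i], y_memo[nb_list[[j]]]))
  }, numeric(11)))
}

# discriminants for union(idx, neighbors), as a vector positional in ctx$keys
phase1_discriminant_memo <- function(ctx, model, tr_idx, alpha, idx, nb_list) {
  needed <- sort(unique(c(idx, unlist(nb_list))))
  y <- phase1_discriminants(ctx, model, tr_idx, alpha, needed)
  memo <- rep(NA_real_, length(ctx$keys))
  memo[needed] <- y
  memo
}

#' Fit the two-phase heterotrimer classifier
#'
#' Phase 1 trains a max-margin classifier on the Gram matrix
#' `<f1, f1'> + alpha * Kc` of the training triplets. Its discriminant is
#' then evaluated, in-sample, on every training triplet and on every
#' connected triplet neighboring one (neighbor triplets need no labels; the
#' neighborhood is taken over the whole network). The resulting
#' 11-dimensional vectors feed a second classifier on
#' `<f2, f2'> + alpha * Kc` with the same labels: either another max-margin
#' machine or a sparse-Bayesian relevance vector machine. Only training
#' triplets' labels are ever read.
#'
#' @param train_keys canonical triplet keys of the training examples (all
#'   connected in `net`); see [triplet_key()]
#' @param labels -1/+1 labels, one per training key
#' @param net a [ppi_network]
#' @param dom a [domain_annotation]
#' @param alpha nonnegative domain-kernel mixing constant
#' @param cost soft-margin cost for the max-margin phases
#' @param second_classifier `"max-margin"` (SVM) or `"sparse-bayes"` (RVM)
#' @param ctx optional precomputed [triplet_context()] for `net`/`dom`
#'   (built on the fly otherwise)
#' @return object of class `two_phase_model`
#' @export
fit_two_phase <- function(train_keys, labels, net, dom, alpha = 0.5,
                          cost = 1,
                          second_classifier = c("max-margin", "sparse-bayes"),
                          ctx = NULL) {
  second_classifier <- match.arg(second_classifier)
  if (is.null(ctx)) ctx <- triplet_context(net, dom)
  labels <- as.numeric(labels)
  stopifnot(length(train_keys) == length(labels), length(labels) > 0)
  tr_idx <- match(train_keys, ctx$keys)
  if (anyNA(tr_idx)) {
    stop("training triplet not connected in the network: ",
         train_keys[which(is.na(tr_idx))[1]])
  }
  F1tr <- ctx$F1[tr_idx, , drop = FALSE]
  sig_tr <- ctx$sig[tr_idx]
  K1 <- combined_gram(F1tr, sig_tr, alpha)
  m1 <- train_kernel_svm(K1, labels, cost)

  nb_list <- lapply(tr_idx, function(i) context_neighbor_idx(ctx, i))
  memo <- phase1_discriminant_memo(ctx, m1, tr_idx, alpha, tr_idx, nb_list)
  F2tr <- phase2_rows(ctx, tr_idx, nb_list, memo)

  K2 <- combined_gram(F2tr, sig_tr, alpha)
  m2 <- if (second_classifier == "max-margin") {
    train_kernel_svm(K2, labels, cost)
  } else {
    fit_rvm(cbind(bias = 1, K2), labels)
  }
  structure(list(phase1 = m1, phase2 = m2,
                 second_classifier = second_classifier,
                 alpha = alpha, cost = cost,
                 train_keys = train_keys, tr_idx = tr_idx,
                 F1tr = F1tr, F2tr = F2tr, sig_tr = sig_tr,
                 ctx = ctx),
            class = "two_phase_model")
}

#' @export
print.two_phase_model <- function(x, ...) {
  cat(sprintf(
    "Two-phase heterotrimer classifier (%s second phase), %d training triplets, alpha = %g\n",
    x$second_classifier, length(x$train_keys), x$alpha))
  invisible(x)
}

#' Predict with a two-phase model
#'
#' Computes the test triplet's phase-1 features, its phase-1 discriminant
#' and those of its neighboring triplets, assembles the 11-dimensional
#' representation, and scores it against the training triplets with the
#' second-phase classifier. The label is the sign of the score; a score of
#' exactly 0 maps to the negative class.
#'
#' @param model a `two_phase_model`
#' @param keys canonical triplet key(s) of the test triplet(s); each must be
#'   connected in the training network
#' @return data.frame with columns `key`, `score` (second-phase
#'   discriminant; the linear response before the logistic link for the
#'   sparse-Bayes second phase) and `label` (-1/+1)
#' @export
predict_two_phase <- function(model, keys) {
  ctx <- model$ctx
  te_idx <- match(keys, ctx$keys)
  if (anyNA(te_idx)) {
    stop("test triplet not connected in the network: ",
         keys[which(is.na(te_idx))[1]])
  }
  nb_list <- lapply(te_idx, function(i) context_neighbor_idx(ctx, i))
  memo <- phase1_discriminant_memo(ctx, model$phase1, model$tr_idx,
                                   model$alpha, te_idx, nb_list)
  F2te <- phase2_rows(ctx, te_idx, nb_list, memo)
  K2c <- combined_gram(F2te, ctx$sig[te_idx], model$alpha,
                       model$F2tr, model$sig_tr)
  if (model$second_classifier == "max-margin") {
    score <- discriminant(model$phase2, K2c)
  } else {
    score <- predict_rvm(model$phase2, cbind(bias = 1, K2c))$y
  }
  data.frame(key = keys, score = score,
             label = ifelse(score > 0, 1, -1),
             stringsAsFactors = FALSE)
}

# single-phase (phase-1 features only) max-margin classifier, same surface
fit_single_phase <- function(train_keys, labels, net, dom, alpha = 0.5,
                             cost = 1, ctx = NULL) {
  if (is.null(ctx)) ctx <- triplet_context(net, dom)
  labels <- as.numeric(labels)
  tr_idx <- match(train_keys, ctx$keys)
  if (anyNA(tr_idx)) {
    stop("training triplet not connected in the network: ",
         train_keys[which(is.na(tr_idx))[1]])
  }
  F1tr <- ctx$F1[tr_idx, , drop = FALSE]
  sig_tr <- ctx$sig[tr_idx]
  K1 <- combined_gram(F1tr, sig_tr, alpha)
  m1 <- train_kernel_svm(K1, labels, cost)
  structure(list(phase1 = m1, alpha = alpha, cost = cost,
                 train_keys = train_keys, tr_idx = tr_idx,
                 F1tr = F1tr, sig_tr = sig_tr, ctx = ctx),
            class = "single_phase_model")
}

predict_single_phase <- function(model, keys) {
  ctx <- model$ctx
  te_idx <- match(keys, ctx$keys)
  if (anyNA(te_idx)) {
    stop("test triplet not connected in the network: ",
         keys[which(is.na(te_idx))[1]])
  }
  K1c <- combined_gram(ctx$F1[te_idx, , drop = FALSE], ctx$sig[te_idx],
                       model$alpha, model$F1tr, model$sig_tr)
  score <- discriminant(model$phase1, K1c)
  data.frame(key = keys, score = score,
             label = ifelse(score > 0, 1, -1),
             stringsAsFactors = FALSE)
}
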