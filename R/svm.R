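#' Train a max-margin classifier on a precomputed Gram matrix
#'
#' Fits a soft-margin support vector classifier (C-svc) on a precomputed
#' kernel matrix and repackages the solution as an explicit linear model in
#' kernel space: discriminant `y(x) = sum_i a_i K(x_i, x) + b` with `a_i`
#' nonzero only on support vectors. The sign convention is normalised so
#' that positive discriminants correspond to the +1 class.
#'
#' @param gram square symmetric PSD kernel matrix over the training examples
#' @param labels vector of -1/+1 class labels, one per row of `gram`
#' @param cost soft-margin cost parameter C (> 0)
#' @return object of class `kernel_svm` with fields `a` (dense coefficient
#'   vector, one per training example), `b` (bias), `labels`, `cost`
#' @export
train_kernel_svm <- function(gram, labels, cost = 1) {
  gram <- as.matrix(gram)
  n <- nrow(gram)
  stopifnot(n == ncol(gram), length(labels) == n, cost > 0)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) stop("labels must be -1 or +1")
  if (length(unique(labels)) < 2L) {
    stop("training requires both classes to be present")
  }
  y <- factor(labels, levels = c(-1, 1))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(gram), y,
                       type = "C-svc", C = cost)
  svi <- kernlab::alphaindex(fit)[[1]]
  co <- kernlab::coef(fit)[[1]]
  a <- numeric(n)
  a[svi] <- co
  b <- -kernlab::b(fit)
  # normalise sign: kernlab's internal +1 coding depends on factor order;
  # align decision values with the fitted responses
  dec <- as.numeric(gram %*% a + b)
  fitlab <- as.numeric(as.character(kernlab::fitted(fit)))
  nz <- dec != 0
  if (any(nz) && sum(sign(dec[nz]) == fitlab[nz]) < sum(nz) / 2) {
    a <- -a
    b <- -b
  }
  structure(list(a = a, b = b, labels = labels, cost = cost,
                 n_train = n), class = "kernel_svm")
}

#' @export
print.kernel_svm <- function(x, ...) {
  cat(sprintf("Precomputed-kernel SVM: %d training examples, %d SVs, C = %g\n",
              x$n_train, sum(x$a != 0), x$cost))
  invisible(x)
}

#' Discriminant value of a kernel model
#'
#' Evaluates `y(x) = sum_i a_i k_i + b` given the kernel row of a new
#' example against the training examples. The caller classifies by sign
#' (with 0 mapping to the negative class).
#'
#' @param model a `kernel_svm` (or any object with numeric fields `a`, `b`)
#' @param kernel_row numeric vector or matrix: kernel values against the
#'   training examples (rows = new examples when a matrix)
#' @return numeric discriminant value(s)
#' @export
discriminant <- function(model, kernel_row) {
  if (is.matrix(kernel_row)) {
    if (ncol(kernel_row) != length(model$a)) {
      stop("kernel row length does not match number of training examples")
    }
    as.numeric(kernel_row %*% model$a + model$b)
  } else {
    if (length(kernel_row) != length(model$a)) {
      stop("kernel row length does not match number of training examples")
    }
    sum(model$a * kernel_row) + model$b
  }
}
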