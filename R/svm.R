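#' RBF-kernel support vector classifier
#'
#' C-SVC with a Gaussian radial-basis kernel, solved by sequential minimal
#' optimization (maximal-violating-pair working-set selection) on a
#' precomputed kernel matrix. Written for per-subject EEG trial
#' classification (hundreds to a few thousand rows).
#'
#' @param x numeric matrix of predictors (rows = cases).
#' @param y two-level factor (or coercible); the second level is coded +1.
#' @param C regularization parameter (> 0).
#' @param gamma RBF kernel width (> 0); default `1/ncol(x)`.
#' @param tol SMO stopping tolerance on the KKT violation.
#' @param max_iter iteration cap; heavily overlapping classes at large `C`
#'   may stop here with a near-converged boundary (flagged by
#'   `converged = FALSE`), which is accurate enough for cross-validated
#'   prediction while keeping grid searches bounded in time.
#' @return An `rbf_svm` model: support vectors, dual coefficients,
#'   intercept, `levels`, `C`, `gamma`.
#' @export
rbf_svm <- function(x, y, C = 1, gamma = 1 / ncol(x), tol = 1e-3,
                    max_iter = 10000L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("y must have exactly two levels")
  stopifnot(C > 0, gamma > 0, nrow(x) == length(y))
  yy <- ifelse(as.integer(y) == 2L, 1, -1)
  fit <- svm_smo_train(x, yy, C, gamma, tol, as.integer(max_iter))
  sv <- which(fit$alpha > 1e-12)
  structure(list(SV = x[sv, , drop = FALSE],
                 coef = fit$alpha[sv] * yy[sv],
                 b = fit$b, gamma = gamma, C = C,
                 levels = levels(y), iterations = fit$iterations,
                 converged = fit$converged),
            class = "rbf_svm")
}

#' @rdname rbf_svm
#' @param object an `rbf_svm` model.
#' @param newx matrix of cases to classify.
#' @param type `"class"` (factor) or `"decision"` (signed margin).
#' @param ... unused.
#' @export
predict.rbf_svm <- function(object, newx, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  storage.mode(newx) <- "double"
  if (ncol(newx) != ncol(object$SV)) stop("predictor count mismatch")
  d <- svm_rbf_decision(object$SV, object$coef, object$b, object$gamma, newx)
  if (type == "decision") return(d)
  factor(object$levels[ifelse(d >= 0, 2L, 1L)], levels = object$levels)
}
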