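# Maximum-likelihood fitting of the CoDP logistic model.
#
# Newton/IRLS iterations on the binomial log-likelihood; convergence when
# the largest absolute coefficient change drops below 1e-8 (at most 100
# iterations). Complete separation — a direction in feature space along
# which the likelihood is unbounded — is detected and reported as an error
# suggesting the ridge option, which adds a quadratic penalty on the slope
# coefficients (never the intercept).

#' Fit the CoDP logistic model to labeled variants
#'
#' @param features Data frame of predictor columns (by default the five CoDP
#'   features; any numeric columns work). May also contain a `label` column
#'   when `labels` is omitted.
#' @param labels Binary vector (0/1 or logical), 1 = pathogenic. At least
#'   two examples of each class are required.
#' @param ridge Non-negative ridge penalty on the slope coefficients
#'   (default 0 = plain maximum likelihood). A small value (for example
#'   `1e-4`) makes tiny separable datasets fittable.
#' @param feature_names Columns of `features` to use as predictors
#'   (default: the five CoDP feature names, or all numeric columns except
#'   `label` if those are absent).
#' @param max_iter,tol Newton iteration cap (100) and convergence tolerance
#'   on the max absolute coefficient change (1e-8).
#' @return An object of class `c("codp_fit", "codp_model")` with the fitted
#'   intercept and coefficients plus diagnostics: `se` (standard errors),
#'   `vcov`, `logLik`, `deviance`, `iterations`, `converged`, and the
#'   training `data`/`labels`. All `codp_model` methods apply.
#' @examples
#' d <- simulate_variants(n = 200, seed = 1)
#' fit <- codp_fit(d, d$label)
#' coef(fit)
#' @export
codp_fit <- function(features, labels = NULL, ridge = 0,
                     feature_names = NULL, max_iter = 100L, tol = 1e-8) {
  features <- as.data.frame(features)
  if (is.null(labels)) {
    if (!"label" %in% names(features)) {
      stop("codp_invalid_argument: supply `labels` or a `label` column",
           call. = FALSE)
    }
    labels <- features$label
  }
  y <- as.integer(labels)
  if (length(y) != nrow(features)) {
    stop("codp_invalid_argument: features and labels lengths differ",
         call. = FALSE)
  }
  if (any(is.na(y)) || !all(y %in% 0:1)) {
    stop("codp_invalid_argument: labels must be binary 0/1", call. = FALSE)
  }
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("codp_invalid_argument: need at least 2 examples of each class",
         call. = FALSE)
  }
  if (ridge < 0) {
    stop("codp_invalid_argument: ridge must be >= 0", call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- if (all(.CODP_FEATURES %in% names(features))) {
      .CODP_FEATURES
    } else {
      setdiff(names(features)[vapply(features, is.numeric, logical(1))],
              c("label", "q"))
    }
  }
  x <- as.matrix(features[, feature_names, drop = FALSE])
  if (any(!is.finite(x))) {
    stop("codp_invalid_argument: non-finite feature values", call. = FALSE)
  }
  const <- apply(x, 2, function(col) diff(range(col)) == 0)
  if (any(const) && ridge == 0) {
    stop("codp_degenerate_features: constant feature(s) without ridge: ",
         paste(feature_names[const], collapse = ", "), call. = FALSE)
  }

  X <- cbind("(Intercept)" = 1, x)
  k <- ncol(X)
  pen <- c(0, rep(ridge, k - 1L))  # intercept unpenalized
  beta <- numeric(k)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    grad <- drop(crossprod(X, y - p)) - pen * beta
    hess <- crossprod(X, X * w) + diag(pen, k)
    step <- tryCatch(solve(hess, grad), error = function(e) {
      stop("codp_complete_separation: singular information matrix; the ",
           "data may be separable or degenerate - consider `ridge`",
           call. = FALSE)
    })
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  # complete separation: the MLE diverges, fitted probabilities pin to 0/1
  if (ridge == 0) {
    pin <- all(p[y == 1] > 1 - 1e-6) && all(p[y == 0] < 1e-6)
    if (pin || (!converged && max(abs(beta)) > 1e3)) {
      stop("codp_complete_separation: classes are perfectly separable; the ",
           "maximum-likelihood estimates diverge - refit with a small ",
           "`ridge` penalty", call. = FALSE)
    }
  }
  if (!converged) {
    warning("codp_fit did not converge in ", max_iter, " iterations")
  }
  w <- pmax(p * (1 - p), 1e-12)
  hess <- crossprod(X, X * w) + diag(pen, k)
  vc <- solve(hess)
  ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))

  out <- codp_model(intercept = beta[1L],
                    coefficients = stats::setNames(beta[-1L], feature_names))
  out$se <- stats::setNames(sqrt(diag(vc)), colnames(X))
  out$vcov <- vc
  out$logLik <- ll
  out$deviance <- -2 * ll
  out$null_deviance <- {
    p0 <- mean(y)
    -2 * sum(y * log(p0) + (1 - y) * log(1 - p0))
  }
  out$iterations <- iter
  out$converged <- converged
  out$ridge <- ridge
  out$data <- features[, feature_names, drop = FALSE]
  out$labels <- y
  class(out) <- c("codp_fit", "codp_model")
  out
}

#' @export
print.codp_fit <- function(x, digits = 4, ...) {
  cat("CoDP logistic fit (", length(x$labels), " variants, ",
      sum(x$labels), " pathogenic)\n", sep = "")
  print(round(coef(x), digits))
  cat("deviance:", format(x$deviance, digits = digits),
      " iterations:", x$iterations, "\n")
  invisible(x)
}

#' @export
summary.codp_fit <- function(object, ...) {
  est <- coef(object)
  se <- object$se
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, deviance = object$deviance,
              null_deviance = object$null_deviance,
              logLik = object$logLik, n = length(object$labels),
              iterations = object$iterations, ridge = object$ridge)
  class(out) <- "summary.codp_fit"
  out
}

#' @export
print.summary.codp_fit <- function(x, digits = 4, ...) {
  cat("CoDP logistic fit, n =", x$n, "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nnull deviance:", format(x$null_deviance, digits = digits),
      " residual deviance:", format(x$deviance, digits = digits), "\n")
  if (x$ridge > 0) cat("ridge penalty:", x$ridge, "\n")
  invisible(x)
}

#' @export
vcov.codp_fit <- function(object, ...) object$vcov

#' @export
logLik.codp_fit <- function(object, ...) {
  structure(object$logLik, df = length(coef(object)), class = "logLik")
}

#' @export
residuals.codp_fit <- function(object,
                               type = c("deviance", "pearson", "response"),
                               ...) {
  type <- match.arg(type)
  y <- object$labels
  p <- joint_score(object$data, object)
  switch(type,
         response = y - p,
         pearson = (y - p) / sqrt(p * (1 - p)),
         deviance = sign(y - p) *
           sqrt(-2 * (y * log(pmax(p, 1e-300)) +
                        (1 - y) * log(pmax(1 - p, 1e-300)))))
}

#' Box-and-whisker comparison of joint scores by class
#'
#' Plots the distribution of fitted joint scores in the pathogenic and
#' non-pathogenic class side by side (quartile boxes, median line, whiskers
#' to the last point within 1.5 IQR, outliers beyond), the display used to
#' compare how well a score separates the two classes.
#'
#' @param x A `codp_fit`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.codp_fit <- function(x, ...) {
  q <- joint_score(x$data, x)
  graphics::boxplot(q ~ factor(x$labels, levels = c(1, 0),
                               labels = c("pathogenic", "non-pathogenic")),
                    ylab = "joint score q", xlab = "", range = 1.5, ...)
  invisible(x)
}
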