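# The CoDP joint-score model.
#
# A logistic regression over five predictors: logit(q) = Z + sum(b_i X_i)
# with X = (normalized MAPP impact score, SIFT score, PolyPhen-2 HumVar
# score, side-chain heavy-atom change, relative accessibility). The packaged
# default coefficients are the published MSH6 model; q ("joint score") is
# the probability that the variant is pathogenic. Scores of q <= 0.56 are
# called non-pathogenic, 0.56 < q <= 0.65 moderate impact, q > 0.65
# impaired function.

.CODP_FEATURES <- c("mapp_norm", "sift", "pph2_humvar", "delta_heavy",
                    "rel_acc")

#' Construct a CoDP logistic model
#'
#' @param intercept Intercept Z of the logit.
#' @param coefficients Named numeric vector of predictor coefficients. The
#'   default is the packaged CoDP model for MSH6:
#'   Z = -3.7273 and b = (mapp_norm 0.1581, sift -1.2824,
#'   pph2_humvar 4.6733, delta_heavy 1.0475, rel_acc -8.0548).
#' @return An object of class `codp_model`.
#' @examples
#' codp_model()
#' @export
codp_model <- function(intercept = -3.7273,
                       coefficients = c(mapp_norm = 0.1581,
                                        sift = -1.2824,
                                        pph2_humvar = 4.6733,
                                        delta_heavy = 1.0475,
                                        rel_acc = -8.0548)) {
  if (!is.numeric(intercept) || length(intercept) != 1L ||
      !is.finite(intercept)) {
    stop("codp_invalid_model: intercept must be a finite number",
         call. = FALSE)
  }
  if (!is.numeric(coefficients) || is.null(names(coefficients)) ||
      any(!is.finite(coefficients)) || any(names(coefficients) == "")) {
    stop("codp_invalid_model: coefficients must be a named finite numeric ",
         "vector", call. = FALSE)
  }
  structure(list(intercept = unname(intercept), coefficients = coefficients),
            class = "codp_model")
}

#' @export
print.codp_model <- function(x, digits = 4, ...) {
  cat("CoDP logistic model: logit(q) = Z + sum(b_i * X_i)\n")
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
coef.codp_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

.feature_matrix <- function(features, model) {
  nm <- names(model$coefficients)
  if (is.numeric(features) && is.null(dim(features))) {
    if (length(features) != length(nm)) {
      stop("codp_invalid_features: expected ", length(nm), " features (",
           paste(nm, collapse = ", "), ")", call. = FALSE)
    }
    features <- as.data.frame(as.list(stats::setNames(features, nm)))
  }
  features <- as.data.frame(features)
  missing <- setdiff(nm, names(features))
  if (length(missing)) {
    stop("codp_invalid_features: missing feature column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(features[, nm, drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop("codp_invalid_features: features must be finite numbers",
         call. = FALSE)
  }
  if (all(c("sift", "pph2_humvar") %in% nm)) {
    probs <- m[, c("sift", "pph2_humvar"), drop = FALSE]
    if (any(probs < 0 | probs > 1)) {
      stop("codp_invalid_features: sift and pph2_humvar must be in [0, 1]",
           call. = FALSE)
    }
  }
  m
}

#' Evaluate the CoDP joint score
#'
#' Computes q = logistic(Z + sum(b_i X_i)) for one or more feature vectors.
#'
#' @param features A data frame (or named list) with the model's feature
#'   columns, or a single unnamed numeric vector in the model's coefficient
#'   order (`mapp_norm`, `sift`, `pph2_humvar`, `delta_heavy`, `rel_acc`
#'   for the default model).
#' @param model A [codp_model()].
#' @return Numeric vector of joint scores in (0, 1).
#' @examples
#' joint_score(c(0, 0, 0, 0, 0))           # logistic(-3.7273)
#' joint_score(data.frame(mapp_norm = 2, sift = 0, pph2_humvar = 0.99,
#'                        delta_heavy = 3, rel_acc = 0.05))
#' @export
joint_score <- function(features, model = codp_model()) {
  m <- .feature_matrix(features, model)
  eta <- model$intercept + drop(m %*% model$coefficients)
  stats::plogis(eta)
}

#' Classify a joint score into impact categories
#'
#' Partition of the score range at the published cut-offs: q <= `t_low`
#' is non-pathogenic (minor impact), `t_low` < q <= `t_high` moderate
#' impact, q > `t_high` impaired function. The pathogenic flag is
#' q > `t_low`.
#'
#' @param q Joint score(s) in `[0, 1]`. Exact model output lies in the open
#'   interval, but published scores rounded to 0.000 or 1.000 are accepted.
#' @param t_low,t_high Category cut-offs (defaults 0.56 and 0.65). Note that
#'   3-decimal rounding of a published score can flip the `t_high` boundary:
#'   a true q slightly above 0.65 prints as 0.650 yet classifies as moderate
#'   here.
#' @return Data frame with columns `q`, `category` (factor: non_pathogenic,
#'   moderate, impaired) and `pathogenic` (logical).
#' @examples
#' classify_impact(c(0.56, 0.595, 0.832))
#' @export
classify_impact <- function(q, t_low = 0.56, t_high = 0.65) {
  if (!(t_low > 0 && t_low < t_high && t_high < 1)) {
    stop("codp_invalid_argument: need 0 < t_low < t_high < 1", call. = FALSE)
  }
  if (any(!is.finite(q)) || any(q < 0 | q > 1)) {
    stop("codp_invalid_argument: joint scores must lie in [0, 1]",
         call. = FALSE)
  }
  category <- ifelse(q <= t_low, "non_pathogenic",
                     ifelse(q <= t_high, "moderate", "impaired"))
  data.frame(
    q = q,
    category = factor(category,
                      levels = c("non_pathogenic", "moderate", "impaired")),
    pathogenic = q > t_low
  )
}

#' Predict method for CoDP models
#'
#' @param object A `codp_model` (or fitted [codp_fit()] object).
#' @param newdata Feature data frame; for fitted models, defaults to the
#'   training features.
#' @param type `"response"` (joint score q), `"link"` (the logit) or
#'   `"class"` (the full [classify_impact()] table).
#' @param t_low,t_high Cut-offs for `type = "class"`.
#' @param ... Unused.
#' @return Numeric vector, or a data frame for `type = "class"`.
#' @export
predict.codp_model <- function(object, newdata, type = c("response", "link",
                                                         "class"),
                               t_low = 0.56, t_high = 0.65, ...) {
  type <- match.arg(type)
  if (missing(newdata) || is.null(newdata)) {
    if (is.null(object$data)) {
      stop("codp_invalid_argument: newdata is required for an unfitted model",
           call. = FALSE)
    }
    newdata <- object$data
  }
  q <- joint_score(newdata, object)
  switch(type,
         response = q,
         link = stats::qlogis(q),
         class = classify_impact(q, t_low, t_high))
}

#' Simulate pathogenic labels from a CoDP model
#'
#' @param object A `codp_model` or `codp_fit`.
#' @param nsim Number of simulated label vectors.
#' @param seed Integer seed.
#' @param newdata Feature data frame (defaults to training data for fits).
#' @param ... Unused.
#' @return Data frame of `nsim` binary label columns (`sim_1`, ...).
#' @export
simulate.codp_model <- function(object, nsim = 1, seed = NULL,
                                newdata = NULL, ...) {
  q <- predict(object, newdata = newdata, type = "response")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(lapply(seq_len(nsim), function(i) {
    as.integer(stats::runif(length(q)) < q)
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Read / write a CoDP model as JSON
#'
#' Format: `{"intercept": Z, "coefficients": {"mapp_norm": ..., ...}}`.
#' The packaged default model ships under
#' `system.file("extdata", "codp_model.json", package = "codp")`.
#'
#' @param path JSON file path.
#' @return `read_model_json()`: a `codp_model`.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  codp_model(intercept = x$intercept, coefficients = unlist(x$coefficients))
}

#' @rdname read_model_json
#' @param model A `codp_model` to serialize.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = as.list(model$coefficients)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
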