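#' Classifier model specification
#'
#' Uniform description of a classifier: family, hyperparameters, seed, and
#' the methylation scale the features are expected on (beta vs M is itself a
#' hyperparameter of the evaluation protocol).
#'
#' @param family one of `logreg_none`, `logreg_l1`, `logreg_l2`,
#'   `logreg_elasticnet`, `decision_tree`, `random_forest`, `svm_linear`,
#'   `svm_rbf`, `adaboost`, `simple_dnn`, `joint_ae`, `joint_vae`.
#' @param hyper named list of family hyperparameters (e.g. `lambda` for the
#'   penalized regressions, `num_trees`, `epochs`, `lr`, `w`, ...).
#' @param seed integer seed used wherever the family is stochastic.
#' @param scale `"M"` or `"beta"` (recorded; deep models use it to wire the
#'   reconstruction loss).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family, hyper = list(), seed = 1L,
                       scale = c("M", "beta")) {
  families <- c("logreg_none", "logreg_l1", "logreg_l2", "logreg_elasticnet",
                "decision_tree", "random_forest", "svm_linear", "svm_rbf",
                "adaboost", "simple_dnn", "joint_ae", "joint_vae")
  if (!family %in% families)
    stop("unknown family: ", family)
  structure(list(family = family, hyper = hyper, seed = as.integer(seed),
                 scale = match.arg(scale)),
            class = "model_spec")
}

# Discrete AdaBoost (SAMME) over depth-1 rpart stumps.
adaboost_fit <- function(x, y01, n_rounds = 50, seed = 1L) {
  set.seed(seed)
  df <- data.frame(y = factor(y01), x, check.names = FALSE)
  n <- nrow(df)
  wts <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (r in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = wts, method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, minsplit = 2,
                                                       xval = 0))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(wts * (pred != y01)) / sum(wts)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    wts <- wts * exp(alpha * ifelse(pred != y01, 1, -1))
    wts <- wts / sum(wts)
    if (err < 1e-9) break
  }
  list(stumps = stumps, alphas = alphas)
}

adaboost_margin <- function(fit, x) {
  df <- data.frame(x, check.names = FALSE)
  if (length(fit$stumps) == 0) return(rep(0, nrow(df)))
  h <- vapply(fit$stumps, function(s) {
    2 * as.integer(as.character(predict(s, df, type = "class"))) - 1
  }, numeric(nrow(df)))
  if (is.null(dim(h))) h <- matrix(h, nrow = nrow(df))
  as.numeric(h %*% fit$alphas)
}

#' Train a classifier under the uniform contract
#'
#' Dispatches on the model family; every trained model exposes the same
#' scoring interface ([score_samples()], i.e. `predict(..., newdata)`)
#' returning a per-sample case score in \[0, 1\]. Training is seeded and
#' reproducible.
#'
#' @param spec a [model_spec()].
#' @param x samples-by-features numeric matrix (no missing values).
#' @param y labels (`"case"`/`"control"`, factor, or 0/1).
#' @return An object of class `methbench_model`.
#' @export
train_classifier <- function(spec, x, y) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  if (anyNA(x)) stop("features contain NaN/NA")
  y01 <- as01(y)
  if (length(unique(y01)) < 2) stop("both classes must be present")
  h <- spec$hyper
  set.seed(spec$seed)
  fit <- switch(spec$family,
    logreg_none = suppressWarnings(
      stats::glm.fit(cbind(1, x), y01, family = stats::binomial())$coefficients),
    logreg_l1 = glmnet::glmnet(x, y01, family = "binomial", alpha = 1,
                               lambda = h$lambda %||% 0.01),
    logreg_l2 = glmnet::glmnet(x, y01, family = "binomial", alpha = 0,
                               lambda = h$lambda %||% 0.01),
    logreg_elasticnet = glmnet::glmnet(x, y01, family = "binomial",
                                       alpha = h$alpha %||% 0.5,
                                       lambda = h$lambda %||% 0.01),
    decision_tree = rpart::rpart(
      y ~ ., data = data.frame(y = factor(y01), x, check.names = FALSE),
      method = "class"),
    random_forest = ranger::ranger(
      x = x, y = factor(y01), probability = TRUE,
      num.trees = h$num_trees %||% 500, seed = spec$seed, num.threads = 1),
    svm_linear = e1071::svm(x, factor(y01), kernel = "linear",
                            cost = h$cost %||% 1, scale = h$scale %||% TRUE),
    svm_rbf = e1071::svm(x, factor(y01), kernel = "radial",
                         cost = h$cost %||% 1, scale = h$scale %||% TRUE),
    adaboost = adaboost_fit(x, y01, n_rounds = h$n_rounds %||% 50,
                            seed = spec$seed),
    simple_dnn = train_simple_dnn(
      x, y01, hidden = h$hidden %||% c(128, 64),
      epochs = h$epochs %||% 1000, batch_size = h$batch_size %||% 128,
      lr = h$lr %||% 1e-4, dropout = h$dropout %||% 0, l2 = h$l2 %||% 0,
      seed = spec$seed),
    joint_ae = train_joint_ae(
      x, y01, scale = spec$scale, w = h$w %||% 0.5,
      epochs = h$epochs %||% 2000, batch_size = h$batch_size %||% 128,
      lr = h$lr %||% 1e-4, dropout = h$dropout %||% 0, l2 = h$l2 %||% 0,
      seed = spec$seed),
    joint_vae = train_joint_vae(
      x, y01, scale = spec$scale, clf_weight = h$clf_weight %||% 1,
      epochs = h$epochs %||% 2250, batch_size = h$batch_size %||% 128,
      lr = h$lr %||% 1e-4, dropout = h$dropout %||% 0, l2 = h$l2 %||% 0,
      seed = spec$seed))
  structure(list(spec = spec, fit = fit, features = colnames(x)),
            class = "methbench_model")
}

#' Score samples with a trained classifier
#'
#' @param model a `methbench_model` from [train_classifier()].
#' @param x samples-by-features matrix with the training feature columns.
#' @return Per-sample case scores in \[0, 1\] (class probabilities where the
#'   family is probabilistic, a sigmoid-squashed decision value for the
#'   margin-based families).
#' @export
score_samples <- function(model, x) {
  stopifnot(inherits(model, "methbench_model"))
  x <- as.matrix(x)
  if (!is.null(model$features) && !is.null(colnames(x)))
    x <- x[, model$features, drop = FALSE]
  fam <- model$spec$family
  fit <- model$fit
  out <- switch(fam,
    logreg_none = {
      co <- ifelse(is.na(fit), 0, fit)
      stats::plogis(as.numeric(cbind(1, x) %*% co))
    },
    logreg_l1 = ,
    logreg_l2 = ,
    logreg_elasticnet =
      as.numeric(predict(fit, newx = x, type = "response")),
    decision_tree = predict(fit, data.frame(x, check.names = FALSE),
                            type = "prob")[, "1"],
    random_forest = predict(fit, data = x,
                            num.threads = 1)$predictions[, "1"],
    svm_linear = ,
    svm_rbf = {
      dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
      # orient the decision value toward the case class
      sgn <- if (colnames(dv)[1] %in% c("0/1")) -1 else 1
      stats::plogis(sgn * as.numeric(dv))
    },
    adaboost = stats::plogis(adaboost_margin(fit, x)),
    simple_dnn = ,
    joint_ae = ,
    joint_vae = dl_score(fit, x))
  as.numeric(out)
}

#' @export
predict.methbench_model <- function(object, newdata, ...) {
  score_samples(object, newdata)
}

#' @export
print.methbench_model <- function(x, ...) {
  cat("methbench_model [", x$spec$family, "] on ",
      length(x$features %||% NA), " features, scale ", x$spec$scale,
      "\n", sep = "")
  invisible(x)
}

#' Write a model manifest as JSON
#'
#' Records family, hyperparameters, seed, scale, and the feature list so a
#' result can be reproduced end to end.
#'
#' @param model a `methbench_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_manifest <- function(model, path) {
  jsonlite::write_json(list(family = model$spec$family,
                            hyper = model$spec$hyper,
                            seed = model$spec$seed,
                            scale = model$spec$scale,
                            features = model$features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
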