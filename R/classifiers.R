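# The five classifier families behind one fit/predict contract: the ICD-9
# rule baseline (no training), naive Bayes (multinomial on raw counts,
# Gaussian on normalised/negative-valued input), linear-kernel SVM with a
# rank-preserving sigmoid score map, 300-tree random forest, and a shallow
# one-hidden-layer neural network (250 nodes). Scores are always P(SLE) in
# [0, 1]; labels threshold at 0.5.

#' Classifier specification
#'
#' Family plus hyperparameters. Defaults are the tuned study settings:
#' neural net with one hidden layer of 250 nodes, random forest with 300
#' trees, SVM with a linear kernel, ICD-9 rule on code 710.0.
#'
#' @param family One of `"icd9_rule"`, `"naive_bayes"`, `"svm"`,
#'   `"random_forest"`, `"neural_net"`.
#' @param ... Hyperparameter overrides (e.g. `trees = 300`, `nodes = 250`,
#'   `kernel = "linear"`, `code = "710.0"`, `nb_variant = "auto"`,
#'   `decay = 1e-3`, `maxit = 200`).
#' @param seed Integer seed used wherever the family's training is
#'   stochastic.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(family = c("icd9_rule", "naive_bayes", "svm",
                                       "random_forest", "neural_net"),
                            ..., seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    icd9_rule = list(code = "710.0"),
    naive_bayes = list(nb_variant = "auto"),
    svm = list(kernel = "linear", cost = 1),
    random_forest = list(trees = 300L),
    neural_net = list(hidden_layers = 1L, nodes = 250L, decay = 1e-3,
                      maxit = 200L)
  )
  hyper <- utils::modifyList(defaults, list(...))
  structure(list(family = family, hyperparameters = hyper,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, format, character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("<classifier_spec> %s (%s), seed %d\n", x$family, hp, x$seed))
  invisible(x)
}

#' ICD-9 rule classifier for a single patient
#'
#' Stateless rule: score 1 if the SLE billing code (default `"710.0"`) is
#' among the patient's codes, else 0. A hard rule has no graded
#' probability, which is why its accuracy and AUC coincide on balanced
#' data.
#'
#' @param patient A `patient_record` (or any list with `patient_id` and
#'   `icd9_codes`).
#' @param code The SLE ICD-9 code.
#' @return One-row data.frame: `patient_id`, `label`, `score`.
#' @examples
#' p <- list(patient_id = "P1", icd9_codes = c("401.9", "710.0"))
#' icd9_classify(p)
#' @export
icd9_classify <- function(patient, code = "710.0") {
  score <- as.numeric(code %in% patient$icd9_codes)
  data.frame(patient_id = patient$patient_id,
             label = if (score >= 0.5) "SLE" else "CONTROL",
             score = score, stringsAsFactors = FALSE)
}

fm_values <- function(x) {
  if (inherits(x, "feature_matrix")) as.matrix(x$values) else as.matrix(x)
}

# hand-rolled multinomial naive Bayes with Laplace smoothing (no installed
# R package provides the multinomial variant)
fit_multinomial_nb <- function(x, y) {
  classes <- levels(y)
  logprior <- log(table(y) / length(y))
  logcond <- t(vapply(classes, function(cls) {
    counts <- colSums(x[y == cls, , drop = FALSE])
    log((counts + 1) / (sum(counts) + ncol(x)))
  }, numeric(ncol(x))))
  rownames(logcond) <- classes
  list(classes = classes, logprior = as.numeric(logprior[classes]),
       logcond = logcond)
}

predict_multinomial_nb <- function(model, x) {
  logpost <- x %*% t(model$logcond) +
    matrix(model$logprior, nrow(x), length(model$classes), byrow = TRUE)
  z <- logpost - apply(logpost, 1, max)
  p <- exp(z) / rowSums(exp(z))
  colnames(p) <- model$classes
  p
}

#' Fit a classifier
#'
#' Uniform training entry point for the feature-matrix families. The model
#' stores its training feature names and refuses prediction on mismatched
#' feature sets. Training is deterministic given `spec$seed`.
#'
#' @param spec A [classifier_spec()].
#' @param matrix A `feature_matrix` (or plain matrix with dimnames),
#'   normally normalised and feature-selected.
#' @param labels `"SLE"`/`"CONTROL"` labels aligned with the rows.
#' @return A `pheno_classifier` model object.
#' @export
fit_classifier <- function(spec, matrix, labels) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (spec$family == "icd9_rule") {
    out <- structure(list(spec = spec, feature_names = NULL, fit = NULL),
                     class = "pheno_classifier")
    return(out)
  }
  x <- fm_values(matrix)
  if (anyNA(x)) stop("NaN/NA in feature matrix", call. = FALSE)
  y <- as_label_factor(labels)
  if (length(unique(y)) < 2L) {
    stop("labels contain a single class", call. = FALSE)
  }
  if (nrow(x) != length(y)) stop("rows and labels misaligned", call. = FALSE)
  hp <- spec$hyperparameters
  fit <- switch(spec$family,
    naive_bayes = {
      variant <- hp$nb_variant
      if (identical(variant, "auto")) {
        variant <- if (all(x >= 0) && all(x == round(x))) "multinomial" else "gaussian"
      }
      if (variant == "multinomial") {
        list(variant = "multinomial", model = fit_multinomial_nb(x, y))
      } else {
        list(variant = "gaussian",
             model = e1071::naiveBayes(x = x, y = y))
      }
    },
    svm = {
      with_seed(spec$seed,
        e1071::svm(x = x, y = y, kernel = hp$kernel, cost = hp$cost,
                   scale = FALSE, probability = FALSE))
    },
    random_forest = {
      ranger::ranger(x = x, y = y, num.trees = hp$trees,
                     probability = TRUE, seed = spec$seed,
                     num.threads = 1L)
    },
    neural_net = {
      if (!identical(as.integer(hp$hidden_layers), 1L)) {
        stop("the shallow network supports exactly one hidden layer",
             call. = FALSE)
      }
      y01 <- as.numeric(y == "SLE")
      nwts <- (ncol(x) + 1L) * hp$nodes + hp$nodes + 1L
      with_seed(spec$seed,
        nnet::nnet(x = x, y = y01, size = hp$nodes, decay = hp$decay,
                   maxit = hp$maxit, entropy = TRUE, trace = FALSE,
                   MaxNWts = nwts + 1L))
    }
  )
  structure(list(spec = spec, feature_names = colnames(x), fit = fit,
                 classes = levels(y)),
            class = "pheno_classifier")
}

#' @export
print.pheno_classifier <- function(x, ...) {
  cat(sprintf("<pheno_classifier> %s, %s\n", x$spec$family,
              if (is.null(x$feature_names)) "rule-based" else
                sprintf("%d features", length(x$feature_names))))
  invisible(x)
}

check_features <- function(model, x) {
  got <- colnames(x)
  want <- model$feature_names
  if (!identical(got, want)) {
    extra <- setdiff(got, want)
    missing <- setdiff(want, got)
    if (length(extra) || length(missing) || !identical(sort(got), sort(want))) {
      stop("feature mismatch; missing: {",
           paste(utils::head(missing, 5), collapse = ", "),
           "}, unexpected: {", paste(utils::head(extra, 5), collapse = ", "),
           "}", call. = FALSE)
    }
    x <- x[, want, drop = FALSE]  # same set, different order
  }
  x
}

#' Predict with a fitted classifier
#'
#' One prediction per row: `score` is the class-probability estimate of SLE
#' (random-forest vote fraction, naive-Bayes posterior, SVM decision value
#' through a rank-preserving sigmoid, network output activation) and
#' `label` thresholds the score at 0.5. For the ICD-9 rule pass a list of
#' `patient_record`s instead of a matrix.
#'
#' @param object A `pheno_classifier`.
#' @param newdata `feature_matrix`/matrix with the training features, or —
#'   for `icd9_rule` — a list of patient records.
#' @param ... Unused.
#' @return data.frame with `patient_id`, `label`, `score`.
#' @export
predict.pheno_classifier <- function(object, newdata, ...) {
  if (object$spec$family == "icd9_rule") {
    recs <- if (inherits(newdata, "pheno_cohort")) newdata$patients else newdata
    out <- lapply(recs, icd9_classify,
                  code = object$spec$hyperparameters$code)
    return(do.call(rbind, out))
  }
  x <- fm_values(newdata)
  x <- check_features(object, x)
  score <- switch(object$spec$family,
    naive_bayes = {
      if (object$fit$variant == "multinomial") {
        predict_multinomial_nb(object$fit$model, x)[, "SLE"]
      } else {
        stats::predict(object$fit$model, x, type = "raw")[, "SLE"]
      }
    },
    svm = {
      pr <- stats::predict(object$fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # column name "A/B": positive values favour class A
      pair <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]]
      d <- if (pair[1L] == "SLE") dv[, 1L] else -dv[, 1L]
      stats::plogis(d)
    },
    random_forest = {
      stats::predict(object$fit, data = x,
                     num.threads = 1L)$predictions[, "SLE"]
    },
    neural_net = {
      as.numeric(stats::predict(object$fit, x))
    }
  )
  score <- pmin(pmax(as.numeric(score), 0), 1)
  data.frame(patient_id = rownames(x),
             label = ifelse(score >= 0.5, "SLE", "CONTROL"),
             score = score, stringsAsFactors = FALSE)
}
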