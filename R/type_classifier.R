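# Multiclass temporal-type prediction from feature vectors.
#
# The default algorithm composes a seeded Gaussian random projection with a
# 1-nearest-neighbour classifier (Euclidean distance, ties broken by smallest
# training index). Plain KNN and multinomial logistic regression are
# registered as alternatives. Everything is bit-reproducible given
# (data, config, seed).

#' Classifier configuration
#'
#' @param algorithm one of `"knn_projected"` (default), `"knn"`, `"logistic"`.
#' @param k neighbour count for the KNN family.
#' @param projection_dim target dimensionality of the random projection; when
#'   it is at least the number of observed features the projection reduces to
#'   the identity.
#' @param seed integer seed for the projection matrix.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(algorithm = c("knn_projected", "knn", "logistic"),
                              k = 1L, projection_dim = 32L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(k >= 1, projection_dim >= 1)
  structure(list(algorithm = algorithm, k = as.integer(k),
                 projection_dim = as.integer(projection_dim),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# Sparse feature vector -> named numeric encoding.
encode_features <- function(v) {
  out <- c(
    if (length(v$pos_bag)) stats::setNames(as.numeric(v$pos_bag),
                                           paste0("POS:", names(v$pos_bag))),
    if (length(v$trigger_ids)) stats::setNames(rep(1, length(v$trigger_ids)),
                                               paste0("TRG:", v$trigger_ids)),
    if (length(v$trigger_positions)) stats::setNames(
      as.numeric(v$trigger_positions),
      paste0("TRGPOS:", names(v$trigger_positions))),
    IND = as.numeric(v$time_indicator)
  )
  out
}

vectors_to_matrix <- function(vectors, feature_names = NULL) {
  enc <- lapply(vectors, encode_features)
  if (is.null(feature_names)) {
    feature_names <- sort(unique(unlist(lapply(enc, names))))
  }
  X <- matrix(0, nrow = length(vectors), ncol = length(feature_names),
              dimnames = list(NULL, feature_names))
  for (i in seq_along(enc)) {
    known <- intersect(names(enc[[i]]), feature_names)  # unseen features ignored
    X[i, known] <- enc[[i]][known]
  }
  X
}

#' Fit a temporal-type classifier
#'
#' @param vectors list of labelled `feature_vector`s (labels among DATE, TIME,
#'   DURATION, SET).
#' @param cfg a [classifier_config()].
#' @return a `type_model`.
#' @export
fit_type_classifier <- function(vectors, cfg = classifier_config()) {
  if (length(vectors) == 0) stop("fit_type_classifier: empty training set")
  labels <- vapply(vectors, `[[`, character(1), "label")
  if (anyNA(labels)) stop("fit_type_classifier: all vectors must be labelled")
  bad <- setdiff(unique(labels), TIMEX_TYPES)
  if (length(bad)) stop(sprintf("fit_type_classifier: unknown label '%s'", bad[1]))
  X <- vectors_to_matrix(vectors)
  proj <- NULL
  Xp <- X
  if (cfg$algorithm == "knn_projected" && cfg$projection_dim < ncol(X)) {
    proj <- with_local_seed(cfg$seed, matrix(
      stats::rnorm(ncol(X) * cfg$projection_dim, sd = 1 / sqrt(cfg$projection_dim)),
      nrow = ncol(X), ncol = cfg$projection_dim))
    Xp <- X %*% proj
  }
  fit <- NULL
  if (cfg$algorithm == "logistic") {
    df <- data.frame(label = factor(labels, levels = TIMEX_TYPES), Xp,
                     check.names = FALSE)
    utils::capture.output(fit <- nnet::multinom(label ~ ., data = df, maxit = 200,
                                         MaxNWts = 10000, trace = FALSE))
  }
  structure(list(feature_names = colnames(X), proj = proj, X = Xp,
                 labels = labels, cfg = cfg, fit = fit),
            class = "type_model")
}

#' Predict temporal types
#'
#' KNN ties are broken by the smallest training index; features unseen during
#' training are ignored.
#'
#' @param model a fitted `type_model`.
#' @param vectors list of `feature_vector`s.
#' @return character vector of labels (DATE/TIME/DURATION/SET).
#' @export
predict_types <- function(model, vectors) {
  stopifnot(inherits(model, "type_model"))
  if (length(vectors) == 0) return(character(0))
  P <- vectors_to_matrix(vectors, model$feature_names)
  if (!is.null(model$proj)) P <- P %*% model$proj
  if (model$cfg$algorithm == "logistic") {
    df <- data.frame(P, check.names = FALSE)
    return(as.character(stats::predict(model$fit, newdata = df)))
  }
  # Euclidean KNN: D^2 = |p|^2 + |x|^2 - 2 p.x
  d2 <- outer(rowSums(P^2), rowSums(model$X^2), "+") - 2 * P %*% t(model$X)
  k <- model$cfg$k
  vapply(seq_len(nrow(P)), function(i) {
    ord <- order(d2[i, ], seq_len(ncol(d2)))  # tie -> smallest training index
    nn <- model$labels[ord[seq_len(min(k, length(ord)))]]
    tab <- table(factor(nn, levels = unique(nn)))  # vote ties -> nearest first
    names(tab)[which.max(tab)]
  }, character(1))
}

#' Cross-validated evaluation of a classifier configuration
#'
#' Seeded shuffling into `folds` folds; out-of-fold predictions are pooled and
#' scored with the macro-averaged metrics.
#'
#' @param vectors labelled `feature_vector`s.
#' @param cfg a [classifier_config()].
#' @param folds number of folds (default 10).
#' @param seed shuffle seed.
#' @return the [macro_metrics()] report of the pooled predictions.
#' @export
cross_validate_types <- function(vectors, cfg = classifier_config(),
                                 folds = 10L, seed = 1L) {
  n <- length(vectors)
  if (folds > n) stop("cross_validate_types: more folds than vectors")
  idx <- with_local_seed(seed, sample.int(n))
  fold_of <- rep(seq_len(folds), length.out = n)[order(idx)]
  gold <- vapply(vectors, `[[`, character(1), "label")
  pred <- character(n)
  for (f in seq_len(folds)) {
    test <- which(fold_of == f)
    model <- fit_type_classifier(vectors[-test], cfg)
    pred[test] <- predict_types(model, vectors[test])
  }
  macro_metrics(gold, pred)
}

#' Persist / restore a trained model as a JSON bundle
#'
#' The bundle embeds the config and seed, so KNN-family models reload
#' bit-for-bit. (Logistic models are refittable from data + config instead.)
#'
#' @param model a `type_model` (KNN family).
#' @param path file path.
#' @return `load_model` returns the `type_model`.
#' @export
save_model <- function(model, path) {
  if (model$cfg$algorithm == "logistic") {
    stop("save_model: only KNN-family models serialize to JSON; refit logistic models from data")
  }
  bundle <- list(feature_names = model$feature_names,
                 proj = model$proj, X = model$X, labels = model$labels,
                 cfg = unclass(model$cfg))
  jsonlite::write_json(bundle, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  b <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  cfg <- do.call(classifier_config, b$cfg)
  proj <- if (is.null(b$proj)) NULL else as.matrix(b$proj)
  structure(list(feature_names = b$feature_names, proj = proj,
                 X = as.matrix(b$X), labels = b$labels, cfg = cfg, fit = NULL),
            class = "type_model")
}
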