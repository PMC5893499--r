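#' Fit a probabilistic neural network
#'
#' A probabilistic neural network (PNN) is a non-iterative Parzen-window
#' classifier with four layers: an input layer of `P` neurons (weights
#' identically 1), a pattern layer holding one Gaussian kernel per stored
#' training example, a summation layer averaging kernel activations within
#' each class, and an output layer taking the argmax. "Training" is
#' pattern storage; there is no optimization.
#'
#' Features are standardized per dimension (z-score with training mean and
#' standard deviation) before kernel evaluation, because GLCM features
#' span orders of magnitude and unstandardized kernels would be dominated
#' by a single dimension. A zero-variance dimension gets scale 1 with a
#' warning.
#'
#' @param x Numeric matrix or data frame of feature vectors, one row per
#'   training example.
#' @param labels Class labels (character or factor), one per row of `x`.
#' @param sigma Positive kernel smoothing width on the standardized scale
#'   (default 0.5). See [pnn_tune_sigma()] for a leave-one-out grid search.
#' @param classes Optional explicit class order (controls tie-breaking:
#'   exact score ties go to the earliest class). Defaults to order of
#'   first appearance in `labels` (or factor levels).
#' @return An object of class `pnn` with stored standardized patterns,
#'   labels, `sigma`, class order, and standardization parameters.
#' @seealso [predict.pnn()], [pnn_accuracy()], [write_pnn()]
#' @examples
#' fit <- pnn(rbind(c(0, 0), c(0.1, 0), c(3, 3)),
#'            c("normal", "normal", "abnormal"), sigma = 0.5)
#' predict(fit, c(2.5, 2.9))
#' @export
pnn <- function(x, labels, sigma = 0.5, classes = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x))
    abort_validation("x must be a numeric matrix without NA")
  if (length(labels) != nrow(x))
    abort_validation("labels length (", length(labels),
                     ") must equal number of rows in x (", nrow(x), ")")
  if (!is_scalar_number(sigma) || sigma <= 0)
    abort_validation("sigma must be a positive number")
  if (is.null(classes)) {
    classes <- if (is.factor(labels)) levels(labels)
               else unique(as.character(labels))
  }
  labels <- as.character(labels)
  classes <- as.character(classes)
  counts <- table(factor(labels, levels = classes))
  if (any(counts == 0L))
    abort_validation("class(es) with zero training examples: ",
                     paste(names(counts)[counts == 0L], collapse = ", "))
  if (any(!labels %in% classes))
    abort_validation("labels outside declared classes")

  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  if (nrow(x) == 1L) scale[] <- 0
  zero_sd <- !is.finite(scale) | scale == 0
  if (any(zero_sd)) {
    warning(sum(zero_sd), " zero-variance feature dimension(s); ",
            "scale set to 1", call. = FALSE)
    scale[zero_sd] <- 1
  }
  patt <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")

  structure(list(patterns = patt, labels = labels, classes = classes,
                 sigma = sigma, center = center, scale = scale,
                 input_dim = ncol(x)),
            class = "pnn")
}

#' @export
print.pnn <- function(x, ...) {
  cat(sprintf("Probabilistic neural network (Parzen-window classifier)\n"))
  cat(sprintf("  %d stored patterns, %d input features, sigma = %g\n",
              nrow(x$patterns), x$input_dim, x$sigma))
  tab <- table(factor(x$labels, levels = x$classes))
  cat("  classes:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pnn <- function(object, ...) {
  print(object)
  res <- pnn_accuracy(object,
                      sweep(sweep(object$patterns, 2L, object$scale, "*"),
                            2L, object$center, "+"),
                      object$labels)
  cat(sprintf("  resubstitution accuracy: %.1f%% (optimistic)\n", res))
  invisible(object)
}

# per-class mean kernel activations; `shifted = TRUE` evaluates in
# log-shifted space (stable at tiny sigma, same argmax ordering)
pnn_scores_one <- function(model, z, shifted = FALSE) {
  d2 <- rowSums(sweep(model$patterns, 2L, z, "-")^2)
  e <- -d2 / (2 * model$sigma^2)
  k <- if (shifted) exp(e - max(e)) else exp(e)
  vapply(model$classes,
         function(cl) mean(k[model$labels == cl]), numeric(1))
}

#' Classify a feature vector with a fitted PNN
#'
#' Standardizes `x` with the model's training parameters, evaluates the
#' Gaussian kernel `exp(-||x - p_i||^2 / (2 sigma^2))` at every stored
#' pattern, averages activations within each class, and returns the
#' argmax class. Exact score ties are broken in favor of the earliest
#' class in the model's class order. The decision is computed in shifted
#' log-kernel space so it remains well defined when raw kernels underflow
#' at very small `sigma`; the reported `scores` are the raw activations.
#'
#' @param model A fitted [pnn()] model.
#' @param x Numeric feature vector of length `model$input_dim`.
#' @return A `pnn_classification`: `label`, named `scores`, and a named
#'   0/1 `decision` vector with exactly one 1.
#' @export
classify <- function(model, x) {
  if (!inherits(model, "pnn")) abort_validation("model must be a pnn")
  x <- as.numeric(x)
  if (length(x) != model$input_dim)
    abort_validation("feature vector has length ", length(x),
                     ", model expects ", model$input_dim)
  z <- (x - model$center) / model$scale
  raw <- pnn_scores_one(model, z, shifted = FALSE)
  dec_scores <- pnn_scores_one(model, z, shifted = TRUE)
  # scores within a relative 1e-9 of the maximum count as tied, so the
  # earliest class wins both exact ties and ties up to rounding noise
  # (e.g. the equal-score limit at very large sigma)
  best <- which(dec_scores >= max(dec_scores) * (1 - 1e-9))[1L]
  decision <- as.integer(seq_along(model$classes) == best)
  names(decision) <- model$classes
  structure(list(label = model$classes[best], scores = raw,
                 decision = decision),
            class = "pnn_classification")
}

#' @export
print.pnn_classification <- function(x, ...) {
  cat(sprintf("<pnn_classification> label: %s\n", x$label))
  cat("  scores:",
      paste(sprintf("%s=%.4g", names(x$scores), x$scores),
            collapse = ", "), "\n")
  invisible(x)
}

#' Predict method for PNN models
#'
#' @param object A fitted [pnn()] model.
#' @param newdata Numeric matrix (one row per case) or a single feature
#'   vector.
#' @param type `"class"` (default) for predicted labels, `"scores"` for
#'   the per-class mean kernel activations.
#' @param ... Unused.
#' @return Character vector of labels, or a matrix of scores with one row
#'   per case.
#' @export
predict.pnn <- function(object, newdata,
                        type = c("class", "scores"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  res <- lapply(seq_len(nrow(newdata)),
                function(i) classify(object, newdata[i, ]))
  if (type == "class") {
    vapply(res, `[[`, character(1), "label")
  } else {
    out <- t(vapply(res, `[[`, numeric(length(object$classes)), "scores"))
    colnames(out) <- object$classes
    out
  }
}

#' Classification accuracy (percent)
#'
#' `100 * correct / total` over a labeled evaluation set.
#'
#' @param model A fitted [pnn()] model.
#' @param x Feature matrix, one row per case.
#' @param labels True labels.
#' @return Accuracy in percent.
#' @export
pnn_accuracy <- function(model, x, labels) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) abort_validation("empty evaluation set")
  if (length(labels) != nrow(x))
    abort_validation("labels length must match rows of x")
  pred <- predict(model, x)
  100 * mean(pred == as.character(labels))
}

#' Leave-one-out grid search for the kernel width
#'
#' Evaluates leave-one-out accuracy over a sigma grid (default 20 points,
#' log-spaced over `[1e-2, 10]`) and returns the grid with the best value
#' (ties to the smallest sigma).
#'
#' @inheritParams pnn
#' @param sigmas Candidate widths.
#' @return List with `best` (sigma) and `grid` (data frame of sigma and
#'   LOO accuracy).
#' @export
pnn_tune_sigma <- function(x, labels,
                           sigmas = 10^seq(-2, 1, length.out = 20),
                           classes = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  if (n < 3L) abort_validation("need at least 3 examples for tuning")
  acc <- vapply(sigmas, function(s) {
    correct <- 0L
    for (i in seq_len(n)) {
      fit <- suppressWarnings(
        pnn(x[-i, , drop = FALSE], labels[-i], sigma = s,
            classes = classes))
      if (predict(fit, x[i, ]) == labels[i]) correct <- correct + 1L
    }
    100 * correct / n
  }, numeric(1))
  list(best = sigmas[which.max(acc)],
       grid = data.frame(sigma = sigmas, loo_accuracy = acc))
}

#' Serialize / restore a PNN model
#'
#' The model (patterns, labels, class order, sigma, standardization
#' parameters) is written as versioned JSON, portable across platforms.
#'
#' @param model A fitted [pnn()] model.
#' @param path Output (input) file path.
#' @return `path` invisibly; `read_pnn()` returns the restored model.
#' @export
write_pnn <- function(model, path) {
  if (!inherits(model, "pnn")) abort_validation("model must be a pnn")
  payload <- list(
    format = "glioscan-pnn", version = 1L,
    sigma = model$sigma, classes = model$classes,
    labels = model$labels, center = as.numeric(model$center),
    scale = as.numeric(model$scale), input_dim = model$input_dim,
    feature_names = colnames(model$patterns),
    patterns = unname(apply(model$patterns, 1L, as.numeric,
                            simplify = FALSE)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pnn
#' @export
read_pnn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "glioscan-pnn"))
    abort_io("not a glioscan PNN model file: ", path)
  patt <- if (is.matrix(p$patterns)) p$patterns
          else do.call(rbind, lapply(p$patterns, as.numeric))
  if (length(p$feature_names) == ncol(patt))
    colnames(patt) <- p$feature_names
  structure(list(patterns = patt, labels = p$labels, classes = p$classes,
                 sigma = p$sigma, center = p$center, scale = p$scale,
                 input_dim = as.integer(p$input_dim)),
            class = "pnn")
}
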