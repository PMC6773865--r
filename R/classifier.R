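#' Train the candidate-event classifier
#'
#' Fits a soft-margin support vector machine on flattened candidate
#' patch stacks (15 x 15 x 11 = 2475 pixel values per candidate),
#' z-scored per feature with statistics taken from the training set and
#' stored with the model so classification is deterministic. The output
#' is binary: accepted (bona fide scission event) or rejected (false
#' positive). Candidate sets are typically ~80% positive, so classes are
#' weighted inversely to their frequency by default.
#'
#' @param patches list of `patch_stack` objects or a numeric matrix
#'   (one row per candidate, 2475 columns).
#' @param labels logical (TRUE = accepted) or a factor/character vector
#'   with levels `accepted`/`rejected`; both classes must be present.
#' @param kernel SVM kernel, `"radial"` (default) or `"linear"`.
#' @param cost soft-margin constant C (default 1).
#' @param gamma RBF width (default `1/n_features`).
#' @param class_weights `"balanced"` (default), `NULL`, or a named
#'   vector.
#' @param seed RNG seed (stored in the metadata; the libsvm fit itself
#'   is deterministic).
#' @return a `pph_classifier` with the fitted SVM, the normalization
#'   statistics and training metadata (including training accuracy).
#' @export
train_event_classifier <- function(patches, labels, kernel = c("radial", "linear"),
                                   cost = 1, gamma = NULL,
                                   class_weights = "balanced", seed = 1) {
  kernel <- match.arg(kernel)
  X <- patch_matrix(patches)
  y <- as_accept_factor(labels, nrow(X))
  if (nlevels(droplevels(y)) < 2L)
    stop("training labels must contain both classes")
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  cw <- class_weights
  if (identical(class_weights, "balanced")) {
    tab <- table(y)
    cw <- as.numeric(length(y) / (length(tab) * tab))
    names(cw) <- names(tab)
  }
  fit <- with_seed(seed,
    e1071::svm(Xs, y, kernel = kernel, cost = cost, gamma = gamma,
               class.weights = cw, scale = FALSE))
  pred <- stats::predict(fit, Xs)
  structure(list(svm = fit, center = center, scale = scale_,
                 kernel = kernel, cost = cost, gamma = gamma,
                 meta = list(n_candidates = nrow(X),
                             n_accepted = sum(y == "accepted"),
                             training_accuracy = mean(pred == y),
                             seed = seed)),
            class = "pph_classifier")
}

#' @export
print.pph_classifier <- function(x, ...) {
  cat(sprintf("<pph_classifier> %s SVM, C = %g, gamma = %g\n",
              x$kernel, x$cost, x$gamma))
  cat(sprintf("  trained on %d candidates (%d accepted), training accuracy %.1f%%\n",
              x$meta$n_candidates, x$meta$n_accepted,
              100 * x$meta$training_accuracy))
  invisible(x)
}

#' Classify candidate events
#'
#' @param model a `pph_classifier`.
#' @param patches list of `patch_stack`s or a matrix with the feature
#'   length the model was trained on.
#' @return factor of labels (`accepted`/`rejected`), empty for empty
#'   input; a pure function of (model, patches).
#' @export
classify_events <- function(model, patches) {
  X <- patch_matrix(patches)
  if (nrow(X) == 0L)
    return(factor(character(0), levels = c("accepted", "rejected")))
  if (ncol(X) != length(model$center))
    stop(sprintf("patches have %d features, model expects %d",
                 ncol(X), length(model$center)))
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  stats::predict(model$svm, Xs)
}

patch_matrix <- function(patches) {
  if (is.matrix(patches)) return(patches)
  if (inherits(patches, "patch_stack")) patches <- list(patches)
  if (length(patches) == 0L) return(matrix(numeric(0), 0, 0))
  do.call(rbind, lapply(patches, function(p) as.vector(p)))
}

as_accept_factor <- function(labels, n) {
  if (is.logical(labels))
    labels <- ifelse(labels, "accepted", "rejected")
  y <- factor(as.character(labels), levels = c("accepted", "rejected"))
  if (anyNA(y) || length(y) != n)
    stop("labels must be logical or accepted/rejected, one per candidate")
  y
}

#' Save / load a trained classifier
#'
#' The model is persisted with `saveRDS` next to a JSON sidecar holding
#' the training metadata.
#'
#' @param model a `pph_classifier`.
#' @param path output `.rds` path; the sidecar is `path` + `.json`.
#' @return `path` (for save) or the model (for load).
#' @export
save_classifier <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(model$meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) readRDS(path)

#' Model-vs-user agreement report
#'
#' Compares the classifier's accepted set with the user's over the same
#' candidates, in exact integer arithmetic: `sorted_fraction` is the
#' number of model-accepted events as a percentage of user-accepted
#' events; `overlap_fraction` the percentage of model-accepted events
#' also accepted by the user; `candidate_false_positive_rate` the
#' percentage of candidates the user rejected.
#'
#' @param model_labels,user_labels logical vectors (TRUE = accepted) or
#'   `accepted`/`rejected` factors over the same candidates; if named,
#'   the names (candidate ids) must match.
#' @return an `agreement_report` list of the counts and percentages.
#' @export
agreement_report <- function(model_labels, user_labels) {
  if (length(model_labels) != length(user_labels))
    stop("label vectors must cover the same candidates")
  if (!is.null(names(model_labels)) && !is.null(names(user_labels)) &&
      !identical(names(model_labels), names(user_labels)))
    stop("candidate ids of model and user labels do not match")
  m <- as_accept_factor(model_labels, length(model_labels)) == "accepted"
  u <- as_accept_factor(user_labels, length(user_labels)) == "accepted"
  n <- length(m)
  nm <- sum(m); nu <- sum(u)
  structure(list(
    n_candidates = n,
    n_user_accepted = nu,
    n_model_accepted = nm,
    sorted_fraction = if (nu > 0) 100 * nm / nu else NA_real_,
    overlap_fraction = if (nm > 0) 100 * sum(m & u) / nm else NA_real_,
    candidate_false_positive_rate = if (n > 0) 100 * (n - nu) / n else NA_real_),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d candidates; user accepted %d, model %d\n",
              x$n_candidates, x$n_user_accepted, x$n_model_accepted))
  cat(sprintf("  sorted: %.1f%% of user-accepted; overlap: %.1f%%; candidate FP rate: %.1f%%\n",
              x$sorted_fraction, x$overlap_fraction,
              x$candidate_false_positive_rate))
  invisible(x)
}
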