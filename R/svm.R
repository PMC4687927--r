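#' Per-class soft-margin constants for imbalanced data
#'
#' With more non-transmembrane than transmembrane training segments, a
#' single soft margin favours the majority class. The misclassification
#' penalty of each class is made inversely proportional to its sample
#' size: the tm class keeps the tuned constant C, the ntm class gets
#' C * n_tm / n_ntm.
#'
#' @param C Tuned soft-margin constant.
#' @param n_tm,n_ntm Class sample counts.
#' @return Named numeric c(C_tm, C_ntm).
#' @export
class_weights <- function(C, n_tm, n_ntm) {
  stopifnot(C > 0)
  if (n_tm <= 0 || n_ntm <= 0) stop("class counts must be positive", call. = FALSE)
  c(C_tm = C, C_ntm = C * n_tm / n_ntm)
}

# Stratified, seeded fold assignment: each class is shuffled and dealt
# round-robin so every fold holds both classes.
.stratified_folds <- function(y, folds, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

# Mean CV accuracy of an RBF (or linear) SVM at one (C, gamma).
.cv_accuracy <- function(x, y, C, gamma, fold, kernel = "radial",
                         weighted = TRUE) {
  folds <- max(fold)
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    cw <- if (weighted) .e1071_weights(y[tr]) else NULL
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = kernel,
                      cost = C, gamma = gamma, scale = FALSE,
                      class.weights = cw)
    p <- predict(fit, x[!tr, , drop = FALSE])
    correct <- correct + sum(p == y[!tr])
  }
  correct / length(y)
}

# e1071 multiplies `cost` by class.weights[class]; the inverse-ratio rule
# keeps the minority (tm) class at weight 1.
.e1071_weights <- function(y) {
  n <- table(y)
  if (length(n) < 2L) return(NULL)
  w <- c(tm = 1, ntm = as.numeric(n["tm"] / n["ntm"]))
  w[levels(y)]
}

#' Two-level grid search for the RBF soft margin and kernel width
#'
#' Level 1 scans (C, gamma) over powers of two; level 2 refines around the
#' level-1 optimum on a 2^(1/4)-step grid. Model selection maximizes mean
#' stratified k-fold cross-validation accuracy; ties break toward smaller C,
#' then smaller gamma. Class weighting (inverse class-size ratio) is applied
#' inside every fold.
#'
#' @param x Descriptor matrix (rows = segments, 400 columns).
#' @param y Factor or character labels ("tm"/"ntm").
#' @param folds Number of CV folds (default 10).
#' @param log2C,log2gamma Level-1 grids as log2 exponents (LIBSVM-guide
#'   defaults: C in 2^-5..2^15 step 2^2, gamma in 2^-15..2^3 step 2^2).
#' @param refine_radius Level-2 half-width in log2 units around the level-1
#'   optimum (default 1), scanned at step 0.25.
#' @param kernel "radial" or "linear" (gamma ignored for linear).
#' @param weighted Apply inverse-ratio class weights during CV.
#' @param seed Fold-assignment seed.
#' @return List: C, gamma, cv_accuracy (fraction), and the full `grid`
#'   data.frame of evaluated points.
#' @export
grid_search <- function(x, y, folds = 10L,
                        log2C = seq(-5, 15, by = 2),
                        log2gamma = seq(-15, 3, by = 2),
                        refine_radius = 1, kernel = "radial",
                        weighted = TRUE, seed = 1L) {
  y <- factor(as.character(y), levels = c("tm", "ntm"))
  if (nlevels(droplevels(y)) < 2L) {
    stop("grid search needs both classes in the training set", call. = FALSE)
  }
  if (min(table(y)) < folds) {
    stop(sprintf("folds (%d) exceed the minority-class count (%d)",
                 folds, min(table(y))), call. = FALSE)
  }
  fold <- .stratified_folds(y, folds, seed)

  eval_grid <- function(l2C, l2g) {
    pts <- expand.grid(log2C = l2C, log2gamma = l2g)
    pts$accuracy <- mapply(function(a, b) {
      .cv_accuracy(x, y, 2^a, 2^b, fold, kernel = kernel, weighted = weighted)
    }, pts$log2C, pts$log2gamma)
    pts
  }
  if (kernel == "linear") log2gamma <- 0

  g1 <- eval_grid(log2C, log2gamma)
  best <- g1[order(-g1$accuracy, g1$log2C, g1$log2gamma)[1], ]
  g2 <- NULL
  if (refine_radius > 0) {
    l2C <- seq(best$log2C - refine_radius, best$log2C + refine_radius,
               by = 0.25)
    l2g <- if (kernel == "linear") 0 else
      seq(best$log2gamma - refine_radius, best$log2gamma + refine_radius,
          by = 0.25)
    g2 <- eval_grid(l2C, l2g)
    all <- rbind(g1, g2)
    best <- all[order(-all$accuracy, all$log2C, all$log2gamma)[1], ]
  }
  list(C = 2^best$log2C, gamma = 2^best$log2gamma,
       cv_accuracy = best$accuracy, grid = rbind(g1, g2))
}

#' Train the tm/ntm segment classifier
#'
#' Fits a class-weighted RBF-kernel support vector machine (LIBSVM via
#' e1071) on 400-dimensional pair-frequency descriptors. Descriptors are
#' used unscaled: they are small sparse counts on a common scale.
#'
#' @param x Descriptor matrix (400 columns).
#' @param y Labels ("tm"/"ntm").
#' @param C Soft-margin constant (for the tm class).
#' @param gamma RBF kernel width.
#' @param weighted Apply the inverse-ratio class weights of
#'   [class_weights()].
#' @param kernel "radial" (default) or "linear".
#' @return A `btm_classifier`: the fit plus its config, the per-class soft
#'   margins actually used, a training-set fingerprint, the encoding
#'   version tag, and the training-set recall (self-consistency).
#' @export
train_svm <- function(x, y, C, gamma, weighted = TRUE, kernel = "radial") {
  y <- factor(as.character(y), levels = c("tm", "ntm"))
  if (nlevels(droplevels(y)) < 2L) stop("need both classes to train", call. = FALSE)
  if (ncol(x) != 400L) {
    stop("descriptor matrix must have 400 columns, got ", ncol(x), call. = FALSE)
  }
  cw <- if (weighted) .e1071_weights(y) else NULL
  fit <- e1071::svm(x, y, kernel = kernel, cost = C, gamma = gamma,
                    scale = FALSE, class.weights = cw)
  n <- table(y)
  margins <- if (weighted) class_weights(C, n[["tm"]], n[["ntm"]]) else
    c(C_tm = C, C_ntm = C)
  self <- mean(predict(fit, x) == y)
  structure(list(
    fit = fit,
    config = list(C = C, gamma = gamma, kernel = kernel, weighted = weighted,
                  C_tm = unname(margins["C_tm"]),
                  C_ntm = unname(margins["C_ntm"])),
    n_train = length(y), class_counts = as.list(n),
    fingerprint = sprintf("n=%d;sum=%d;labsum=%d", length(y), sum(x),
                          sum(y == "tm")),
    encoding_version = ENCODING_VERSION,
    self_consistency = self), class = "btm_classifier")
}

#' @export
print.btm_classifier <- function(x, ...) {
  cat(sprintf(
    "<btm_classifier> %s kernel, C=%.4g gamma=%.4g (C_tm=%.4g, C_ntm=%.4g)\n",
    x$config$kernel, x$config$C, x$config$gamma, x$config$C_tm,
    x$config$C_ntm))
  cat(sprintf("  trained on %d segments (tm=%d, ntm=%d); self-consistency %.2f%%\n",
              x$n_train, x$class_counts$tm, x$class_counts$ntm,
              100 * x$self_consistency))
  invisible(x)
}

#' Classify segment descriptors as tm or ntm
#'
#' @param model A `btm_classifier`.
#' @param descriptors Matrix with 400 columns (or a single named vector).
#' @return Character vector of "tm"/"ntm", one per row, order preserved.
#' @export
predict_segments <- function(model, descriptors) {
  stopifnot(inherits(model, "btm_classifier"))
  if (is.null(dim(descriptors))) descriptors <- matrix(descriptors, nrow = 1L)
  if (nrow(descriptors) == 0L) return(character(0))
  if (ncol(descriptors) != 400L) {
    stop("descriptors must have 400 columns, got ", ncol(descriptors),
         call. = FALSE)
  }
  as.character(predict(model$fit, descriptors))
}

#' Persist / restore a trained classifier
#'
#' The model file embeds the SVM config, class order and encoding version
#' tag; [load_model()] refuses files whose descriptor layout differs from
#' the running package.
#'
#' @param model A `btm_classifier`.
#' @param path Destination file.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "btm_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "btm_classifier")) {
    stop("not a barreltm classifier file: ", path, call. = FALSE)
  }
  if (!identical(model$encoding_version, ENCODING_VERSION)) {
    stop(sprintf(
      "model encoding version '%s' does not match this package ('%s'); retrain",
      model$encoding_version, ENCODING_VERSION), call. = FALSE)
  }
  model
}
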