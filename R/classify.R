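# Percent-change feature tables, PCA feature extraction, and multinomial
# logistic regression to identify the blocked channel from AP metric changes.

.METRIC_COLS <- c("rise_ms", "apd30_ms", "apd50_ms", "apd80_ms",
                  "apd_mxr_ms", "apd_tri_ms")

#' Percent-change feature table
#'
#' Per-sample percent change of each AP metric between a blocked (or
#' drug-treated) measurement set and its reference,
#' \code{100 * (blocked - reference) / reference}. In paired mode samples
#' are matched on their id column (the same cell or tissue measured with and
#' without block); in unpaired mode the change is taken against the
#' reference population mean. Samples with any undefined metric are dropped;
#' the number dropped is recorded in \code{attr(, "n_dropped")}.
#'
#' @param blocked,reference data.frames carrying the metric columns
#'   (\code{rise_ms}, \code{apd30_ms}, \code{apd50_ms}, \code{apd80_ms},
#'   \code{apd_mxr_ms}, \code{apd_tri_ms}, optionally
#'   \code{stim_delay_ms}) and, for paired mode, an id column.
#' @param pairing "paired" (default when both tables share an id column) or
#'   "unpaired".
#' @param idCol id column name (default "cell").
#' @param label optional class label attached as a \code{channel} column.
#' @param metricCols metric columns to difference.
#' @return data.frame of percent changes, one row per retained sample.
#' @export
percentChangeFeatures <- function(blocked, reference,
                                  pairing = c("paired", "unpaired"),
                                  idCol = "cell", label = NULL,
                                  metricCols = .METRIC_COLS) {
  pairing <- if (missing(pairing) &&
                 !(idCol %in% names(blocked) && idCol %in% names(reference)))
    "unpaired" else match.arg(pairing)
  metricCols <- intersect(metricCols, intersect(names(blocked),
                                                names(reference)))
  stopifnot(length(metricCols) >= 1)
  if ("excluded" %in% names(blocked)) blocked <- blocked[!blocked$excluded, ]
  if ("excluded" %in% names(reference))
    reference <- reference[!reference$excluded, ]

  if (pairing == "paired") {
    common <- intersect(blocked[[idCol]], reference[[idCol]])
    b <- blocked[match(common, blocked[[idCol]]), metricCols, drop = FALSE]
    r <- reference[match(common, reference[[idCol]]), metricCols,
                   drop = FALSE]
    ids <- common
  } else {
    r_mean <- colMeans(reference[, metricCols, drop = FALSE], na.rm = TRUE)
    b <- blocked[, metricCols, drop = FALSE]
    r <- as.data.frame(as.list(r_mean))[rep(1, nrow(b)), , drop = FALSE]
    ids <- if (idCol %in% names(blocked)) blocked[[idCol]]
           else seq_len(nrow(b))
  }
  if (any(unlist(r) == 0, na.rm = TRUE)) stop("reference metric equals 0")
  pc <- 100 * (b - r) / r
  ok <- complete.cases(pc)
  out <- pc[ok, , drop = FALSE]
  out[[idCol]] <- ids[ok]
  if (!is.null(label)) out$channel <- label
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' PCA of a standardized feature table
#'
#' Features are z-scored (per-feature mean and SD from the table itself) and
#' decomposed by principal components analysis, equivalent to an
#' eigen-decomposition of the feature correlation matrix. Components are
#' sorted by explained variance, and each component's sign is fixed so its
#' largest-magnitude loading is positive. Zero-variance features are dropped
#' with a warning.
#'
#' @param x data.frame or matrix of features (numeric columns only are
#'   used).
#' @param nComponents number of components to keep (default all).
#' @return list of class "cardiomapPCA": \code{loadings} (features x
#'   components), \code{explained_variance_ratio}, \code{center},
#'   \code{scale}, \code{scores}.
#' @export
fitPCA <- function(x, nComponents = NULL) {
  if (is.data.frame(x))
    x <- as.matrix(x[, vapply(x, is.numeric, logical(1)), drop = FALSE])
  stopifnot(nrow(x) >= 2, ncol(x) >= 2)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  load <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  k <- if (is.null(nComponents)) ncol(load) else min(nComponents, ncol(load))
  structure(list(loadings = load[, seq_len(k), drop = FALSE],
                 explained_variance_ratio = evr[seq_len(k)],
                 center = pc$center, scale = pc$scale,
                 scores = scores[, seq_len(k), drop = FALSE]),
            class = "cardiomapPCA")
}

#' @export
print.cardiomapPCA <- function(x, ...) {
  cat("PCA:", ncol(x$loadings), "components of", nrow(x$loadings),
      "features\n")
  cat("explained variance ratio:",
      paste(signif(x$explained_variance_ratio, 3), collapse = ", "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

# indices of a stratified random subset holding `frac` of every class
.stratified_idx <- function(labels, frac) {
  idx <- integer(0)
  for (cl in unique(labels)) {
    pool <- which(labels == cl)
    n_take <- round(frac * length(pool))
    n_take <- max(1L, min(length(pool) - 1L, n_take))
    idx <- c(idx, sample(pool, n_take))
  }
  sort(idx)
}

# stratified fold assignment (1..k) per sample
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    pool <- sample(which(labels == cl))
    fold[pool] <- rep_len(seq_len(k), length(pool))
  }
  fold
}

#' Train and evaluate a multinomial logistic-regression block classifier
#'
#' The protocol mirrors the validation design: an 80/20 stratified
#' train/test split; features z-scored with means and SDs fitted on the
#' training set and applied unchanged to the test set; an L2-penalized
#' multinomial logistic regression whose regularization strength is tuned on
#' the training set by stratified 5-fold cross-validation over a log-spaced
#' grid; and the whole procedure repeated over several different splits to
#' give mean and SD accuracies.
#'
#' @param x feature data.frame or matrix (numeric columns used).
#' @param labels class labels, one per row (factor or character).
#' @param nRepeats number of repeated splits (use 100 for small tables, 5
#'   for large ones).
#' @param trainFrac training fraction (default 0.8).
#' @param nFolds CV folds for tuning (default 5).
#' @param cGrid inverse-regularization grid; default 13 log-spaced points
#'   over 1e-3..1e3.
#' @param seed RNG seed for splits and folds.
#' @return list of class "cardiomapClassifier": \code{overall} (mean, sd),
#'   \code{per_class} (data.frame of mean/sd per class), \code{repeats}
#'   (per-repeat overall accuracy), \code{best_C} per repeat.
#' @export
trainEvalLogreg <- function(x, labels, nRepeats = 5, trainFrac = 0.8,
                            nFolds = 5,
                            cGrid = 10^seq(-3, 3, length.out = 13),
                            seed = 1) {
  if (is.data.frame(x))
    x <- as.matrix(x[, intersect(names(x), .METRIC_COLS), drop = FALSE])
  labels <- factor(labels)
  stopifnot(nrow(x) == length(labels), nlevels(labels) >= 2)
  if (any(table(labels) < 5))
    stop("every class needs at least 5 samples")

  fit_predict <- function(xtr, ytr, xte, lambda, lambda_path) {
    # fit the full path; glmnet is unreliable with a single lambda
    fit <- glmnet::glmnet(xtr, ytr, family = "multinomial", alpha = 0,
                          lambda = lambda_path, standardize = FALSE)
    pr <- predict(fit, newx = xte, type = "class", s = lambda)
    factor(pr[, 1], levels = levels(ytr))
  }

  acc_overall <- numeric(nRepeats)
  best_C <- numeric(nRepeats)
  per_class <- matrix(NA_real_, nRepeats, nlevels(labels),
                      dimnames = list(NULL, levels(labels)))
  withSeed(seed, {
    for (r in seq_len(nRepeats)) {
      tr <- .stratified_idx(labels, trainFrac)
      te <- setdiff(seq_len(nrow(x)), tr)
      xtr <- x[tr, , drop = FALSE]; ytr <- droplevels(labels[tr])
      mu <- colMeans(xtr); sg <- apply(xtr, 2, sd)
      sg[sg == 0] <- 1
      xtr_s <- scale(xtr, mu, sg)
      xte_s <- scale(x[te, , drop = FALSE], mu, sg)
      lambdas <- 1 / (cGrid * nrow(xtr_s))

      fold <- .stratified_folds(ytr, nFolds)
      cv_acc <- numeric(length(lambdas))
      for (f in seq_len(nFolds)) {
        xin <- xtr_s[fold != f, , drop = FALSE]
        yin <- ytr[fold != f]
        xout <- xtr_s[fold == f, , drop = FALSE]
        yout <- ytr[fold == f]
        fit <- glmnet::glmnet(xin, yin, family = "multinomial", alpha = 0,
                              lambda = sort(lambdas, decreasing = TRUE),
                              standardize = FALSE)
        for (li in seq_along(lambdas)) {
          pr <- predict(fit, newx = xout, type = "class", s = lambdas[li])
          cv_acc[li] <- cv_acc[li] + mean(pr[, 1] == as.character(yout))
        }
      }
      best <- which.max(cv_acc)  # ties: strongest regularization not forced;
      best_C[r] <- cGrid[best]   # first (smallest C) maximum wins
      pred <- fit_predict(xtr_s, ytr, xte_s, lambdas[best],
                          sort(lambdas, decreasing = TRUE))
      yte <- labels[te]
      acc_overall[r] <- mean(pred == yte)
      for (cl in levels(labels)) {
        m <- yte == cl
        if (any(m)) per_class[r, cl] <- mean(pred[m] == yte[m])
      }
    }
  })
  structure(list(
    overall = c(mean = mean(acc_overall), sd = sd(acc_overall)),
    per_class = data.frame(class = colnames(per_class),
                           mean = colMeans(per_class, na.rm = TRUE),
                           sd = apply(per_class, 2, sd, na.rm = TRUE),
                           row.names = NULL),
    repeats = acc_overall, best_C = best_C),
    class = "cardiomapClassifier")
}

#' @export
print.cardiomapClassifier <- function(x, ...) {
  cat(sprintf("Block classifier: overall accuracy %.4f (sd %.4f) over %d splits\n",
              x$overall["mean"], x$overall["sd"], length(x$repeats)))
  print(x$per_class, digits = 4)
  invisible(x)
}
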