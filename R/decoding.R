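#' Train a linear max-margin (SVM) classifier
#'
#' Finds the separating hyperplane maximising the margin between the two
#' classes, via a linear-kernel support vector machine with a large cost
#' (hard margin on separable data, soft-margin fallback otherwise).
#'
#' @param x Feature matrix (trials x features).
#' @param y Labels coercible to a two-level factor.
#' @param cost Soft-margin cost (large = effectively hard margin).
#' @return List of class `maxmargin_model`: `beta`, `b` (decision rule
#'   sign(x . beta + b) maps to the second factor level), `levels`, and the
#'   underlying `svm` fit.
#' @export
train_linear_maxmargin <- function(x, y, cost = 1e3) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2)
    stop("need exactly two classes in the training labels", call. = FALSE)
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  beta <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  structure(list(beta = beta, b = b, levels = levels(y), fit = fit),
            class = "maxmargin_model")
}

#' Predict classes from a `maxmargin_model`
#' @param object A `maxmargin_model`.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.maxmargin_model <- function(object, newdata, ...) {
  stats::predict(object$fit, as.matrix(newdata))
}

#' Cross-validated decoding and joint distribution of true vs decoded label
#'
#' Stratified k-fold cross-validation of the linear max-margin decoder;
#' held-out predictions are pooled into the 2x2 joint probability table of
#' (presented stimulus, decoded stimulus).
#'
#' @param x Feature matrix (trials x features).
#' @param y Two-level labels.
#' @param folds Number of folds.
#' @param seed Seed for the fold assignment.
#' @param cost Passed to [train_linear_maxmargin()].
#' @return List of class `joint_distribution`: `joint` (2x2 probabilities,
#'   rows = true), `counts`, `accuracy`.
#' @export
decode_and_tabulate <- function(x, y, folds = 5, seed = 1, cost = 1e3) {
  x <- as.matrix(x)
  y <- factor(y)
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  counts <- matrix(0, 2, 2, dimnames = list(true = levels(y),
                                            decoded = levels(y)))
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < 2) next
    mdl <- train_linear_maxmargin(x[tr, , drop = FALSE], y[tr], cost = cost)
    pred <- predict(mdl, x[!tr, , drop = FALSE])
    tab <- table(factor(y[!tr], levels(y)), factor(pred, levels(y)))
    counts <- counts + tab
  }
  joint <- counts / sum(counts)
  structure(list(joint = joint, counts = counts,
                 accuracy = sum(diag(counts)) / sum(counts)),
            class = "joint_distribution")
}

#' Mutual information of a 2x2 joint distribution, in bits
#'
#' I(r, s) = sum_s p(s) sum_r p(r|s) log2( p(r|s) / p(r) ), with
#' 0 log 0 = 0. For two equiprobable stimuli the maximum is 1 bit.
#'
#' @param joint 2x2 matrix of joint probabilities or counts (rows = true
#'   stimulus s, columns = decoded response r), or a `joint_distribution`.
#' @return Mutual information, bits (>= 0).
#' @export
mutual_information <- function(joint) {
  if (inherits(joint, "joint_distribution")) joint <- joint$joint
  joint <- as.matrix(joint)
  if (any(joint < 0)) stop("negative entries in joint", call. = FALSE)
  p <- joint / sum(joint)
  ps <- rowSums(p)          # p(s)
  pr <- colSums(p)          # p(r)
  mi <- 0
  for (s in seq_len(nrow(p))) for (r in seq_len(ncol(p))) {
    if (p[s, r] > 0)
      mi <- mi + p[s, r] * log2(p[s, r] / (ps[s] * pr[r]))
  }
  max(mi, 0)
}

#' Decoding performance and information versus neuron count
#'
#' Repeats cross-validated decoding on random neuron subsets of decreasing
#' size, reporting the mean accuracy and mutual information per size.
#'
#' @param x Per-neuron feature matrix (trials x neurons).
#' @param y Two-level labels.
#' @param subset_sizes Neuron counts to evaluate.
#' @param n_repeats Random subsets per size.
#' @param folds Cross-validation folds.
#' @param seed Integer seed.
#' @return Data frame with `n_neurons`, `accuracy`, `mi_bits`.
#' @export
decoding_curve <- function(x, y, subset_sizes, n_repeats = 5, folds = 5,
                           seed = 1) {
  x <- as.matrix(x)
  stopifnot(all(subset_sizes <= ncol(x)), all(subset_sizes >= 1))
  set.seed(seed)
  out <- lapply(subset_sizes, function(k) {
    acc <- mi <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      cols <- if (k == ncol(x)) seq_len(ncol(x)) else sample(ncol(x), k)
      jd <- decode_and_tabulate(x[, cols, drop = FALSE], y, folds = folds,
                                seed = sample.int(2^30, 1))
      acc[r] <- jd$accuracy
      mi[r] <- mutual_information(jd)
    }
    data.frame(n_neurons = k, accuracy = mean(acc), mi_bits = mean(mi))
  })
  do.call(rbind, out)
}
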