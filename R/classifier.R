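#' Length-matched negative sampling
#'
#' Samples `length(positives)` sequences from a larger negative pool so the
#' binned length histogram of the sample matches the positives'
#' histogram bin for bin where the pool allows; bins that fall short are
#' topped up from the nearest (by bin distance) bins. Deterministic given
#' `seed`.
#'
#' @param positives,negative_pool numeric vectors of peptide lengths (or
#'   lists of [peptide_record()]s, from which lengths are taken).
#' @param n_bins number of equal-width bins over the positives' length
#'   range (default 20).
#' @param seed integer seed.
#' @return integer indices into `negative_pool` of the sampled negatives.
#' @export
match_length_distribution <- function(positives, negative_pool, n_bins = 20,
                                      seed = 1L) {
  len <- function(x) if (is.numeric(x)) x else
    vapply(x, function(r) nchar(r$sequence), numeric(1))
  lp <- len(positives); ln <- len(negative_pool)
  if (length(ln) == 0) stop("negative pool is empty", call. = FALSE)
  if (length(ln) < length(lp))
    stop("negative pool smaller than positive set", call. = FALSE)
  rng <- range(lp)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin_of <- function(x) findInterval(x, breaks, rightmost.closed = TRUE)
  bp <- pmax(bin_of(lp), 1L)
  # pool bins: 0 = below the positives' range, n_bins + 1 = above; those
  # overflow bins are only drawn from when an in-range bin falls short
  bn <- bin_of(ln)
  target <- tabulate(bp, n_bins)
  with_seed(seed, {
    picked <- integer(0)
    avail <- split(seq_along(ln), factor(bn, levels = 0:(n_bins + 1)))
    names(avail) <- as.character(0:(n_bins + 1))
    draw <- function(pool, k) if (length(pool) == 1) pool else sample(pool, k)
    deficit <- integer(n_bins)
    for (b in seq_len(n_bins)) {
      pool <- avail[[as.character(b)]]
      take <- min(target[b], length(pool))
      if (take > 0) {
        sel <- draw(pool, take)[seq_len(take)]
        picked <- c(picked, sel)
        avail[[as.character(b)]] <- setdiff(pool, sel)
      }
      deficit[b] <- target[b] - take
    }
    for (b in which(deficit > 0)) {
      need <- deficit[b]
      for (d in seq_len(n_bins + 1)) {   # nearest bins, lower first on ties
        for (nb in unique(pmin(pmax(c(b - d, b + d), 0L), n_bins + 1L))) {
          if (need == 0) break
          pool <- avail[[as.character(nb)]]
          take <- min(need, length(pool))
          if (take > 0) {
            sel <- draw(pool, take)[seq_len(take)]
            picked <- c(picked, sel)
            avail[[as.character(nb)]] <- setdiff(pool, sel)
            need <- need - take
          }
        }
        if (need == 0) break
      }
    }
    sort(picked)
  })
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the AMP probability classifier
#'
#' L2-regularised (ridge) logistic regression on standardised features,
#' fitted by iteratively reweighted least squares. The small ridge penalty
#' keeps the fit finite on linearly separable data; training is exactly
#' deterministic (the `seed` argument is accepted for interface symmetry
#' with the generators but the IRLS itself has no randomness).
#'
#' @param features numeric matrix (rows = peptides), e.g. from
#'   [feature_matrix()].
#' @param labels logical or 0/1 vector; TRUE/1 = AMP.
#' @param lambda ridge penalty on standardised coefficients (default 1e-2).
#' @param max_iter,tol IRLS controls.
#' @param seed unused; kept so all training entry points share a signature.
#' @return an object of class `amp_classifier` holding coefficients, the
#'   feature scaler, and the feature schema.
#' @export
train_amp_classifier <- function(features, labels, lambda = 1e-2,
                                 max_iter = 100, tol = 1e-10, seed = 1L) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2)
    stop("training data must contain both classes", call. = FALSE)
  X <- as.matrix(features)
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev == 0] <- 1
  Xs <- scale(X, mu, sdev)
  Z <- cbind(1, Xs)
  p <- ncol(Z)
  pen <- diag(c(0, rep(lambda, p - 1)))    # intercept unpenalised
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    prob <- sigmoid(eta)
    W <- prob * (1 - prob)
    g <- crossprod(Z, y - prob) - pen %*% beta
    H <- crossprod(Z * W, Z) + pen
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  structure(list(coefficients = setNames(drop(beta), c("(Intercept)", colnames(X))),
                 center = mu, scale = sdev, features = colnames(X),
                 lambda = lambda, iterations = it),
            class = "amp_classifier")
}

#' @export
print.amp_classifier <- function(x, ...) {
  cat("Ridge-logistic AMP classifier (", length(x$features), " features, ",
      "lambda = ", x$lambda, ")\n", sep = "")
  invisible(x)
}

#' @method coef amp_classifier
#' @export
coef.amp_classifier <- function(object, ...) object$coefficients

#' AMP probability prediction and thresholded calls
#'
#' @param object trained [train_amp_classifier()] model.
#' @param newdata feature matrix, list of records, or character vector of
#'   sequences.
#' @param threshold retain-if-above probability cutoff; the call is strict
#'   (`probability > threshold`). The discovery pipeline uses 0.7 for
#'   putative-AMP retention and 0.8 for the final positive set.
#' @param ... unused.
#' @return data.frame with `probability` and logical `call`.
#' @export
predict.amp_classifier <- function(object, newdata, threshold = 0.7, ...) {
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  X <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  X <- X[, object$features, drop = FALSE]
  Z <- cbind(1, scale(X, object$center, object$scale))
  prob <- sigmoid(drop(Z %*% object$coefficients))
  data.frame(probability = prob, call = prob > threshold)
}

#' Serialise / restore a classifier as versioned JSON-compatible list
#'
#' @param object an `amp_classifier`.
#' @return a plain list (coefficients, scaler, schema, version) suitable
#'   for `jsonlite::write_json`; invert with [amp_classifier_from_list()].
#' @export
amp_classifier_to_list <- function(object) {
  list(version = 1L, coefficients = as.list(object$coefficients),
       center = as.list(object$center), scale = as.list(object$scale),
       features = object$features, lambda = object$lambda)
}

#' @rdname amp_classifier_to_list
#' @param x list produced by [amp_classifier_to_list()].
#' @export
amp_classifier_from_list <- function(x) {
  structure(list(coefficients = unlist(x$coefficients),
                 center = unlist(x$center), scale = unlist(x$scale),
                 features = unlist(x$features), lambda = x$lambda,
                 iterations = NA_integer_),
            class = "amp_classifier")
}

#' Confusion-matrix performance report
#'
#' All the rates a standard confusion-matrix report prints, as percentages:
#' sensitivity (= recall), specificity, positive/negative predictive value
#' (PPV = precision), F1, prevalence, detection rate, detection prevalence
#' and balanced accuracy. Undefined ratios (zero denominators) are
#' returned as `NaN` with a warning rather than an error.
#'
#' @param tp,fp,fn,tn confusion counts (all >= 0, total > 0).
#' @return named numeric vector of percentages.
#' @examples
#' confusion_metrics(tp = 3, fp = 1, fn = 1, tn = 5)
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be >= 0", call. = FALSE)
  N <- tp + fp + fn + tn
  if (N == 0) stop("empty confusion matrix", call. = FALSE)
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)", call. = FALSE); NaN }
    else num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  ppv <- safe(tp, tp + fp, "ppv")
  npv <- safe(tn, tn + fn, "npv")
  f1 <- if (is.nan(ppv) || is.nan(sens) || (ppv + sens) == 0) NaN else
    2 * ppv * sens / (ppv + sens)
  100 * c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
          precision = ppv, recall = sens, f1 = f1,
          prevalence = (tp + fn) / N, detection_rate = tp / N,
          detection_prevalence = (tp + fp) / N,
          balanced_accuracy = (sens + spec) / 2)
}
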