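#' Labeled set of domain frequency profiles for signature vetting
#'
#' Candidate reference signatures from metagenomes (e.g. viromes) must be
#' well distinguishable from the opposing class (e.g. microbial
#' metagenomes) before entering the mixture model; otherwise a contaminated
#' reference would soak up weight that belongs elsewhere. This container
#' holds the sample-by-family frequency matrix, the class labels and the
#' per-sample eligibility for elimination.
#'
#' @param profiles numeric matrix, samples in rows (rownames = sample ids),
#'   domain families in columns; each row must sum to 1 within `1e-6`.
#' @param labels numeric vector of class labels, `+1` (candidate class,
#'   e.g. viral) or `-1` (opposing class, e.g. microbial).
#' @param eligible logical vector: whether a sample may be eliminated.
#'   Defaults to the candidate (+1) class.
#' @return An object of class `labeled_profile_set`.
#' @export
labeled_profile_set <- function(profiles, labels, eligible = labels > 0) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)) || anyDuplicated(rownames(profiles)))
    stop("profiles must have unique rownames (sample ids)")
  labels <- as.numeric(labels)
  eligible <- as.logical(eligible)
  stopifnot(nrow(profiles) == length(labels),
            nrow(profiles) == length(eligible))
  if (!all(labels %in% c(-1, 1)))
    stop("labels must be +1 or -1")
  if (min(sum(labels > 0), sum(labels < 0)) < 2L)
    stop("each class needs at least 2 samples")
  if (anyNA(profiles) || any(profiles < 0))
    stop("profiles must be nonnegative and complete")
  rs <- rowSums(profiles)
  if (any(abs(rs - 1) > 1e-6))
    stop("profile rows must sum to 1; offending: ",
         paste(utils::head(rownames(profiles)[abs(rs - 1) > 1e-6], 5L),
               collapse = ", "))
  structure(list(profiles = profiles, labels = labels, eligible = eligible,
                 sample_ids = rownames(profiles)),
            class = "labeled_profile_set")
}

#' @export
print.labeled_profile_set <- function(x, ...) {
  cat(sprintf(
    "<labeled_profile_set> %d samples (%d +1 / %d -1), %d families, %d eligible\n",
    length(x$labels), sum(x$labels > 0), sum(x$labels < 0),
    ncol(x$profiles), sum(x$eligible)))
  invisible(x)
}

.subset_lps <- function(data, keep) {
  labeled_profile_set(data$profiles[keep, , drop = FALSE],
                      data$labels[keep], data$eligible[keep])
}

#' Train a regularized least squares (ridge) classifier
#'
#' Fits the linear model minimizing
#' `sum_s (label_s - (w . profile_s + b))^2 + lambda * ||w||^2` with an
#' unpenalized bias `b`. With more families than samples (the usual case
#' for domain profiles) the solution is computed in the sample-space dual,
#' `w = Xc' (Xc Xc' + lambda I)^{-1} yc` on centered data, which yields
#' predictions identical to the primal normal equations.
#'
#' @param x a [labeled_profile_set()], or a samples-by-families numeric
#'   matrix.
#' @param y class labels (ignored when `x` is a `labeled_profile_set`).
#' @param lambda ridge penalty, strictly positive.
#' @return An object of class `rls_model`: list with `w` (named by
#'   family), `b` and `lambda`.
#' @export
train_rls <- function(x, y = NULL, lambda) {
  if (inherits(x, "labeled_profile_set")) {
    y <- x$labels
    x <- x$profiles
  }
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), is_scalar_number(lambda), lambda > 0)
  n <- nrow(x); d <- ncol(x)
  xbar <- colMeans(x)
  ybar <- mean(y)
  xc <- sweep(x, 2L, xbar)
  yc <- y - ybar
  w <- tryCatch({
    if (d > n) {
      gram <- tcrossprod(xc)
      alpha <- solve(gram + diag(lambda, n), yc)
      as.vector(crossprod(xc, alpha))
    } else {
      as.vector(solve(crossprod(xc) + diag(lambda, d), crossprod(xc, yc)))
    }
  }, error = function(e)
    stop("ridge system could not be solved (lambda = ", lambda, "): ",
         conditionMessage(e), call. = FALSE))
  names(w) <- colnames(x)
  structure(list(w = w, b = ybar - sum(xbar * w), lambda = lambda),
            class = "rls_model")
}

#' Predict classes with a regularized least squares model
#'
#' Returns `sign(w . profile + b)` per sample; a score of exactly zero is
#' assigned to the `+1` class.
#'
#' @param model an [train_rls()] model.
#' @param profiles numeric matrix (samples x families, aligned with the
#'   training families) or a single profile vector.
#' @return numeric vector of `+1`/`-1` labels.
#' @export
predict_rls <- function(model, profiles) {
  stopifnot(inherits(model, "rls_model"))
  if (is.null(dim(profiles))) profiles <- base::matrix(profiles, nrow = 1L)
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != length(model$w))
    stop("profile family universe does not match the model")
  score <- as.vector(profiles %*% model$w) + model$b
  ifelse(score >= 0, 1, -1)
}

.stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cls in c(-1, 1)) {
    idx <- which(labels == cls)
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Per-sample misclassification rate under repeated cross-validation
#'
#' Runs `n_repeats` rounds of stratified `n_folds`-fold cross-validation.
#' Within each repeat, the ridge penalty is chosen from `lambda_grid` to
#' minimize the total cross-validated misclassification count (ties go to
#' the smallest penalty), and every sample's held-out prediction at that
#' penalty is recorded. The returned rate per sample is the fraction of
#' repeats in which it was misclassified; with the default 10 repeats each
#' rate is a multiple of 0.1. Fold partitions are drawn from the seeded
#' generator, so results are reproducible.
#'
#' @param data a [labeled_profile_set()].
#' @param lambda_grid positive penalties to choose from (default
#'   `10^(-4:2)`).
#' @param n_folds folds per repeat (default 5); each class must have at
#'   least `n_folds` members.
#' @param n_repeats repeats with fresh random partitions (default 10).
#' @param seed integer seed for the partition stream.
#' @return Named numeric vector of misclassification rates in `[0, 1]`,
#'   one per sample, with attribute `lambda` (the penalty chosen in each
#'   repeat).
#' @export
cv_misclassification <- function(data, lambda_grid = 10^(-4:2),
                                 n_folds = 5L, n_repeats = 10L, seed = 1L) {
  stopifnot(inherits(data, "labeled_profile_set"),
            length(lambda_grid) >= 1L, all(lambda_grid > 0),
            is_scalar_number(n_folds), n_folds >= 2L,
            is_scalar_number(n_repeats), n_repeats >= 1L)
  lambda_grid <- sort(as.numeric(lambda_grid))
  n <- length(data$labels)
  if (min(sum(data$labels > 0), sum(data$labels < 0)) < n_folds)
    stop(sprintf("each class needs at least n_folds = %d members", n_folds))
  mis <- integer(n)
  lam_used <- numeric(n_repeats)
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      fold <- .stratified_folds(data$labels, n_folds)
      # held-out predictions for every lambda in one pass over the folds
      pred <- base::matrix(0, nrow = n, ncol = length(lambda_grid))
      for (f in seq_len(n_folds)) {
        test <- fold == f
        for (li in seq_along(lambda_grid)) {
          m <- train_rls(data$profiles[!test, , drop = FALSE],
                         data$labels[!test], lambda_grid[li])
          pred[test, li] <- predict_rls(m, data$profiles[test, , drop = FALSE])
        }
      }
      errs <- colSums(pred != data$labels)
      best <- which.min(errs)  # ties -> smallest lambda (grid is sorted)
      lam_used[r] <- lambda_grid[best]
      mis <- mis + (pred[, best] != data$labels)
    }
  })
  structure(stats::setNames(mis / n_repeats, data$sample_ids),
            lambda = lam_used)
}

#' Stepwise elimination of indistinguishable candidate signatures
#'
#' Vets candidate metagenome signatures by repeatedly cross-validating a
#' regularized least squares classifier ([cv_misclassification()]) and
#' removing, one per round, the eligible sample with the highest
#' misclassification rate over the repeats (ties broken by lexicographically
#' smallest sample id). The procedure repeats on the reduced set with a
#' fresh seeded partition stream and stops when no test error occurs in any
#' repeat — every remaining sample is then reliably separable from the
#' opposing class. If errors persist but only among ineligible samples, the
#' procedure stalls (status `"stalled"`); if another elimination would drop
#' a class below `n_folds` members it aborts with the partial trace
#' (status `"aborted"`).
#'
#' @inheritParams cv_misclassification
#' @return An object of class `selection_result`: list with
#'   `retained_ids`, `eliminated` (data frame `round`, `sample_id`,
#'   `rate`), `n_rounds`, `seed` and `status` (one of `"converged"`,
#'   `"stalled"`, `"aborted"`).
#' @export
stepwise_eliminate <- function(data, lambda_grid = 10^(-4:2), n_folds = 5L,
                               n_repeats = 10L, seed = 1L) {
  stopifnot(inherits(data, "labeled_profile_set"))
  n_eligible <- sum(data$eligible)
  round_seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                            n_eligible + 1L))
  current <- data
  elim <- data.frame(round = integer(), sample_id = character(),
                     rate = numeric(), stringsAsFactors = FALSE)
  status <- "converged"
  r <- 0L
  repeat {
    r <- r + 1L
    rates <- cv_misclassification(current, lambda_grid = lambda_grid,
                                  n_folds = n_folds, n_repeats = n_repeats,
                                  seed = round_seeds[r])
    if (all(rates == 0)) break
    el_rates <- rates[current$eligible]
    if (length(el_rates) == 0L || max(el_rates) == 0) {
      status <- "stalled"
      break
    }
    worst <- names(el_rates)[el_rates == max(el_rates)]
    victim <- lex_sort(worst)[1L]
    vi <- match(victim, current$sample_ids)
    cls <- current$labels[vi]
    if (sum(current$labels == cls) - 1L < n_folds) {
      warning("eliminating '", victim, "' would drop its class below ",
              "n_folds members; aborting with partial trace")
      status <- "aborted"
      break
    }
    elim <- rbind(elim, data.frame(round = r, sample_id = victim,
                                   rate = rates[[victim]],
                                   stringsAsFactors = FALSE))
    current <- .subset_lps(current, -vi)
  }
  structure(list(retained_ids = current$sample_ids,
                 eliminated = elim,
                 n_rounds = r,
                 seed = as.integer(seed),
                 status = status),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d retained, %d eliminated in %d rounds (%s)\n",
              length(x$retained_ids), nrow(x$eliminated), x$n_rounds,
              x$status))
  if (nrow(x$eliminated))
    print(x$eliminated, row.names = FALSE)
  invisible(x)
}
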