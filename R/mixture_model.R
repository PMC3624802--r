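#' Options for the EM mixture fit
#'
#' @param max_iter maximum number of EM iterations (default 10000).
#' @param rel_tol convergence threshold on the relative change of the
#'   log-likelihood between consecutive iterations (default 1e-9).
#' @param init either `"uniform"` (default; the objective is concave on the
#'   simplex, so the optimum does not depend on the start) or a numeric
#'   vector of starting weights on the simplex.
#' @param epsilon_floor smallest mixture density used inside logarithms,
#'   guarding against `-Inf` (default 1e-300).
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(max_iter = 10000L, rel_tol = 1e-9,
                        init = "uniform", epsilon_floor = 1e-300) {
  stopifnot(is_scalar_number(max_iter), max_iter >= 1,
            is_scalar_number(rel_tol), rel_tol > 0,
            is_scalar_number(epsilon_floor), epsilon_floor > 0)
  if (!identical(init, "uniform")) {
    init <- as.numeric(init)
    if (any(init < 0) || abs(sum(init) - 1) > 1e-6)
      stop("custom init weights must be nonnegative and sum to 1")
  }
  structure(list(max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 init = init, epsilon_floor = epsilon_floor),
            class = "fit_options")
}

# Families that enter the likelihood: observed (y > 0) and supported by at
# least one reference (some x_ij > 0). Unsupported observed mass would force
# a -Inf log-likelihood; it is excluded here but fully charged to the FDU.
.supported_mask <- function(y, X) {
  obs <- y > 0
  supp <- rowSums(X) > 0
  list(use = obs & supp, unsupported_mass = sum(y[obs & !supp]))
}

.check_aligned <- function(profile, refs) {
  if (!identical(profile$family_ids, rownames(refs)))
    stop("profile and signature matrix are not aligned on one family ",
         "universe; call align_families() first")
}

#' Fit the domain-frequency mixture model by EM
#'
#' Reconstructs a metagenome's domain family frequency profile `y` as a
#' convex combination of reference signatures, `y ~ sum_i w_i x_i` with
#' `w_i >= 0`, `sum_i w_i = 1`. Under the generative model - each domain
#' hit falls into family `j` with probability `p_j = sum_i w_i x_ij` - the
#' weights maximize the profile-weighted log-likelihood
#' `L(w) = sum_j y_j log(sum_i w_i x_ij)`, which is concave in `w`, so EM
#' from the uniform start converges to a global optimum. The EM update is
#' the classical fixed-components mixture-proportion step: responsibilities
#' `r_ij = w_i x_ij / p_j`, then `w_i <- sum_j y'_j r_ij`, where `y'` is `y`
#' restricted to families supported by at least one reference and
#' renormalized (for the likelihood only).
#'
#' The returned fit carries the reconstruction `yhat = refs %*% w`, the
#' per-iteration log-likelihood trace (non-decreasing, an EM guarantee) and
#' the fraction of domain hits unexplained ([fdu()]) computed on the full,
#' unrestricted `y`, so mass outside every reference's support is counted
#' as unexplained.
#'
#' @param profile a normalized [domain_profile()], aligned with `refs`.
#' @param refs a [signature_matrix()] over the same family universe.
#' @param opts a [fit_options()] object.
#' @return An object of class `mixture_fit`: list with `weights` (named,
#'   on the simplex), `reconstruction` (a `domain_profile`),
#'   `loglik_trace`, `n_iter`, `converged`, `fdu` and `unsupported_mass`.
#' @examples
#' refs <- signature_matrix(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("PF_A", "PF_B"), c("s1", "s2"))))
#' y <- domain_profile(c(PF_A = 0.3, PF_B = 0.7))
#' fit <- em_fit(y, refs)
#' fit$weights
#' @export
em_fit <- function(profile, refs, opts = fit_options()) {
  stopifnot(inherits(profile, "domain_profile"),
            inherits(refs, "signature_matrix"),
            inherits(opts, "fit_options"))
  .check_aligned(profile, refs)
  if (abs(sum(profile$values) - 1) > 1e-9)
    stop("profile must be normalized before fitting")
  X <- unclass(refs)
  y <- profile$values
  K <- ncol(X)
  sup <- .supported_mask(y, X)
  if (!any(sup$use))
    stop(sprintf(
      "degenerate fit: all observed mass (%.6g) lies outside the support of every reference signature",
      sup$unsupported_mass))
  yl <- y[sup$use]
  yl <- yl / sum(yl)
  Xl <- X[sup$use, , drop = FALSE]
  Xt <- t(Xl)

  w <- if (identical(opts$init, "uniform")) rep(1 / K, K) else {
    if (length(opts$init) != K)
      stop("init weight vector length must equal the number of signatures")
    opts$init
  }

  eps <- opts$epsilon_floor
  p <- pmax(as.vector(Xl %*% w), eps)
  ll <- sum(yl * log(p))
  trace <- numeric(opts$max_iter + 1L)
  trace[1L] <- ll
  converged <- FALSE
  it <- 0L
  while (it < opts$max_iter) {
    it <- it + 1L
    w <- w * as.vector(Xt %*% (yl / p))
    w <- pmax(w, 0)
    w <- w / sum(w)
    p <- pmax(as.vector(Xl %*% w), eps)
    ll_new <- sum(yl * log(p))
    trace[it + 1L] <- ll_new
    if (abs(ll_new - ll) <= opts$rel_tol * abs(ll)) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  names(w) <- colnames(X)
  yhat <- as.vector(X %*% w)
  names(yhat) <- rownames(X)
  recon <- domain_profile(yhat, normalized = TRUE)
  fit <- structure(
    list(weights = w,
         reconstruction = recon,
         loglik_trace = trace[seq_len(it + 1L)],
         n_iter = it,
         converged = converged,
         unsupported_mass = sup$unsupported_mass,
         fdu = NA_real_),
    class = "mixture_fit")
  fit$fdu <- fdu(profile, recon)
  fit
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> %d signatures, %d iterations (%s)\n",
              length(x$weights), x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  cat(sprintf("  log-likelihood: %.8g   FDU: %.4f   unsupported mass: %.4g\n",
              x$loglik_trace[length(x$loglik_trace)], x$fdu,
              x$unsupported_mass))
  top <- utils::head(x$weights[order(-x$weights)], 5L)
  for (i in seq_along(top))
    cat(sprintf("  %-30s %7.4f\n", names(top)[i], top[[i]]))
  if (length(x$weights) > 5L) cat("  ...\n")
  invisible(x)
}

#' Mixture log-likelihood of a profile under given weights
#'
#' Computes `sum_j y'_j log(sum_i w_i x_ij)` over the families that are
#' observed (`y_j > 0`) and supported by at least one reference, with `y'`
#' renormalized over those families — the same objective that [em_fit()]
#' maximizes and traces.
#'
#' @inheritParams em_fit
#' @param weights numeric weight vector on the simplex (within 1e-6).
#' @param epsilon_floor density floor inside the logarithm.
#' @return scalar log-likelihood (per unit of profile mass).
#' @export
log_likelihood <- function(profile, refs, weights, epsilon_floor = 1e-300) {
  stopifnot(inherits(profile, "domain_profile"),
            inherits(refs, "signature_matrix"))
  .check_aligned(profile, refs)
  weights <- as.numeric(weights)
  if (length(weights) != ncol(refs))
    stop("weight vector length must equal the number of signatures")
  if (any(weights < -1e-6) || abs(sum(weights) - 1) > 1e-6)
    stop("weights must lie on the simplex (nonnegative, unit sum)")
  X <- unclass(refs)
  y <- profile$values
  sup <- .supported_mask(y, X)
  if (!any(sup$use)) stop("no observed family is supported by any reference")
  yl <- y[sup$use] / sum(y[sup$use])
  p <- pmax(as.vector(X[sup$use, , drop = FALSE] %*% pmax(weights, 0)),
            epsilon_floor)
  sum(yl * log(p))
}

#' Fraction of domain hits unexplained (FDU)
#'
#' Half the Manhattan (L1) distance between the observed and the
#' reconstructed domain frequency profile:
#' `FDU = 0.5 * sum_j |y_j - yhat_j|`, ranging from 0 (perfect
#' reconstruction) to 1 (disjoint support). It equals the fraction of
#' domain-hit mass missing from the reconstruction; by symmetry an equally
#' sized fraction is overpredicted. A low FDU indicates a well-fitting
#' mixture model and hence a trustworthy taxonomic profile.
#'
#' @param observed,reconstructed normalized [domain_profile()]s over the
#'   same family universe.
#' @return scalar in `[0, 1]`.
#' @examples
#' fdu(domain_profile(c(a = 0.6, b = 0.4)), domain_profile(c(a = 0.5, b = 0.5)))
#' @export
fdu <- function(observed, reconstructed) {
  stopifnot(inherits(observed, "domain_profile"),
            inherits(reconstructed, "domain_profile"))
  if (!identical(observed$family_ids, reconstructed$family_ids))
    stop("profiles are not on the same family universe")
  if (abs(sum(observed$values) - 1) > 1e-9 ||
      abs(sum(reconstructed$values) - 1) > 1e-9)
    stop("fdu requires normalized (unit-sum) profiles")
  0.5 * sum(abs(observed$values - reconstructed$values))
}

#' Bray-Curtis dissimilarity between two taxonomic profiles
#'
#' For unit-sum abundance vectors the Bray-Curtis dissimilarity equals half
#' the Manhattan distance, `0.5 * sum_t |p_t - q_t|` — the same statistic
#' as [fdu()], applied to taxon abundances instead of domain frequencies.
#' Profiles are compared over the union of their taxa with zero fill.
#'
#' @param p,q [taxonomic_profile()]s at the same rank.
#' @return scalar in `[0, 1]`; 0 iff the profiles are equal.
#' @export
bray_curtis <- function(p, q) {
  stopifnot(inherits(p, "taxonomic_profile"), inherits(q, "taxonomic_profile"))
  if (!identical(p$rank, q$rank))
    stop(sprintf("rank mismatch: '%s' vs '%s'", p$rank, q$rank))
  taxa <- lex_sort(union(names(p$abundances), names(q$abundances)))
  pv <- qv <- stats::setNames(numeric(length(taxa)), taxa)
  pv[names(p$abundances)] <- p$abundances
  qv[names(q$abundances)] <- q$abundances
  0.5 * sum(abs(pv - qv))
}

#' Aggregate mixture weights into a taxonomic profile
#'
#' The abundance of a taxon at a rank is the sum of the mixture weights of
#' all reference signatures whose lineage carries that taxon at that rank.
#' Signatures lacking an annotation at the rank (e.g. virome-derived
#' signatures, which carry only a superkingdom) contribute their weight to
#' `"unclassified <superkingdom>"`, so total mass is conserved.
#'
#' @param fit a [em_fit()] result, or a named weight vector on the simplex.
#' @param taxonomy a [taxonomy_table()] covering every signature id.
#' @param rank one of `"superkingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return A [taxonomic_profile()] at `rank`.
#' @export
aggregate_weights <- function(fit, taxonomy, rank = "superkingdom") {
  w <- if (inherits(fit, "mixture_fit")) fit$weights else fit
  if (is.null(names(w))) stop("weights must be named by signature id")
  stopifnot(inherits(taxonomy, "taxonomy_table"))
  rank <- match.arg(rank, .tax_ranks)
  miss <- setdiff(names(w), taxonomy$signature_id)
  if (length(miss))
    stop("signature ids missing from taxonomy: ",
         paste(utils::head(miss, 10L), collapse = ", "))
  idx <- match(names(w), taxonomy$signature_id)
  taxon <- taxonomy[[rank]][idx]
  sk <- taxonomy$superkingdom[idx]
  if (any(w < -1e-9) || abs(sum(w) - 1) > 1e-9)
    stop("weights must be nonnegative and sum to 1")
  taxon[is.na(taxon)] <- paste("unclassified", sk[is.na(taxon)])
  ab <- tapply(w, taxon, sum)
  taxonomic_profile(stats::setNames(as.vector(ab), names(ab)), rank = rank)
}

#' Restrict a taxonomic profile to a taxon subset and renormalize
#'
#' Keeps only the listed taxa and rescales their abundances to unit sum —
#' e.g. to compare archaea-vs-bacteria fractions across methods that
#' classify different portions of a dataset.
#'
#' @param profile a [taxonomic_profile()].
#' @param taxa character vector of taxa to keep; at least one must carry
#'   positive abundance.
#' @return A [taxonomic_profile()] over `taxa` (those present).
#' @export
renormalize_subset <- function(profile, taxa) {
  stopifnot(inherits(profile, "taxonomic_profile"), length(taxa) >= 1L)
  keep <- intersect(names(profile$abundances), taxa)
  v <- profile$abundances[keep]
  if (length(v) == 0L || sum(v) <= 0)
    stop("no positive abundance on the requested taxon subset")
  taxonomic_profile(v / sum(v), rank = profile$rank)
}
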