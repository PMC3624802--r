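# Independent oracles and small random-instance builders. The oracles
# deliberately avoid the package's own code paths: plain loops and direct
# linear algebra only.

# Naive per-family log-likelihood: restrict y to families supported by at
# least one component, renormalize, and sum y_j * log(sum_i w_i x_ij)
# with explicit loops.
oracle_loglik <- function(y, X, w) {
  supported <- logical(length(y))
  for (j in seq_along(y)) {
    s <- FALSE
    for (i in seq_len(ncol(X))) if (X[j, i] > 0) s <- TRUE
    supported[j] <- s && y[j] > 0
  }
  yl <- y[supported]
  yl <- yl / sum(yl)
  Xl <- X[supported, , drop = FALSE]
  ll <- 0
  for (j in seq_along(yl)) {
    p <- 0
    for (i in seq_len(ncol(Xl))) p <- p + w[i] * Xl[j, i]
    ll <- ll + yl[[j]] * log(p)
  }
  ll
}

# Best log-likelihood over the 3-component simplex sampled at `step`.
# Vectorized over grid points but never calls package code.
oracle_grid_search_k3 <- function(y, X, step = 0.01) {
  stopifnot(ncol(X) == 3L)
  supported <- rowSums(X > 0) > 0 & y > 0
  yl <- y[supported]; yl <- yl / sum(yl)
  Xl <- X[supported, , drop = FALSE]
  w1 <- rep(seq(0, 1, by = step), each = length(seq(0, 1, by = step)))
  w2 <- rep(seq(0, 1, by = step), times = length(seq(0, 1, by = step)))
  keep <- w1 + w2 <= 1 + 1e-12
  W <- cbind(w1[keep], w2[keep], pmax(1 - w1[keep] - w2[keep], 0))
  P <- Xl %*% t(W)
  P[P < 1e-300] <- 1e-300
  max(colSums(yl * log(P)))
}

# Naive fragment enumeration by a while loop.
oracle_fragments <- function(L, len = 400L, step = len %/% 2L,
                             min_tail = step) {
  out <- list()
  if (L >= len) {
    s <- 0L
    while (s + len <= L) {
      out[[length(out) + 1L]] <- c(s, s + len)
      s <- s + step
    }
    covered_to <- out[[length(out)]][2L]
    if (L - covered_to >= min_tail)
      out[[length(out) + 1L]] <- c(L - len, L)
  } else if (L >= min_tail) {
    out[[1L]] <- c(0L, L)
  }
  if (length(out) == 0L)
    return(matrix(integer(), ncol = 2L))
  do.call(rbind, out)
}

# Penalized least squares with unpenalized intercept, solved through the
# augmented primal normal equations.
oracle_ridge <- function(X, y, lambda) {
  A <- cbind(1, X)
  pen <- diag(c(0, rep(lambda, ncol(X))))
  theta <- solve(crossprod(A) + pen, crossprod(A, y))
  list(b = theta[1L], w = theta[-1L])
}

# Random normalized profile over D families named PF....
rand_profile_vec <- function(D, concentration = 1) {
  v <- rgamma(D, concentration)
  v <- v / sum(v)
  names(v) <- sprintf("PF%04d", seq_len(D))
  v
}

# Random column-stochastic D x K matrix with matching family names.
rand_refs_mat <- function(D, K, concentration = 1) {
  X <- matrix(rgamma(D * K, concentration), D, K)
  X <- sweep(X, 2, colSums(X), "/")
  dimnames(X) <- list(sprintf("PF%04d", seq_len(D)),
                      sprintf("sig%03d", seq_len(K)))
  X
}

rand_instance <- function(D, K, concentration = 1) {
  X <- rand_refs_mat(D, K, concentration)
  y <- rand_profile_vec(D, concentration)
  list(profile = domain_profile(y), refs = signature_matrix(X),
       y = y[order(names(y), method = "radix")],
       X = X[order(rownames(X), method = "radix"), , drop = FALSE])
}

# Minimal taxonomy for a set of signature ids.
toy_taxonomy <- function(ids, superkingdoms, phyla = NULL,
                         source_type = "genome") {
  taxonomy_table(data.frame(
    signature_id = ids,
    source_type = rep_len(source_type, length(ids)),
    superkingdom = rep_len(superkingdoms, length(ids)),
    phylum = if (is.null(phyla)) NA_character_ else rep_len(phyla, length(ids)),
    stringsAsFactors = FALSE))
}
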