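test_that("em_fit recovers weights for profiles inside the reference hull", {
  refs <- signature_matrix(matrix(c(1, 0, 0, 1), 2, 2,
    dimnames = list(c("PF_A", "PF_B"), c("s1", "s2"))))
  y <- domain_profile(c(PF_A = 0.3, PF_B = 0.7))
  fit <- em_fit(y, refs)
  expect_equal(unname(fit$weights), c(0.3, 0.7), tolerance = 1e-6)
  expect_lt(fit$fdu, 1e-9)
  expect_true(fit$converged)

  # single reference equal to the profile
  solo <- signature_matrix(matrix(c(0.3, 0.7), 2, 1,
    dimnames = list(c("PF_A", "PF_B"), "only")))
  fit1 <- em_fit(y, solo)
  expect_equal(unname(fit1$weights), 1.0)
  expect_lt(fit1$fdu, 1e-12)
})

test_that("em_fit handles profiles outside the hull: best L1 fit with FDU", {
  # y = (1,0) cannot be reconstructed; the closest mixture puts all weight
  # on the component with the largest mass at PF_A
  refs <- signature_matrix(matrix(c(0.5, 0.5, 0, 1), 2, 2,
    dimnames = list(c("PF_A", "PF_B"), c("x1", "x2"))))
  y <- domain_profile(c(PF_A = 1, PF_B = 0))
  fit <- em_fit(y, refs)
  expect_equal(unname(fit$weights), c(1, 0), tolerance = 1e-6)
  expect_equal(unname(fit$reconstruction$values), c(0.5, 0.5),
               tolerance = 1e-6)
  expect_equal(fit$fdu, 0.5, tolerance = 1e-6)
})

test_that("em_fit errors when no observed family is supported", {
  refs <- signature_matrix(matrix(1, 1, 1,
    dimnames = list("PF_B", "s1")))
  y <- domain_profile(c(PF_A = 1, PF_B = 0))
  al <- align_families(y, refs)
  expect_error(em_fit(al$profile, al$refs), "degenerate")
  expect_error(em_fit(y, refs), "align")
})

test_that("unsupported observed mass is excluded from the likelihood but kept in the FDU", {
  refs <- signature_matrix(matrix(c(0.6, 0.4), 2, 1,
    dimnames = list(c("PF_A", "PF_B"), "s1")))
  y <- domain_profile(c(PF_A = 0.48, PF_B = 0.32, PF_C = 0.2))
  al <- align_families(y, refs)
  fit <- em_fit(al$profile, al$refs)
  expect_equal(fit$unsupported_mass, 0.2)
  # reconstruction is (0.6, 0.4, 0): fdu = 0.5*(0.12 + 0.08 + 0.2)
  expect_equal(fit$fdu, 0.2, tolerance = 1e-9)
})

test_that("log_likelihood matches closed forms and the naive oracle", {
  refs1 <- signature_matrix(matrix(c(1, 0), 2, 1,
    dimnames = list(c("a", "b"), "s1")))
  y1 <- domain_profile(c(a = 1, b = 0))
  expect_equal(log_likelihood(y1, refs1, 1), 0)

  refs2 <- signature_matrix(matrix(c(0.5, 0.5), 2, 1,
    dimnames = list(c("a", "b"), "s1")))
  y2 <- domain_profile(c(a = 0.5, b = 0.5))
  expect_equal(log_likelihood(y2, refs2, 1), log(0.5))

  set.seed(21)
  for (i in 1:10) {
    inst <- rand_instance(sample(3:40, 1), 3)
    w <- rgamma(3, 1); w <- w / sum(w)
    expect_equal(log_likelihood(inst$profile, inst$refs, w),
                 oracle_loglik(inst$y, inst$X, w), tolerance = 1e-12)
  }
  expect_error(log_likelihood(y2, refs2, 2), "simplex")
})

test_that("EM log-likelihood trace is non-decreasing on random instances", {
  set.seed(22)
  for (i in 1:20) {
    inst <- rand_instance(sample(5:100, 1), sample(2:10, 1),
                          concentration = 0.5)
    fit <- em_fit(inst$profile, inst$refs)
    tr <- fit$loglik_trace
    expect_true(all(diff(tr) >= -1e-9 * pmax(abs(tr[-length(tr)]), 1)))
    expect_true(all(fit$weights >= 0))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  }
})

test_that("EM attains the concave optimum found by grid search", {
  set.seed(23)
  for (i in 1:5) {
    inst <- rand_instance(sample(5:60, 1), 3)
    fit <- em_fit(inst$profile, inst$refs)
    ll_em <- fit$loglik_trace[length(fit$loglik_trace)]
    expect_gte(ll_em, oracle_grid_search_k3(inst$y, inst$X) - 1e-6)
  }
})

test_that("EM recovers exact mixtures to high precision", {
  set.seed(24)
  X <- rand_refs_mat(50, 5)
  w_star <- rgamma(5, 1); w_star <- w_star / sum(w_star)
  y <- as.vector(X %*% w_star); names(y) <- rownames(X)
  fit <- em_fit(domain_profile(y), signature_matrix(X),
                fit_options(max_iter = 200000, rel_tol = 1e-15))
  expect_lt(sum(abs(fit$weights - w_star)), 1e-4)
  expect_lt(fit$fdu, 1e-6)
})

test_that("fdu is half the L1 distance with symmetric over/under mass", {
  p <- domain_profile(c(a = 0.6, b = 0.4))
  q <- domain_profile(c(a = 0.5, b = 0.5))
  expect_equal(fdu(p, q), 0.1)
  expect_identical(fdu(p, p), 0)
  expect_equal(fdu(domain_profile(c(a = 1, b = 0)),
                   domain_profile(c(a = 0, b = 1))), 1.0)
  expect_error(fdu(domain_profile(c(a = 2, b = 3), normalized = FALSE), q),
               "normalized")

  set.seed(25)
  for (i in 1:20) {
    D <- sample(2:50, 1)
    y <- rand_profile_vec(D); yh <- rand_profile_vec(D)
    under <- sum(pmax(y - yh, 0))
    over <- sum(pmax(yh - y, 0))
    expect_equal(under, over, tolerance = 1e-12)
    d <- fdu(domain_profile(y), domain_profile(yh))
    expect_equal(d, under, tolerance = 1e-12)
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("fdu and bray_curtis are the same statistic", {
  set.seed(26)
  for (i in 1:10) {
    D <- sample(2:30, 1)
    y <- rand_profile_vec(D); yh <- rand_profile_vec(D)
    expect_identical(fdu(domain_profile(y), domain_profile(yh)),
                     bray_curtis(taxonomic_profile(y, "phylum"),
                                 taxonomic_profile(yh, "phylum")))
  }
})

test_that("bray_curtis compares profiles over the union of taxa", {
  p <- taxonomic_profile(c(A = 1), "superkingdom")
  q <- taxonomic_profile(c(B = 1), "superkingdom")
  expect_equal(bray_curtis(p, q), 1.0)
  expect_identical(bray_curtis(p, p), 0)
  r <- taxonomic_profile(c(A = 0.7, B = 0.3), "superkingdom")
  s <- taxonomic_profile(c(A = 0.4, B = 0.6), "superkingdom")
  expect_equal(bray_curtis(r, s), 0.3)
  expect_equal(bray_curtis(r, s), bray_curtis(s, r))
  expect_error(bray_curtis(p, taxonomic_profile(c(A = 1), "phylum")),
               "rank mismatch")
})

test_that("aggregate_weights sums weights per taxon and conserves mass", {
  tax <- toy_taxonomy(c("sigA", "sigB", "sigC"),
                      c("Bacteria", "Archaea", "Viruses"))
  w <- c(sigA = 0.6, sigB = 0.3, sigC = 0.1)
  tp <- aggregate_weights(w, tax, rank = "superkingdom")
  expect_equal(tp$abundances[c("Bacteria", "Archaea", "Viruses")],
               c(Bacteria = 0.6, Archaea = 0.3, Viruses = 0.1))
})

test_that("signatures without a rank annotation land in unclassified", {
  tax <- taxonomy_table(data.frame(
    signature_id = c("gen1", "vir1"),
    source_type = c("genome", "metagenome"),
    superkingdom = c("Bacteria", "Viruses"),
    phylum = c("Proteobacteria", NA),
    stringsAsFactors = FALSE))
  tp <- aggregate_weights(c(gen1 = 0.8, vir1 = 0.2), tax, rank = "phylum")
  expect_equal(tp$abundances[["unclassified Viruses"]], 0.2)
  expect_equal(tp$abundances[["Proteobacteria"]], 0.8)
})

test_that("aggregation conserves total weight for random taxonomies", {
  set.seed(27)
  for (i in 1:10) {
    K <- sample(3:15, 1)
    ids <- sprintf("s%02d", seq_len(K))
    sk <- sample(c("Bacteria", "Archaea", "Viruses"), K, replace = TRUE)
    phyla <- ifelse(runif(K) < 0.4, NA, sprintf("phy%d", sample(1:3, K, TRUE)))
    tax <- taxonomy_table(data.frame(
      signature_id = ids, source_type = "genome", superkingdom = sk,
      phylum = phyla, stringsAsFactors = FALSE))
    w <- rgamma(K, 1); w <- w / sum(w); names(w) <- ids
    for (rk in c("superkingdom", "phylum", "species")) {
      tp <- aggregate_weights(w, tax, rank = rk)
      expect_equal(sum(tp$abundances), 1, tolerance = 1e-9)
    }
  }
})

test_that("aggregate_weights reports unknown signature ids", {
  tax <- toy_taxonomy("sigA", "Bacteria")
  expect_error(aggregate_weights(c(sigA = 0.5, ghost = 0.5), tax), "ghost")
})

test_that("renormalize_subset rescales the kept taxa to unit sum", {
  tp <- taxonomic_profile(c(Archaea = 0.2, Bacteria = 0.6, Viruses = 0.2),
                          "superkingdom")
  sub <- renormalize_subset(tp, c("Archaea", "Bacteria"))
  expect_equal(sub$abundances, c(Archaea = 0.25, Bacteria = 0.75))
  same <- renormalize_subset(tp, names(tp$abundances))
  expect_equal(same$abundances, tp$abundances)
  zero <- taxonomic_profile(c(Archaea = 0, Bacteria = 0, Viruses = 1),
                            "superkingdom")
  expect_error(renormalize_subset(zero, c("Archaea", "Bacteria")),
               "no positive abundance")
})
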