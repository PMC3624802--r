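# Synthetic data generators. They emulate the statistical structure the
# mixture model assumes: reference signatures are sparse frequency vectors
# over many domain families (Dirichlet draws, one concentration per
# superkingdom group), a metagenome profile is a convex combination of
# signatures observed through multinomial sampling of a finite number of
# domain hits, and reads receive hits independently with a fixed
# probability. All generators are pure functions of their arguments and
# seed.

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- base::matrix(stats::rgamma(n * k, shape = alpha), nrow = n,
                    byrow = TRUE)
  # guard against all-zero rows at very small concentrations
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- stats::rgamma(sum(zero) * k, shape = 1)
  g / rowSums(g)
}

#' Specification of a synthetic profiling study
#'
#' Bundles the parameters of the synthetic ground-truth world: how many
#' domain families and reference signatures exist, how references are
#' distributed over superkingdoms, how sparse their signatures are, and how
#' the observed metagenome is sampled. The default superkingdom proportions
#' mirror the composition of a realistic reference collection (dominated by
#' bacteria, with few archaeal and eukaryotic genomes and a small viral
#' contingent, half of it metagenome-derived), and the default sampling
#' depth of 100000 domain hits with a per-read hit probability of 0.7
#' reflects a well-covered short-read survey.
#'
#' @param n_families number of domain families (default 2000).
#' @param n_references number of reference signatures (default 20).
#' @param group_proportions named numeric vector of superkingdom
#'   proportions used to apportion references (each group gets at least
#'   one).
#' @param alpha named numeric vector: Dirichlet concentration per group;
#'   smaller values give sparser signatures.
#' @param true_weights optional mixture weights on the simplex (length
#'   `n_references`); when `NULL`, weights are drawn from a flat Dirichlet
#'   at generation time.
#' @param n_hits number of multinomially sampled domain hits.
#' @param hit_probability probability that a read carries a domain hit;
#'   the planted fraction of sequences unexplained is `1 - hit_probability`.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(
    n_families = 2000L, n_references = 20L,
    group_proportions = c(Bacteria = 0.825, Archaea = 0.058,
                          Eukaryota = 0.024, Viruses = 0.093),
    alpha = c(Bacteria = 0.02, Archaea = 0.05, Eukaryota = 0.1,
              Viruses = 0.2),
    true_weights = NULL, n_hits = 100000L, hit_probability = 0.7) {
  stopifnot(is_scalar_number(n_families), n_families >= 2,
            is_scalar_number(n_references), n_references >= 1,
            is_scalar_number(n_hits), n_hits >= 0,
            is_scalar_number(hit_probability),
            hit_probability >= 0, hit_probability <= 1)
  if (is.null(names(group_proportions)) ||
      !setequal(names(group_proportions), names(alpha)))
    stop("group_proportions and alpha must be named by the same groups")
  if (any(group_proportions <= 0) || any(alpha <= 0))
    stop("group proportions and alpha must be positive")
  if (!is.null(true_weights)) {
    true_weights <- as.numeric(true_weights)
    if (length(true_weights) != n_references || any(true_weights < 0) ||
        abs(sum(true_weights) - 1) > 1e-9)
      stop("true_weights must be a simplex vector of length n_references")
  }
  structure(list(n_families = as.integer(n_families),
                 n_references = as.integer(n_references),
                 group_proportions = group_proportions / sum(group_proportions),
                 alpha = alpha[names(group_proportions)],
                 true_weights = true_weights,
                 n_hits = as.integer(n_hits),
                 hit_probability = hit_probability),
            class = "simulation_spec")
}

# Apportion n_references to groups: at least one each, remainder by
# largest fractional part (ties by group order).
.group_counts <- function(spec) {
  p <- spec$group_proportions
  k <- spec$n_references
  if (k < length(p))
    stop("n_references must be at least the number of groups")
  raw <- p * k
  cnt <- floor(raw)
  cnt[cnt < 1] <- 1
  while (sum(cnt) > k) {                     # min-1 overshoot at small k
    big <- which(cnt > 1)
    i <- big[which.max((cnt - raw)[big])]
    cnt[i] <- cnt[i] - 1L
  }
  frac <- raw - floor(raw)
  while (sum(cnt) < k) {
    i <- order(-frac)[1L]
    cnt[i] <- cnt[i] + 1L
    frac[i] <- -Inf
  }
  cnt
}

#' Generate ground-truth reference signatures with taxonomy
#'
#' Draws each reference signature from a per-group Dirichlet over the
#' family universe and builds the matching taxonomy table. Viral
#' references are split between `genome` and `metagenome` source types
#' (alternating); metagenome-derived viral signatures carry only
#' `superkingdom = "Viruses"`, all other references get a full synthetic
#' lineage (two phyla per group, one class/order/family/genus/species line
#' per reference).
#'
#' @param spec a [simulation_spec()].
#' @param seed integer seed.
#' @return A list with `refs` (a [signature_matrix()]) and `taxonomy`
#'   (a [taxonomy_table()]).
#' @export
gen_reference_signatures <- function(spec = simulation_spec(), seed = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  cnt <- .group_counts(spec)
  fam <- sprintf("PF%05d", seq_len(spec$n_families))
  with_seed(seed, {
    cols <- vector("list", length(cnt))
    rows <- vector("list", length(cnt))
    for (gi in seq_along(cnt)) {
      grp <- names(cnt)[gi]
      kg <- cnt[[gi]]
      sig <- t(.rdirichlet(kg, rep(spec$alpha[[grp]], spec$n_families)))
      ids <- sprintf("%s_sig%03d", grp, seq_len(kg))
      colnames(sig) <- ids
      cols[[gi]] <- sig
      is_meta <- grp == "Viruses" & (seq_len(kg) %% 2L == 0L)
      phylum <- sprintf("%s_phylum_%d", grp, (seq_len(kg) %% 2L) + 1L)
      rows[[gi]] <- data.frame(
        signature_id = ids,
        source_type = ifelse(is_meta, "metagenome", "genome"),
        superkingdom = grp,
        phylum = ifelse(is_meta, NA, phylum),
        class = ifelse(is_meta, NA, sprintf("%s_class", phylum)),
        order = ifelse(is_meta, NA, sprintf("%s_order_%d", grp, seq_len(kg))),
        family = ifelse(is_meta, NA, sprintf("%s_family_%d", grp, seq_len(kg))),
        genus = ifelse(is_meta, NA, sprintf("%s_genus_%d", grp, seq_len(kg))),
        species = ifelse(is_meta, NA, sprintf("%s_species_%d", grp, seq_len(kg))),
        stringsAsFactors = FALSE)
    }
    m <- do.call(cbind, cols)
    rownames(m) <- fam
    list(refs = signature_matrix(m),
         taxonomy = taxonomy_table(do.call(rbind, rows)))
  })
}

#' Sample a metagenome profile from a known mixture
#'
#' Forms the exact mixture `p = refs %*% weights` and either returns it
#' directly (`exact = TRUE`, the noise-free in-hull case) or draws
#' `n_hits` domain hits from the categorical distribution `p` and returns
#' the empirical frequencies (multinomial sampling noise).
#'
#' @param refs a [signature_matrix()].
#' @param weights true mixture weights on the simplex (named or in column
#'   order of `refs`).
#' @param n_hits number of hits to sample (ignored when `exact`).
#' @param seed integer seed.
#' @param exact logical; return the exact mixture without sampling.
#' @return A list with `profile` (a [domain_profile()]) and
#'   `true_weights` (named).
#' @export
gen_mixture_sample <- function(refs, weights, n_hits = 100000L, seed = 1L,
                               exact = FALSE) {
  stopifnot(inherits(refs, "signature_matrix"))
  weights <- as.numeric(weights)
  if (length(weights) != ncol(refs) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("weights must be a simplex vector, one entry per signature")
  names(weights) <- colnames(refs)
  p <- as.vector(unclass(refs) %*% weights)
  names(p) <- rownames(refs)
  if (exact) {
    prof <- domain_profile(p, normalized = TRUE)
  } else {
    if (n_hits < 1L) stop("n_hits must be >= 1 unless exact = TRUE")
    cnt <- with_seed(seed, stats::rmultinom(1L, size = n_hits, prob = p))
    prof <- normalize_profile(stats::setNames(as.numeric(cnt), rownames(refs)),
                              total_hits = n_hits)
  }
  list(profile = prof, true_weights = weights)
}

#' Generate a per-read hit table with planted FSU
#'
#' Each of `n_reads` reads independently receives one domain hit with
#' probability `hit_probability`; hit families are drawn from `profile`.
#' The planted fraction of sequences unexplained is
#' `1 - hit_probability`.
#'
#' @param profile a [domain_profile()] to draw hit families from.
#' @param n_reads number of reads.
#' @param hit_probability per-read hit probability in `[0, 1]`.
#' @param seed integer seed.
#' @return A [domain_hit_table()].
#' @export
gen_hit_table <- function(profile, n_reads, hit_probability, seed = 1L) {
  stopifnot(inherits(profile, "domain_profile"),
            is_scalar_number(n_reads), n_reads >= 1,
            is_scalar_number(hit_probability),
            hit_probability >= 0, hit_probability <= 1)
  n_reads <- as.integer(n_reads)
  with_seed(seed, {
    hit <- stats::runif(n_reads) < hit_probability
    fams <- if (any(hit))
      sample(profile$family_ids, sum(hit), replace = TRUE,
             prob = profile$values)
    else character(0)
    domain_hit_table(sprintf("read%07d", which(hit)), fams,
                     total_reads = n_reads)
  })
}

# Symmetric Kullback-Leibler divergence between two distributions.
.sym_kl <- function(p, q) sum((p - q) * log(p / q))

#' Generate a two-class profile set with planted contamination
#'
#' Builds two Dirichlet classes of row-normalized domain profiles whose
#' class means are tilted apart along a random log-linear direction until
#' their symmetric Kullback-Leibler divergence equals `separation`
#' (`separation = 0` gives statistically indistinguishable classes).
#' `n_flipped` candidate-class (+1) samples are drawn from the opposing
#' class distribution instead — planted contamination whose ids are
#' recorded in the `flipped_ids` attribute.
#'
#' @param n_per_class samples per class.
#' @param n_families number of domain families.
#' @param separation symmetric KL divergence between the class mean
#'   distributions (>= 0).
#' @param n_flipped number of planted contaminated samples in the +1
#'   class; must be smaller than `n_per_class`.
#' @param seed integer seed.
#' @param concentration Dirichlet concentration (total pseudo-mass) of
#'   the within-class sampling; larger values give tighter classes
#'   (default 100).
#' @return A [labeled_profile_set()] with attribute `flipped_ids`.
#' @export
gen_classification_dataset <- function(n_per_class, n_families = 100L,
                                       separation = 3, n_flipped = 0L,
                                       seed = 1L, concentration = 100) {
  stopifnot(is_scalar_number(n_per_class), n_per_class >= 2,
            is_scalar_number(n_families), n_families >= 2,
            is_scalar_number(separation), separation >= 0,
            is_scalar_number(n_flipped), n_flipped >= 0,
            is_scalar_number(concentration), concentration > 0)
  if (n_flipped >= n_per_class)
    stop("n_flipped must be smaller than n_per_class")
  with_seed(seed, {
    base_mean <- as.vector(.rdirichlet(1L, rep(5, n_families)))
    u <- stats::rnorm(n_families)
    if (separation == 0) {
      m_pos <- m_neg <- base_mean
    } else {
      tilt <- function(t) {
        mp <- base_mean * exp(t * u / 2); mp <- mp / sum(mp)
        mn <- base_mean * exp(-t * u / 2); mn <- mn / sum(mn)
        list(mp = mp, mn = mn)
      }
      f <- function(t) {
        m <- tilt(t)
        .sym_kl(m$mp, m$mn) - separation
      }
      hi <- 1
      while (f(hi) < 0 && hi < 64) hi <- hi * 2
      t_star <- stats::uniroot(f, c(0, hi), tol = 1e-10)$root
      m <- tilt(t_star)
      m_pos <- m$mp; m_neg <- m$mn
    }
    n_clean_pos <- n_per_class - n_flipped
    pos <- .rdirichlet(n_clean_pos, concentration * m_pos)
    flip <- if (n_flipped > 0) .rdirichlet(n_flipped, concentration * m_neg)
    neg <- .rdirichlet(n_per_class, concentration * m_neg)
    profiles <- rbind(pos, flip, neg)
    colnames(profiles) <- sprintf("PF%05d", seq_len(n_families))
    ids <- c(sprintf("viral_%03d", seq_len(n_per_class)),
             sprintf("microbial_%03d", seq_len(n_per_class)))
    rownames(profiles) <- ids
    flipped_ids <- if (n_flipped > 0)
      sprintf("viral_%03d", seq.int(n_clean_pos + 1L, n_per_class))
    else character(0)
    out <- labeled_profile_set(profiles,
                               labels = rep(c(1, -1), each = n_per_class))
    attr(out, "flipped_ids") <- flipped_ids
    out
  })
}

#' Generate random DNA sequences
#'
#' Uniform ACGT sequences with seeded lengths, for exercising
#' fragmentation and length filtering.
#'
#' @param n_seqs number of sequences.
#' @param length_range integer vector `c(min, max)` of sequence lengths.
#' @param seed integer seed.
#' @return A `Biostrings::DNAStringSet` named `contig_001`, ...
#' @export
gen_random_fasta <- function(n_seqs, length_range = c(500L, 5000L),
                             seed = 1L) {
  stopifnot(is_scalar_number(n_seqs), n_seqs >= 0,
            length(length_range) == 2L, all(length_range >= 1),
            length_range[1] <= length_range[2])
  if (n_seqs == 0L) return(Biostrings::DNAStringSet())
  with_seed(seed, {
    lens <- sample.int(length_range[2] - length_range[1] + 1L, n_seqs,
                       replace = TRUE) + length_range[1] - 1L
    seqs <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("contig_%03d", seq_len(n_seqs))
    out
  })
}

#' Write a complete synthetic fixture bundle to a directory
#'
#' Generates, from one seed, everything the profiling pipeline consumes:
#' reference signatures with taxonomy, a mixed metagenome profile drawn
#' from known true weights, the per-read hit table behind it, a small
#' random FASTA, and a `truth.json` recording the ground truth (true
#' weights, superkingdom fractions, planted FSU, seed).
#'
#' @param spec a [simulation_spec()].
#' @param seed integer seed; all generator seeds are derived from it.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a named list of the written file paths.
#' @export
simulate_bundle <- function(spec = simulation_spec(), seed = 1L, out_dir) {
  stopifnot(inherits(spec, "simulation_spec"), !missing(out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 4L))
  gen <- gen_reference_signatures(spec, seed = seeds[1L])
  w_true <- spec$true_weights %||%
    with_seed(seeds[2L],
              as.vector(.rdirichlet(1L, rep(1, spec$n_references))))
  samp <- gen_mixture_sample(gen$refs, w_true, n_hits = spec$n_hits,
                             seed = seeds[3L])
  n_reads <- as.integer(ceiling(spec$n_hits / max(spec$hit_probability, 1e-12)))
  hits <- gen_hit_table(samp$profile, n_reads = n_reads,
                        hit_probability = spec$hit_probability,
                        seed = seeds[4L])
  fasta <- gen_random_fasta(5L, c(50000L, 150000L), seed = seeds[4L])

  paths <- list(
    refs = file.path(out_dir, "signatures.tsv"),
    taxonomy = file.path(out_dir, "taxonomy.tsv"),
    profile = file.path(out_dir, "profile.tsv"),
    hits = file.path(out_dir, "hits.tsv"),
    fasta = file.path(out_dir, "genomes.fasta"),
    truth = file.path(out_dir, "truth.json"))
  write_signature_table(gen$refs, paths$refs)
  write_taxonomy_table(gen$taxonomy, paths$taxonomy)
  write_profile_table(samp$profile, paths$profile)
  write_hit_table(hits, paths$hits)
  Biostrings::writeXStringSet(fasta, paths$fasta)
  truth_sk <- aggregate_weights(samp$true_weights, gen$taxonomy,
                                rank = "superkingdom")
  jsonlite::write_json(
    list(seed = as.integer(seed),
         true_weights = as.list(samp$true_weights),
         superkingdom_fractions = as.list(truth_sk$abundances),
         planted_fsu = 1 - spec$hit_probability,
         n_hits = spec$n_hits,
         n_reads = n_reads),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
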