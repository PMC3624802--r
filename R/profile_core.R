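#' Domain frequency profile
#'
#' A `domain_profile` holds the relative frequencies of protein domain
#' families (e.g. Pfam accessions) observed in a sequence collection: the
#' vector `y` that the mixture model reconstructs. Family identifiers are
#' opaque strings; they are stored in lexicographic (C collation) order so
#' that all outputs are byte-stable.
#'
#' @param values numeric vector of nonnegative values, named by family id
#'   unless `family_ids` is given.
#' @param family_ids character vector of unique family identifiers, parallel
#'   to `values`.
#' @param total_hits optional nonnegative integer: the number of domain hits
#'   the frequencies were computed from.
#' @param normalized logical; when `TRUE` (default) the values must sum to 1
#'   within `1e-9`.
#' @return An object of class `domain_profile`: a list with elements
#'   `family_ids`, `values` (named numeric, same order), `total_hits` and
#'   `normalized`.
#' @examples
#' domain_profile(c(PF_A = 0.5, PF_B = 0.25, PF_C = 0.25))
#' @seealso [normalize_profile()], [align_families()]
#' @export
domain_profile <- function(values, family_ids = names(values),
                           total_hits = NULL, normalized = TRUE) {
  if (is.null(family_ids))
    stop("family ids are required (give named values or `family_ids`)")
  family_ids <- as.character(family_ids)
  values <- as.numeric(values)
  if (length(values) == 0L)
    stop("invalid profile: empty profile")
  if (length(values) != length(family_ids))
    stop("`values` and `family_ids` lengths differ")
  if (anyNA(values) || anyNA(family_ids))
    stop("invalid profile: NA values or family ids")
  if (any(values < 0))
    stop("invalid profile: negative values")
  if (anyDuplicated(family_ids))
    stop("invalid profile: duplicated family ids: ",
         paste(unique(family_ids[duplicated(family_ids)]), collapse = ", "))
  if (!is.null(total_hits)) {
    stopifnot(is_scalar_number(total_hits), total_hits >= 0)
    total_hits <- as.integer(round(total_hits))
  }
  if (isTRUE(normalized) && abs(sum(values) - 1) > 1e-9)
    stop(sprintf("invalid profile: values sum to %.12g, not 1", sum(values)))
  ord <- order(family_ids, method = "radix")
  values <- values[ord]
  family_ids <- family_ids[ord]
  names(values) <- family_ids
  structure(
    list(family_ids = family_ids, values = values,
         total_hits = total_hits, normalized = isTRUE(normalized)),
    class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf("<domain_profile> %d families, sum = %.6f%s\n",
              length(x$values), sum(x$values),
              if (is.null(x$total_hits)) ""
              else sprintf(", total_hits = %d", x$total_hits)))
  top <- utils::head(x$values[order(-x$values)], 5L)
  for (i in seq_along(top))
    cat(sprintf("  %s  %.6g\n", names(top)[i], top[[i]]))
  if (length(x$values) > 5L) cat("  ...\n")
  invisible(x)
}

#' Normalize raw domain counts or values to relative frequencies
#'
#' Divides a nonnegative vector keyed by family id by its sum so that the
#' result is a valid, unit-sum [domain_profile()]. Inputs that already sum
#' to 1 within `1e-9` are passed through unchanged, which makes the
#' operation exactly idempotent. When the input consists of integer counts,
#' their total is preserved in `total_hits`.
#'
#' @param x named nonnegative numeric vector (counts or values), or a
#'   `domain_profile`.
#' @param total_hits optional override for the underlying hit count.
#' @return A normalized `domain_profile`.
#' @examples
#' normalize_profile(c(PF_A = 2, PF_B = 1, PF_C = 1))
#' @export
normalize_profile <- function(x, total_hits = NULL) {
  if (inherits(x, "domain_profile")) {
    total_hits <- total_hits %||% x$total_hits
    x <- x$values
  }
  if (length(x) == 0L) stop("invalid profile: empty input")
  if (is.null(names(x))) stop("invalid profile: values must be named by family id")
  if (anyNA(x)) stop("invalid profile: NA values")
  if (any(x < 0)) stop("invalid profile: negative values")
  s <- sum(x)
  if (s <= 0) stop("invalid profile: all values are zero")
  if (is.null(total_hits) && all(x == round(x)))
    total_hits <- as.integer(round(s))
  v <- if (abs(s - 1) <= 1e-9) x else x / s
  domain_profile(v, total_hits = total_hits, normalized = TRUE)
}

#' Reference signature matrix
#'
#' A `signature_matrix` is the column-stochastic matrix whose columns are
#' the precalculated reference signatures `x_i`: relative domain family
#' frequencies of a reference genome or reference metagenome. Rows are
#' domain families (lexicographic order), columns are references.
#'
#' @param matrix nonnegative numeric matrix, rows = families, columns =
#'   references; every column must sum to 1 within `1e-9`.
#' @param family_ids,signature_ids row and column identifiers; default to
#'   `rownames`/`colnames` of `matrix`.
#' @return An object of class `signature_matrix` (a numeric matrix with
#'   dimnames and a class attribute).
#' @export
signature_matrix <- function(matrix, family_ids = rownames(matrix),
                             signature_ids = colnames(matrix)) {
  m <- base::matrix(as.numeric(matrix), nrow = nrow(matrix), ncol = ncol(matrix))
  if (is.null(family_ids) || is.null(signature_ids))
    stop("signature matrix needs family ids (rows) and signature ids (columns)")
  family_ids <- as.character(family_ids)
  signature_ids <- as.character(signature_ids)
  stopifnot(length(family_ids) == nrow(m), length(signature_ids) == ncol(m))
  if (nrow(m) == 0L || ncol(m) == 0L) stop("signature matrix must be non-empty")
  if (anyNA(m)) stop("signature matrix contains NA")
  if (any(m < 0)) stop("signature matrix contains negative values")
  if (anyDuplicated(family_ids))
    stop("duplicated family ids in signature matrix")
  if (anyDuplicated(signature_ids))
    stop("duplicated signature ids: ",
         paste(unique(signature_ids[duplicated(signature_ids)]), collapse = ", "))
  cs <- colSums(m)
  bad <- which(abs(cs - 1) > 1e-9)
  if (length(bad))
    stop("signature columns must sum to 1; offending: ",
         paste(sprintf("%s (%.12g)", signature_ids[utils::head(bad, 5L)],
                       cs[utils::head(bad, 5L)]), collapse = ", "))
  ord <- order(family_ids, method = "radix")
  m <- m[ord, , drop = FALSE]
  dimnames(m) <- list(family_ids[ord], signature_ids)
  structure(m, class = c("signature_matrix", "matrix", "array"))
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d families x %d signatures\n",
              nrow(x), ncol(x)))
  cat("  signatures:", paste(utils::head(colnames(x), 5L), collapse = ", "),
      if (ncol(x) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Table of per-read domain hits
#'
#' Records which domain family each read (or other sequence unit) hit,
#' together with the total number of reads in the dataset. A read may carry
#' several hits; `total_reads` must therefore be at least the number of
#' distinct read ids. This is the raw material for both the frequency
#' profile (per hit) and the fraction of sequences unexplained (per read).
#'
#' @param read_id,family_id parallel character vectors, one entry per hit.
#' @param total_reads positive integer, the total number of reads including
#'   those without any hit.
#' @return An object of class `domain_hit_table`: a data frame with columns
#'   `read_id` and `family_id` and attribute `total_reads`.
#' @export
domain_hit_table <- function(read_id, family_id, total_reads) {
  read_id <- as.character(read_id)
  family_id <- as.character(family_id)
  stopifnot(length(read_id) == length(family_id))
  if (anyNA(read_id) || anyNA(family_id))
    stop("hit table contains NA ids")
  stopifnot(is_scalar_number(total_reads), total_reads >= 1)
  total_reads <- as.integer(round(total_reads))
  n_hit_reads <- length(unique(read_id))
  if (total_reads < n_hit_reads)
    stop(sprintf("total_reads (%d) < number of distinct reads with hits (%d)",
                 total_reads, n_hit_reads))
  structure(
    data.frame(read_id = read_id, family_id = family_id,
               stringsAsFactors = FALSE),
    total_reads = total_reads,
    class = c("domain_hit_table", "data.frame"))
}

#' @export
print.domain_hit_table <- function(x, ...) {
  cat(sprintf("<domain_hit_table> %d hits on %d of %d reads, %d families\n",
              nrow(x), length(unique(x$read_id)), attr(x, "total_reads"),
              length(unique(x$family_id))))
  invisible(x)
}

#' Total number of reads underlying a hit table
#' @param hits a [domain_hit_table()].
#' @return integer scalar.
#' @export
total_reads <- function(hits) {
  stopifnot(inherits(hits, "domain_hit_table"))
  attr(hits, "total_reads")
}

.tax_ranks <- c("superkingdom", "phylum", "class", "order",
                "family", "genus", "species")

#' Taxonomy table for reference signatures
#'
#' Maps each reference signature id to a rank-structured lineage
#' (superkingdom down to species) and a source type: `genome` for
#' signatures computed from (fragmented) genome sequences, `metagenome` for
#' signatures computed from whole metagenomes (typically viromes, which
#' carry only `superkingdom = "Viruses"`). Every record must have a
#' non-empty superkingdom; lower ranks may be `NA`.
#'
#' @param x data frame with columns `signature_id`, `source_type` and the
#'   seven ranks `superkingdom` ... `species` (missing rank columns are
#'   added as `NA`). Empty strings are treated as `NA`.
#' @return An object of class `taxonomy_table` (a data frame).
#' @export
taxonomy_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("signature_id", "source_type")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("taxonomy table lacks columns: ", paste(miss, collapse = ", "))
  for (r in .tax_ranks) if (!r %in% names(x)) x[[r]] <- NA_character_
  x <- x[, c(need, .tax_ranks)]
  for (j in seq_along(x)) {
    x[[j]] <- as.character(x[[j]])
    x[[j]][!is.na(x[[j]]) & x[[j]] == ""] <- NA_character_
  }
  if (nrow(x) == 0L) stop("taxonomy table is empty")
  if (anyNA(x$signature_id) || anyDuplicated(x$signature_id))
    stop("taxonomy table signature ids must be unique and non-missing")
  bad <- !x$source_type %in% c("genome", "metagenome")
  if (any(bad))
    stop("source_type must be 'genome' or 'metagenome'; offending: ",
         paste(utils::head(x$signature_id[bad], 5L), collapse = ", "))
  nosk <- is.na(x$superkingdom)
  if (any(nosk))
    stop("every taxonomy record needs a superkingdom; missing for: ",
         paste(utils::head(x$signature_id[nosk], 5L), collapse = ", "))
  rownames(x) <- NULL
  structure(x, class = c("taxonomy_table", "data.frame"))
}

#' Taxonomic abundance profile
#'
#' Relative abundances of taxa at one taxonomic rank, as produced by
#' [aggregate_weights()]. An explicit `"unclassified <superkingdom>"` taxon
#' absorbs the weight of signatures without an annotation at the rank, so
#' the fractions always sum to 1.
#'
#' @param abundances named nonnegative numeric vector, one entry per taxon;
#'   must sum to 1 within `1e-9`.
#' @param rank the rank name (e.g. `"superkingdom"`, `"phylum"`).
#' @return An object of class `taxonomic_profile`.
#' @export
taxonomic_profile <- function(abundances, rank) {
  stopifnot(is.character(rank), length(rank) == 1L, nzchar(rank))
  v <- as.numeric(abundances)
  nm <- names(abundances)
  if (is.null(nm) || anyNA(nm) || anyDuplicated(nm))
    stop("abundances must be uniquely named by taxon")
  if (length(v) == 0L || anyNA(v) || any(v < 0))
    stop("abundances must be nonnegative and non-empty")
  if (abs(sum(v) - 1) > 1e-9)
    stop(sprintf("abundances sum to %.12g, not 1", sum(v)))
  ord <- order(nm, method = "radix")
  v <- v[ord]; names(v) <- nm[ord]
  structure(list(rank = rank, abundances = v), class = "taxonomic_profile")
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  cat(sprintf("<taxonomic_profile> rank = %s\n", x$rank))
  ab <- x$abundances[order(-x$abundances)]
  for (i in seq_along(ab))
    cat(sprintf("  %-30s %7.4f\n", names(ab)[i], ab[[i]]))
  invisible(x)
}

#' Align a profile and a signature matrix on one family universe
#'
#' The mixture model requires the metagenome profile `y` and the reference
#' signatures `x_i` to be indexed by the same domain families. This takes
#' the union of both family universes (so observed domains absent from all
#' references stay in `y` and are correctly charged to the approximation
#' error), fills missing entries with zero, and orders families
#' lexicographically. No renormalization takes place: profile values and
#' column sums are unchanged.
#'
#' @param profile a [domain_profile()].
#' @param refs a [signature_matrix()].
#' @return A list with elements `profile` and `refs`, both over the union
#'   universe.
#' @export
align_families <- function(profile, refs) {
  stopifnot(inherits(profile, "domain_profile"),
            inherits(refs, "signature_matrix"))
  fam <- lex_sort(union(profile$family_ids, rownames(refs)))
  v <- stats::setNames(numeric(length(fam)), fam)
  v[profile$family_ids] <- profile$values
  p <- domain_profile(v, total_hits = profile$total_hits,
                      normalized = profile$normalized)
  m <- base::matrix(0, nrow = length(fam), ncol = ncol(refs),
                    dimnames = list(fam, colnames(refs)))
  m[rownames(refs), ] <- unclass(refs)
  list(profile = p, refs = signature_matrix(m))
}
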