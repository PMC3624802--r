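#' Fragment genome sequences into half-overlapping windows
#'
#' Domain frequency signatures depend on sequence length, so genomic
#' reference sequences are cut into short, half-overlapping fragments
#' before domain detection to make genome-derived and metagenome-derived
#' signatures comparable. Defaults: 400 bp fragments advanced by 200 bp
#' (half overlap).
#'
#' Fragments start at `0, step, 2*step, ...` as long as a full fragment
#' fits. When the last full fragment leaves at least `min_tail` bp of the
#' sequence uncovered, one extra fragment anchored at the end,
#' `(L - fragment_length, L)`, is emitted. Sequences shorter than
#' `fragment_length` but at least `min_tail` long yield a single
#' whole-sequence fragment; shorter sequences yield none (with a warning).
#'
#' @param sequences a `Biostrings::DNAStringSet`, or a named character
#'   vector of sequences, or a named integer vector of sequence lengths.
#' @param fragment_length fragment size in bp; must be even when `step` is
#'   left at its default of half the fragment length.
#' @param step distance between consecutive fragment starts in bp.
#' @param min_tail smallest uncovered tail (bp) worth an extra anchored
#'   fragment; also the minimum length for a whole-sequence fragment.
#' @return An object of class `fragment_set`: a data frame with columns
#'   `source_id`, `start`, `end` (0-based, half-open) and attributes
#'   `fragment_length` and `step`.
#' @examples
#' fragment_sequences(c(chr = 1000L), fragment_length = 400)
#' @export
fragment_sequences <- function(sequences, fragment_length = 400L,
                               step = fragment_length %/% 2L,
                               min_tail = step) {
  default_step <- missing(step)
  stopifnot(is_scalar_number(fragment_length), fragment_length >= 2,
            is_scalar_number(step), step >= 1,
            is_scalar_number(min_tail), min_tail >= 1)
  if (default_step && fragment_length %% 2L != 0L)
    stop("fragment_length must be even for half-overlapping fragments")
  fragment_length <- as.integer(fragment_length)
  step <- as.integer(step)
  min_tail <- as.integer(min_tail)

  lens <- .sequence_lengths(sequences)
  if (length(lens) == 0L) stop("no input sequences")
  out <- vector("list", length(lens))
  dropped <- character(0)
  for (i in seq_along(lens)) {
    L <- lens[[i]]
    id <- names(lens)[i]
    if (L >= fragment_length) {
      starts <- seq.int(0L, L - fragment_length, by = step)
      last_end <- starts[length(starts)] + fragment_length
      if (L - last_end >= min_tail)
        starts <- c(starts, L - fragment_length)
      out[[i]] <- data.frame(source_id = id, start = starts,
                             end = starts + fragment_length,
                             stringsAsFactors = FALSE)
    } else if (L >= min_tail) {
      out[[i]] <- data.frame(source_id = id, start = 0L, end = L,
                             stringsAsFactors = FALSE)
    } else {
      dropped <- c(dropped, id)
    }
  }
  if (length(dropped))
    warning("sequences too short to fragment (< min_tail), skipped: ",
            paste(utils::head(dropped, 10L), collapse = ", "))
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(source_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, fragment_length = fragment_length, step = step,
            class = c("fragment_set", "data.frame"))
}

.sequence_lengths <- function(sequences) {
  if (inherits(sequences, "XStringSet")) {
    lens <- Biostrings::width(sequences)
    names(lens) <- names(sequences)
  } else if (is.character(sequences)) {
    lens <- nchar(sequences)
    names(lens) <- names(sequences)
  } else if (is.numeric(sequences)) {
    lens <- as.integer(sequences)
    names(lens) <- names(sequences)
  } else stop("unsupported sequence container: ", class(sequences)[1L])
  if (is.null(names(lens)) || any(!nzchar(names(lens))))
    stop("sequences must be named")
  lens
}

#' Extract fragment sequences as a DNAStringSet
#'
#' @param sequences the sequences that were fragmented (`DNAStringSet` or
#'   named character vector).
#' @param fragments a [fragment_sequences()] result.
#' @return A `Biostrings::DNAStringSet` with names `<source_id>:<start>-<end>`
#'   (0-based, half-open).
#' @export
extract_fragments <- function(sequences, fragments) {
  stopifnot(inherits(fragments, "fragment_set"))
  if (!inherits(sequences, "XStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  miss <- setdiff(unique(fragments$source_id), names(sequences))
  if (length(miss))
    stop("fragment sources absent from sequences: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  idx <- match(fragments$source_id, names(sequences))
  out <- Biostrings::subseq(sequences[idx], start = fragments$start + 1L,
                            end = fragments$end)
  names(out) <- sprintf("%s:%d-%d", fragments$source_id, fragments$start,
                        fragments$end)
  out
}

#' Filter sequences by minimum length
#'
#' Short genomes do not provide enough sequence for a stable domain
#' frequency signature; phage genomes in particular are only used as
#' references when strictly longer than 100 kbp.
#'
#' @param sequences a `Biostrings::DNAStringSet` or named character vector.
#' @param min_bp keep records with length strictly greater than this
#'   (default 100000).
#' @return The input container filtered, original order preserved.
#' @export
filter_min_length <- function(sequences, min_bp = 100000L) {
  stopifnot(is_scalar_number(min_bp), min_bp >= 0)
  lens <- if (inherits(sequences, "XStringSet")) Biostrings::width(sequences)
          else nchar(sequences)
  sequences[lens > min_bp]
}

#' Domain frequency profile from a hit table
#'
#' The value of family `f` is the number of hits to `f` divided by the
#' total number of hits. Counting is per hit, not per read: a read with
#' several domain hits contributes each of them.
#'
#' @param hits a [domain_hit_table()] with at least one hit.
#' @return A normalized [domain_profile()] with `total_hits` set.
#' @export
profile_from_hits <- function(hits) {
  stopifnot(inherits(hits, "domain_hit_table"))
  if (nrow(hits) == 0L) stop("hit table contains no hits")
  cnt <- table(hits$family_id)
  normalize_profile(stats::setNames(as.numeric(cnt), names(cnt)),
                    total_hits = nrow(hits))
}

#' Fraction of sequences unexplained (FSU)
#'
#' The fraction of reads without any domain hit:
#' `1 - (#distinct reads with >= 1 hit) / total_reads`. A read with several
#' hits counts once as explained. Together with [fdu()], the FSU
#' characterizes the reliability of a composition estimate: FSU measures
#' the statistical coverage of the profile, FDU the model approximation
#' error.
#'
#' @param hits a [domain_hit_table()].
#' @return scalar in `[0, 1]`.
#' @export
fsu <- function(hits) {
  stopifnot(inherits(hits, "domain_hit_table"))
  tr <- total_reads(hits)
  1 - length(unique(hits$read_id)) / tr
}

#' Build a signature matrix from per-reference hit tables
#'
#' Each reference's hit table is converted to a frequency profile with
#' [profile_from_hits()]; profiles are aligned on the union of their family
#' universes (zero fill) and become the columns of a column-stochastic
#' [signature_matrix()]. References without any hit are skipped with a
#' warning; every retained reference must have a taxonomy record.
#'
#' @param hit_tables named list of [domain_hit_table()]s, one per reference
#'   signature, names = signature ids.
#' @param taxonomy a [taxonomy_table()] covering all reference ids.
#' @return A [signature_matrix()].
#' @export
build_signature_matrix <- function(hit_tables, taxonomy) {
  stopifnot(is.list(hit_tables), length(hit_tables) >= 1L,
            inherits(taxonomy, "taxonomy_table"))
  ids <- names(hit_tables)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("hit_tables must be uniquely named by signature id")
  miss <- setdiff(ids, taxonomy$signature_id)
  if (length(miss))
    stop("references without taxonomy record: ",
         paste(utils::head(miss, 10L), collapse = ", "))
  empty <- vapply(hit_tables, nrow, integer(1)) == 0L
  if (any(empty)) {
    warning("references without hits skipped: ",
            paste(ids[empty], collapse = ", "))
    hit_tables <- hit_tables[!empty]
    ids <- ids[!empty]
  }
  if (length(hit_tables) == 0L) stop("no reference has any hit")
  profiles <- lapply(hit_tables, profile_from_hits)
  fam <- lex_sort(unique(unlist(lapply(profiles, `[[`, "family_ids"))))
  m <- base::matrix(0, nrow = length(fam), ncol = length(profiles),
                    dimnames = list(fam, ids))
  for (k in seq_along(profiles))
    m[profiles[[k]]$family_ids, k] <- profiles[[k]]$values
  signature_matrix(m)
}
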