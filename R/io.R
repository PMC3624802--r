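# Plain TSV readers and writers for profiles, signature matrices, taxonomy
# tables, hit tables and taxonomic profiles. All files are UTF-8, LF,
# tab-separated, unquoted. Numeric values are written with %.17g so a
# write/read round trip reproduces doubles exactly.

.read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

.split_row <- function(line, n = NULL) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (!is.null(n) && length(f) < n) f <- c(f, rep("", n - length(f)))
  f
}

.parse_num <- function(x, path, lineno) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop(sprintf("%s: line %d: non-numeric value '%s'",
                 path, lineno, x[bad[1L]]))
  v
}

.fmt_num <- function(x) sprintf("%.17g", x)

#' Read and write domain profile tables
#'
#' Profile TSV format: header `family_id<TAB>value`, one row per family.
#'
#' @param path file path.
#' @param normalized whether the profile read is expected to be unit-sum
#'   (default `TRUE`); pass `FALSE` to read raw count tables.
#' @return `read_profile_table` returns a [domain_profile()];
#'   `write_profile_table` invisibly returns `path`.
#' @export
read_profile_table <- function(path, normalized = TRUE) {
  lines <- .read_tsv_lines(path)
  if (length(lines) < 1L || !identical(lines[1L], "family_id\tvalue"))
    stop(sprintf("%s: line 1: expected header 'family_id\\tvalue'", path))
  if (length(lines) < 2L) stop(path, ": profile table has no rows")
  ids <- character(length(lines) - 1L)
  vals <- numeric(length(lines) - 1L)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(ids)) {
    f <- .split_row(lines[i + 1L])
    if (length(f) != 2L)
      stop(sprintf("%s: line %d: expected 2 fields, got %d", path, i + 1L,
                   length(f)))
    if (!nzchar(f[1L]))
      stop(sprintf("%s: line %d: empty family id", path, i + 1L))
    if (!is.null(seen[[f[1L]]]))
      stop(sprintf("%s: line %d: duplicated family id '%s'", path, i + 1L,
                   f[1L]))
    seen[[f[1L]]] <- TRUE
    ids[i] <- f[1L]
    vals[i] <- .parse_num(f[2L], path, i + 1L)
  }
  names(vals) <- ids
  if (normalized) domain_profile(vals) else normalize_profile(vals)
}

#' @rdname read_profile_table
#' @param profile a [domain_profile()] to write.
#' @export
write_profile_table <- function(profile, path) {
  stopifnot(inherits(profile, "domain_profile"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("family_id\tvalue",
               paste(profile$family_ids, .fmt_num(profile$values), sep = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' Read and write signature matrix tables
#'
#' Signature TSV format: header `family_id<TAB><sig_id_1><TAB>...`, one
#' column per reference signature, one row per family.
#'
#' @param path file path.
#' @return `read_signature_table` returns a [signature_matrix()].
#' @export
read_signature_table <- function(path) {
  lines <- .read_tsv_lines(path)
  if (length(lines) < 1L) stop(path, ": empty file")
  hdr <- .split_row(lines[1L])
  if (length(hdr) < 2L || hdr[1L] != "family_id")
    stop(sprintf("%s: line 1: expected header 'family_id\\t<signature ids>'",
                 path))
  sig_ids <- hdr[-1L]
  if (anyDuplicated(sig_ids))
    stop(sprintf("%s: line 1: duplicated signature ids", path))
  if (length(lines) < 2L) stop(path, ": signature table has no rows")
  n <- length(lines) - 1L
  ids <- character(n)
  m <- base::matrix(0, nrow = n, ncol = length(sig_ids))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    f <- .split_row(lines[i + 1L])
    if (length(f) != length(hdr))
      stop(sprintf("%s: line %d: expected %d fields, got %d", path, i + 1L,
                   length(hdr), length(f)))
    if (!is.null(seen[[f[1L]]]))
      stop(sprintf("%s: line %d: duplicated family id '%s'", path, i + 1L,
                   f[1L]))
    seen[[f[1L]]] <- TRUE
    ids[i] <- f[1L]
    m[i, ] <- .parse_num(f[-1L], path, i + 1L)
  }
  dimnames(m) <- list(ids, sig_ids)
  signature_matrix(m)
}

#' @rdname read_signature_table
#' @param refs a [signature_matrix()] to write.
#' @export
write_signature_table <- function(refs, path) {
  stopifnot(inherits(refs, "signature_matrix"))
  m <- unclass(refs)
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], .fmt_num(m[i, ])), collapse = "\t"), character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(c("family_id", colnames(m)), collapse = "\t"), rows),
             con, sep = "\n")
  invisible(path)
}

.tax_header <- function() c("signature_id", "source_type", .tax_ranks)

#' Read and write taxonomy tables
#'
#' Taxonomy TSV format: header
#' `signature_id<TAB>source_type<TAB>superkingdom<TAB>...<TAB>species`;
#' cells below superkingdom may be empty.
#'
#' @param path file path.
#' @return `read_taxonomy_table` returns a [taxonomy_table()].
#' @export
read_taxonomy_table <- function(path) {
  lines <- .read_tsv_lines(path)
  if (length(lines) < 1L ||
      !identical(.split_row(lines[1L], length(.tax_header())), .tax_header()))
    stop(sprintf("%s: line 1: expected header '%s'", path,
                 paste(.tax_header(), collapse = "\\t")))
  if (length(lines) < 2L) stop(path, ": taxonomy table has no rows")
  n <- length(lines) - 1L
  rows <- base::matrix("", nrow = n, ncol = length(.tax_header()))
  for (i in seq_len(n)) {
    f <- .split_row(lines[i + 1L], length(.tax_header()))
    if (length(f) > length(.tax_header()))
      stop(sprintf("%s: line %d: expected at most %d fields, got %d", path,
                   i + 1L, length(.tax_header()), length(f)))
    rows[i, ] <- f
  }
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(df) <- .tax_header()
  tab <- tryCatch(taxonomy_table(df), error = function(e)
    stop(sprintf("%s: %s", path, conditionMessage(e)), call. = FALSE))
  tab
}

#' @rdname read_taxonomy_table
#' @param taxonomy a [taxonomy_table()] to write.
#' @export
write_taxonomy_table <- function(taxonomy, path) {
  stopifnot(inherits(taxonomy, "taxonomy_table"))
  m <- as.matrix(as.data.frame(taxonomy)[, .tax_header()])
  m[is.na(m)] <- ""
  rows <- apply(m, 1L, paste, collapse = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(.tax_header(), collapse = "\t"), rows), con, sep = "\n")
  invisible(path)
}

#' Read and write per-read domain hit tables
#'
#' Hit-table TSV format: a comment line `#total_reads=<N>`, then the header
#' `read_id<TAB>family_id`, then one row per hit.
#'
#' @param path file path.
#' @return `read_hit_table` returns a [domain_hit_table()].
#' @export
read_hit_table <- function(path) {
  lines <- .read_tsv_lines(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "#total_reads="))
    stop(sprintf("%s: line 1: expected '#total_reads=<N>'", path))
  tr <- suppressWarnings(as.integer(sub("^#total_reads=", "", lines[1L])))
  if (is.na(tr)) stop(sprintf("%s: line 1: malformed total_reads", path))
  if (!identical(lines[2L], "read_id\tfamily_id"))
    stop(sprintf("%s: line 2: expected header 'read_id\\tfamily_id'", path))
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body) == 0L)
    return(domain_hit_table(character(), character(), total_reads = tr))
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop(sprintf("%s: line %d: expected 2 fields, got %d", path,
                 which(nf != 2L)[1L] + 2L, nf[nf != 2L][1L]))
  domain_hit_table(vapply(parts, `[[`, character(1), 1L),
                   vapply(parts, `[[`, character(1), 2L),
                   total_reads = tr)
}

#' @rdname read_hit_table
#' @param hits a [domain_hit_table()] to write.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(inherits(hits, "domain_hit_table"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("#total_reads=%d", total_reads(hits)),
               "read_id\tfamily_id",
               paste(hits$read_id, hits$family_id, sep = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' Read and write taxonomic abundance tables
#'
#' Aggregate-report TSV format: header `taxon<TAB>abundance`.
#'
#' @param path file path.
#' @param rank the rank the abundances refer to.
#' @return `read_taxonomic_profile` returns a [taxonomic_profile()].
#' @export
read_taxonomic_profile <- function(path, rank = "superkingdom") {
  lines <- .read_tsv_lines(path)
  if (length(lines) < 2L || !identical(lines[1L], "taxon\tabundance"))
    stop(sprintf("%s: line 1: expected header 'taxon\\tabundance'", path))
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop(sprintf("%s: line %d: expected 2 fields", path,
                 which(nf != 2L)[1L] + 1L))
  v <- .parse_num(vapply(parts, `[[`, character(1), 2L), path, 2L)
  names(v) <- vapply(parts, `[[`, character(1), 1L)
  taxonomic_profile(v, rank = rank)
}

#' @rdname read_taxonomic_profile
#' @param profile a [taxonomic_profile()] to write.
#' @export
write_taxonomic_profile <- function(profile, path) {
  stopifnot(inherits(profile, "taxonomic_profile"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("taxon\tabundance",
               paste(names(profile$abundances),
                     .fmt_num(profile$abundances), sep = "\t")),
             con, sep = "\n")
  invisible(path)
}
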