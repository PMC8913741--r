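#' Construct an MSA object
#'
#' An `msa` holds aligned rows of a multiple sequence alignment after a3m
#' normalization (lowercase insertion states removed), together with the
#' original headers, parsed organism identifiers and the 0-based rank of
#' each row in its source file (rank 0 is the query).
#'
#' @param headers character vector of FASTA headers (without the leading
#'   `>`).
#' @param sequences character vector of aligned sequences over `A-Z` and
#'   `-`, all of equal width.
#' @param organism_id optional integer vector of NCBI taxon identifiers
#'   (`NA` where the header carries no `OX=` token). Parsed from
#'   `headers` when omitted.
#' @param rank optional integer vector of 0-based source ranks; defaults
#'   to `seq_along(headers) - 1L`.
#'
#' @return An object of class `msa`: a list with elements `header`,
#'   `sequence`, `organism_id`, `rank`.
#' @export
msa <- function(headers, sequences, organism_id = NULL, rank = NULL) {
  headers <- as.character(headers)
  sequences <- toupper(as.character(sequences))
  if (length(headers) != length(sequences))
    stop("headers and sequences must have the same length")
  if (length(sequences) == 0L)
    stop("an MSA must contain at least the query row")
  widths <- nchar(sequences)
  if (length(unique(widths)) > 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf(
      "aligned rows differ in length after normalization: record %d ('%s') has width %d, query has width %d",
      bad, substr(headers[bad], 1L, 40L), widths[bad], widths[1L]))
  }
  if (is.null(organism_id)) organism_id <- parse_ox(headers)
  if (is.null(rank)) rank <- seq_along(headers) - 1L
  structure(
    list(header = headers, sequence = sequences,
         organism_id = as.integer(organism_id), rank = as.integer(rank)),
    class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("MSA: %d rows x %d columns (%d with organism id)\n",
              n_rows(x), query_length(x), sum(!is.na(x$organism_id))))
  invisible(x)
}

#' Number of rows in an MSA
#' @param m an `msa`.
#' @export
n_rows <- function(m) length(m$sequence)

#' Query (row 0) width of an MSA
#' @param m an `msa`.
#' @export
query_length <- function(m) nchar(m$sequence[1L])

# UniProt-style `OX=<digits>` taxonomy token -> integer, NA when absent
parse_ox <- function(headers) {
  hit <- regmatches(headers, regexpr("\\bOX=([0-9]+)", headers))
  out <- rep(NA_integer_, length(headers))
  found <- grepl("\\bOX=([0-9]+)", headers)
  out[found] <- as.integer(sub("^OX=", "", hit))
  out
}

#' Read an a3m/FASTA alignment
#'
#' Parses an a3m (or plain aligned FASTA) file. Lowercase letters and
#' `.` characters, which in a3m mark insertions relative to the query
#' columns, are deleted so that every row has the query's width.
#' `OX=<digits>` tokens in headers (UniProt convention) are parsed into
#' organism identifiers.
#'
#' @param path path to an a3m or FASTA file.
#' @return An [msa] object.
#' @export
read_a3m <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L)
    stop("a3m format error: file is empty: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L)
    stop("a3m format error: no records in ", path)
  raw <- as.character(set)
  normalized <- gsub("[a-z.]", "", raw)
  msa(headers = names(set), sequences = normalized)
}

#' Write an MSA as single-line FASTA/a3m
#'
#' Inverse of [read_a3m] for normalized alignments:
#' `read_a3m(write_a3m(m))` reproduces rows, headers and organism ids.
#'
#' @param m an [msa].
#' @param path output path.
#' @export
write_a3m <- function(m, path) {
  stopifnot(inherits(m, "msa"))
  if (n_rows(m) == 0L) stop("refusing to write an empty MSA")
  lines <- as.vector(rbind(paste0(">", m$header), m$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Remove rows dominated by gaps
#'
#' Drops every non-query row whose gap fraction strictly exceeds
#' `max_gap_fraction` (default 0.9: rows with more than 90% gaps are
#' removed). The query row is always retained, as it defines the column
#' coordinate system that pairing and fusion rely on.
#'
#' @param m an [msa].
#' @param max_gap_fraction rows with gap fraction strictly greater than
#'   this are removed; in (0, 1].
#' @return A filtered [msa]; idempotent.
#' @export
filter_gapped_rows <- function(m, max_gap_fraction = 0.9) {
  stopifnot(inherits(m, "msa"),
            max_gap_fraction > 0, max_gap_fraction <= 1)
  gaps <- nchar(gsub("[^-]", "", m$sequence))
  frac <- gaps / nchar(m$sequence)
  keep <- frac <= max_gap_fraction
  keep[1L] <- TRUE
  msa(m$header[keep], m$sequence[keep],
      organism_id = m$organism_id[keep], rank = m$rank[keep])
}

#' Pair two chain alignments by organism
#'
#' For every organism present (via `OX=` taxonomy) among the hits of
#' both alignments, the highest-ranked (lowest row index) hit of chain A
#' is concatenated with the highest-ranked hit of chain B from the same
#' organism, exposing inter-chain coevolutionary signal. Row 0 of the
#' result is the concatenated query pair. Hits without an organism id
#' are ignored; organisms found in only one alignment contribute
#' nothing.
#'
#' @param msa_a,msa_b gap-filtered [msa] objects for the two chains.
#' @return An [msa] (class `c("paired_msa", "msa")`) of width
#'   `query_length(msa_a) + query_length(msa_b)`, with a `provenance`
#'   attribute: a data.frame of `organism_id`, `rank_a`, `rank_b` per
#'   paired row.
#' @export
pair_by_organism <- function(msa_a, msa_b) {
  stopifnot(inherits(msa_a, "msa"), inherits(msa_b, "msa"))
  hit_idx_a <- which(seq_len(n_rows(msa_a)) > 1L & !is.na(msa_a$organism_id))
  hit_idx_b <- which(seq_len(n_rows(msa_b)) > 1L & !is.na(msa_b$organism_id))
  shared <- intersect(msa_a$organism_id[hit_idx_a], msa_b$organism_id[hit_idx_b])

  # best (lowest-rank) hit per shared organism in each alignment
  best_a <- vapply(shared, function(org)
    hit_idx_a[which(msa_a$organism_id[hit_idx_a] == org)[1L]], integer(1))
  best_b <- vapply(shared, function(org)
    hit_idx_b[which(msa_b$organism_id[hit_idx_b] == org)[1L]], integer(1))
  ord <- order(best_a)
  best_a <- best_a[ord]; best_b <- best_b[ord]; shared <- shared[ord]

  headers <- c(paste(msa_a$header[1L], msa_b$header[1L], sep = " | "),
               paste(msa_a$header[best_a], msa_b$header[best_b], sep = " | "))
  seqs <- c(paste0(msa_a$sequence[1L], msa_b$sequence[1L]),
            paste0(msa_a$sequence[best_a], msa_b$sequence[best_b]))
  out <- msa(headers, seqs,
             organism_id = c(NA_integer_, as.integer(shared)))
  attr(out, "provenance") <- data.frame(
    organism_id = as.integer(shared),
    rank_a = msa_a$rank[best_a],
    rank_b = msa_b$rank[best_b])
  class(out) <- c("paired_msa", "msa")
  out
}

#' Block-diagonalize two chain alignments
#'
#' Stacks the two per-chain alignments into one alignment over the
#' concatenated query: row 0 is the concatenated query pair; every
#' non-query row of chain A is elongated with gaps on the right to the
#' combined width, and every non-query row of chain B is elongated with
#' gaps on the left. No pairing information is used; intra-chain signal
#' is preserved without asserting any inter-chain correspondence.
#'
#' @param msa_a,msa_b [msa] objects for the two chains.
#' @return An [msa] with `1 + (n_rows(msa_a)-1) + (n_rows(msa_b)-1)`
#'   rows of width `query_length(msa_a) + query_length(msa_b)`.
#' @export
block_diagonalize <- function(msa_a, msa_b) {
  stopifnot(inherits(msa_a, "msa"), inherits(msa_b, "msa"))
  l1 <- query_length(msa_a); l2 <- query_length(msa_b)
  pad_r <- strrep("-", l2); pad_l <- strrep("-", l1)
  ia <- setdiff(seq_len(n_rows(msa_a)), 1L)
  ib <- setdiff(seq_len(n_rows(msa_b)), 1L)
  pad_right <- if (length(ia)) paste0(msa_a$sequence[ia], pad_r) else character(0)
  pad_left <- if (length(ib)) paste0(pad_l, msa_b$sequence[ib]) else character(0)
  msa(
    headers = c(paste(msa_a$header[1L], msa_b$header[1L], sep = " | "),
                msa_a$header[ia], msa_b$header[ib]),
    sequences = c(paste0(msa_a$sequence[1L], msa_b$sequence[1L]),
                  pad_right, pad_left),
    organism_id = c(NA_integer_, msa_a$organism_id[ia], msa_b$organism_id[ib]))
}

#' Fuse alignments sharing a query
#'
#' Concatenates the rows of several alignments built over the same
#' (typically concatenated two-chain) query — e.g. a paired and a
#' block-diagonalized alignment — keeping the shared query row once.
#'
#' @param parts list of [msa] objects whose row-0 sequences are
#'   identical.
#' @return A single fused [msa].
#' @export
fuse_msas <- function(parts) {
  stopifnot(is.list(parts), length(parts) >= 1L,
            all(vapply(parts, inherits, logical(1), "msa")))
  q <- parts[[1L]]$sequence[1L]
  for (i in seq_along(parts)) {
    if (!identical(parts[[i]]$sequence[1L], q))
      stop(sprintf("query mismatch: part %d has a different row-0 sequence", i))
  }
  headers <- parts[[1L]]$header[1L]
  seqs <- q
  orgs <- parts[[1L]]$organism_id[1L]
  for (p in parts) {
    idx <- setdiff(seq_len(n_rows(p)), 1L)
    headers <- c(headers, p$header[idx])
    seqs <- c(seqs, p$sequence[idx])
    orgs <- c(orgs, p$organism_id[idx])
  }
  msa(headers, seqs, organism_id = orgs)
}
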