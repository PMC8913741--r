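#' Effective number of sequences by greedy clustering
#'
#' Estimates the information content of an alignment as the number of
#' clusters obtained by greedy single-pass clustering at a sequence
#' identity threshold (default 62%), in the spirit of CD-HIT-style
#' clustering. Rows are visited in order of decreasing ungapped length
#' (stable on ties); a row joins the first cluster whose representative
#' it matches at `identity_threshold` or higher with coverage of at
#' least `coverage_threshold`, otherwise it founds a new cluster. The
#' cluster count is the Neff value.
#'
#' Identity and coverage are computed directly on the aligned rows:
#' over the columns where both rows are non-gap, identity is the number
#' of identical residues divided by the shorter row's ungapped length,
#' and coverage is the number of shared non-gap columns divided by the
#' same denominator. This operates on the alignment as given rather
#' than re-aligning ungapped sequences, so it is deterministic and
#' alignment-consistent; no word-size pre-filter is used.
#'
#' @param m an [msa].
#' @param identity_threshold minimum fractional identity to join a
#'   cluster (default 0.62).
#' @param coverage_threshold minimum fractional coverage of the shorter
#'   sequence (default 0.9).
#' @return A list of class `neff_result`: `n_clusters` (the Neff
#'   value), and `cluster_assignment`, an integer vector mapping each
#'   input row (in input order) to its cluster index.
#' @export
compute_neff <- function(m, identity_threshold = 0.62,
                         coverage_threshold = 0.9) {
  stopifnot(inherits(m, "msa"), n_rows(m) >= 1L,
            identity_threshold > 0, identity_threshold <= 1,
            coverage_threshold > 0, coverage_threshold <= 1)
  chars <- do.call(rbind, strsplit(m$sequence, "", fixed = TRUE))
  nongap <- chars != "-"
  ungapped <- rowSums(nongap)
  visit <- order(-ungapped)               # stable: ties keep input order

  rep_rows <- integer(0)                  # representative row index per cluster
  assignment <- integer(n_rows(m))
  for (i in visit) {
    placed <- FALSE
    for (ci in seq_along(rep_rows)) {
      r <- rep_rows[ci]
      shorter <- min(ungapped[i], ungapped[r])
      if (shorter == 0L) {
        ok <- ungapped[i] == 0L && ungapped[r] == 0L   # all-gap rows cluster together
      } else {
        both <- nongap[i, ] & nongap[r, ]
        coverage <- sum(both) / shorter
        identity <- sum(chars[i, ] == chars[r, ] & both) / shorter
        ok <- identity >= identity_threshold && coverage >= coverage_threshold
      }
      if (ok) {
        assignment[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_rows <- c(rep_rows, i)
      assignment[i] <- length(rep_rows)
    }
  }
  structure(list(n_clusters = length(rep_rows),
                 cluster_assignment = assignment),
            class = "neff_result")
}

#' @export
print.neff_result <- function(x, ...) {
  cat(sprintf("Neff = %d (from %d rows)\n",
              x$n_clusters, length(x$cluster_assignment)))
  invisible(x)
}
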