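#' Confusion counts at a score threshold
#'
#' Builds the confusion matrix used to rank docking models: predictions
#' with `score >= threshold` are called positive (the boundary is
#' inclusive, matching the "DockQ >= 0.23" convention), and `labels`
#' say which instances are truly positive (e.g. acceptable models).
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector of the same length.
#' @param threshold decision threshold.
#' @return list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  stopifnot(length(scores) >= 1L, !anyNA(scores), !anyNA(labels))
  pos <- scores >= threshold
  structure(list(tp = sum(pos & labels), fp = sum(pos & !labels),
                 tn = sum(!pos & !labels), fn = sum(!pos & labels)),
            class = "confusion_counts")
}

#' Confusion-matrix rates
#'
#' TPR = TP/(TP+FN), FPR = FP/(FP+TN), PPV = TP/(TP+FP) and
#' FDR = 1 - PPV. A rate whose denominator is zero is returned as
#' `NA` (undefined).
#'
#' @param cc a `confusion_counts` (or list with tp/fp/tn/fn).
#' @return list with `tpr`, `fpr`, `ppv`, `fdr`.
#' @export
rates <- function(cc) {
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  ppv <- safe_div(cc$tp, cc$tp + cc$fp)
  list(tpr = safe_div(cc$tp, cc$tp + cc$fn),
       fpr = safe_div(cc$fp, cc$fp + cc$tn),
       ppv = ppv,
       fdr = if (is.na(ppv)) NA_real_ else 1 - ppv)
}

#' Empirical ROC curve and AUC
#'
#' Sweeps the decision threshold over all distinct score values (plus a
#' +Inf sentinel so the curve starts at (0, 0)) and records TPR against
#' FPR; the area under the curve is computed by trapezoidal
#' integration, which on tie-free data equals the Mann-Whitney
#' concordant-pair probability.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector; both classes must be present.
#' @return list of class `roc_curve`: `thresholds` (descending), `tpr`,
#'   `fpr`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (length(unique(labels)) < 2L)
    stop("ROC requires both positive and negative labels")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  np <- sum(labels); nn <- sum(!labels)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / nn, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d operating points, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' TPR at a bounded FPR
#'
#' The highest true-positive rate achieved by any operating point of
#' the curve whose false-positive rate does not exceed `fpr_level`
#' (conservative step interpolation: reported operating points are
#' actually achievable, nothing is interpolated).
#'
#' @param roc a [roc_curve].
#' @param fpr_level maximum tolerated FPR, in \[0, 1\].
#' @return The achievable TPR (0 if no point qualifies beyond the
#'   origin sentinel).
#' @export
tpr_at_fpr <- function(roc, fpr_level) {
  stopifnot(inherits(roc, "roc_curve"), fpr_level >= 0, fpr_level <= 1)
  ok <- roc$fpr <= fpr_level
  if (!any(ok)) return(0)
  max(roc$tpr[ok])
}

#' Success rate
#'
#' Fraction of models whose DockQ reaches the acceptable threshold
#' (default 0.23, boundary inclusive).
#'
#' @param dockqs numeric vector of DockQ scores.
#' @param threshold acceptability threshold.
#' @return fraction in \[0, 1\].
#' @export
success_rate <- function(dockqs, threshold = 0.23) {
  stopifnot(length(dockqs) >= 1L, !anyNA(dockqs))
  mean(dockqs >= threshold)
}

#' Precision of top-N inter-chain coupling signals
#'
#' Assesses a direct-coupling-analysis (or other coupling) score matrix
#' between the columns of two chains: with N the number of true
#' interface contacts, the N highest-scoring inter-chain cells are
#' taken (ties broken deterministically in row-major order) and the PPV
#' is the fraction of them that are true contacts.
#'
#' @param coupling numeric matrix (rows = chain-A positions, columns =
#'   chain-B positions) of coupling scores.
#' @param native_contacts two-column matrix or data.frame of true
#'   contact index pairs (i in A, j in B).
#' @return list of class `dca_assessment`: `n_true_contacts`,
#'   `n_correct_in_top_n`, `ppv`, and `top_cells` (the selected index
#'   pairs).
#' @export
dca_interface_ppv <- function(coupling, native_contacts) {
  coupling <- as.matrix(coupling)
  stopifnot(all(is.finite(coupling)))
  nc <- unique(as.data.frame(native_contacts)[, 1:2])
  names(nc) <- c("i", "j")
  if (nrow(nc) == 0L) stop("native contact set is empty")
  if (any(nc$i < 1L | nc$i > nrow(coupling) | nc$j < 1L | nc$j > ncol(coupling)))
    stop("native contact indices outside the coupling matrix")
  n <- nrow(nc)
  cells <- data.frame(i = as.vector(row(coupling)),
                      j = as.vector(col(coupling)),
                      s = as.vector(coupling))
  cells <- cells[order(-cells$s, cells$i, cells$j), , drop = FALSE]
  top <- cells[seq_len(min(n, nrow(cells))), , drop = FALSE]
  correct <- sum(paste(top$i, top$j) %in% paste(nc$i, nc$j))
  structure(list(n_true_contacts = n, n_correct_in_top_n = correct,
                 ppv = correct / n,
                 top_cells = top[, c("i", "j")]),
            class = "dca_assessment")
}

#' Interface secondary-structure class
#'
#' Collapses DSSP 8-state annotations of interface residues into three
#' categories — helix (H: alpha, G: 3-10, I: pi), sheet (E: strand,
#' B: isolated bridge) and loop (everything else) — and returns the
#' majority class. Ties are broken toward the more structured class
#' (helix > sheet > loop).
#'
#' @param dssp_states character string (or vector of single
#'   characters) of DSSP states over the interface residues. Allowed
#'   states: `H G I E B T S C - ~` and space.
#' @return `"helix"`, `"sheet"` or `"loop"`.
#' @export
interface_ss_class <- function(dssp_states) {
  chars <- unlist(strsplit(paste(dssp_states, collapse = ""), "", fixed = TRUE))
  if (length(chars) == 0L) stop("empty secondary-structure annotation")
  known <- c("H", "G", "I", "E", "B", "T", "S", "C", "-", "~", " ")
  bad <- setdiff(unique(chars), known)
  if (length(bad))
    stop("unknown DSSP state character(s): ", paste(bad, collapse = " "))
  counts <- c(helix = sum(chars %in% c("H", "G", "I")),
              sheet = sum(chars %in% c("E", "B")))
  counts <- c(counts, loop = length(chars) - sum(counts))
  names(counts)[which.max(counts)]   # which.max: first max, order helix > sheet > loop
}

#' Tertile binning
#'
#' Splits a numeric vector into three bins at the 1/3 and 2/3
#' empirical quantiles, for stratified breakdowns (e.g. by interface
#' contact count). On tie-free data the bin sizes differ by at most 1.
#'
#' @param values numeric vector, length >= 3.
#' @return list of class `tertile_split`: `bins` (list of three numeric
#'   vectors `low`, `mid`, `high`), `breaks` (the two quantiles),
#'   `assignment` (1/2/3 per input value) and `degenerate` (TRUE when
#'   the two breaks coincide).
#' @export
tertile_split <- function(values) {
  stopifnot(is.numeric(values), !anyNA(values))
  if (length(values) < 3L) stop("need at least 3 values for tertiles")
  q <- stats::quantile(values, probs = c(1, 2) / 3, names = FALSE)
  assignment <- ifelse(values <= q[1L], 1L, ifelse(values <= q[2L], 2L, 3L))
  structure(list(
    bins = list(low = values[assignment == 1L],
                mid = values[assignment == 2L],
                high = values[assignment == 3L]),
    breaks = q,
    assignment = assignment,
    degenerate = q[1L] == q[2L]), class = "tertile_split")
}
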