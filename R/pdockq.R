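#' pDockQ sigmoid parameters
#'
#' The four parameters of the pDockQ sigmoid
#' `pDockQ = L / (1 + exp(-k (x - x0))) + b`, where
#' `x = IF_plDDT * log(IF_contacts)`. Defaults are the published fit
#' (L = 0.724, x0 = 152.611, k = 0.052, b = 0.018) with log base 10;
#' the midpoint x0 ~ 153 is consistent with plDDT in [0, 100] times
#' log10 of typical contact counts.
#'
#' @param L amplitude (> 0).
#' @param x0 sigmoid midpoint, in x-units (plDDT times log contacts).
#' @param k steepness (> 0), 1/x-units.
#' @param b baseline offset.
#' @param log_base base of the logarithm in the combined metric x
#'   (10 or `exp(1)`).
#' @return An object of class `pdockq_params`.
#' @export
pdockq_params <- function(L = 0.724, x0 = 152.611, k = 0.052, b = 0.018,
                          log_base = 10) {
  stopifnot(L > 0, k > 0, log_base > 1)
  structure(list(L = L, x0 = x0, k = k, b = b, log_base = log_base),
            class = "pdockq_params")
}

#' @export
print.pdockq_params <- function(x, ...) {
  cat(sprintf("pdockq_params: L = %.4g, x0 = %.4f, k = %.4g, b = %.4g (log base %.4g)\n",
              x$L, x$x0, x$k, x$b, x$log_base))
  if (!is.null(attr(x, "residual_mae")))
    cat(sprintf("  fit residual MAE = %.4f\n", attr(x, "residual_mae")))
  invisible(x)
}

pdockq_sigmoid <- function(x, params) {
  params$L / (1 + exp(-params$k * (x - params$x0))) + params$b
}

#' Combined interface confidence metric x
#'
#' The predictor variable of the pDockQ sigmoid: the mean interface
#' plDDT multiplied by the logarithm of the number of interface
#' contacts. Undefined (NA) when the model has no interface contacts.
#'
#' @param metrics an [interface_metrics] object.
#' @param log_base logarithm base (default 10).
#' @return x, or `NA_real_` for an empty interface.
#' @export
pdockq_x <- function(metrics, log_base = 10) {
  stopifnot(inherits(metrics, "interface_metrics"))
  if (metrics$empty_interface || metrics$n_if_contacts == 0L)
    return(NA_real_)
  metrics$if_plddt * log(metrics$n_if_contacts, base = log_base)
}

#' pDockQ confidence score
#'
#' Evaluates the pDockQ sigmoid at the model's combined interface
#' metric. Models with no interface contacts score 0 by convention
#' (no predicted interface — this is what makes pDockQ usable as a
#' non-interactor signal), rather than the sigmoid floor `b`.
#'
#' @param metrics an [interface_metrics] object, or a numeric vector of
#'   precomputed x values (in which case the empty-interface convention
#'   does not apply and `NA` propagates).
#' @param params a [pdockq_params] (defaults to the published fit).
#' @return The pDockQ score(s), strictly increasing in x.
#' @export
pdockq_score <- function(metrics, params = pdockq_params()) {
  stopifnot(inherits(params, "pdockq_params"))
  if (inherits(metrics, "interface_metrics")) {
    x <- pdockq_x(metrics, log_base = params$log_base)
    if (is.na(x)) return(0.0)
    return(pdockq_sigmoid(x, params))
  }
  pdockq_sigmoid(as.numeric(metrics), params)
}

#' Re-fit the pDockQ sigmoid
#'
#' Fits the four-parameter sigmoid to observed (x, DockQ) pairs by
#' Levenberg-Marquardt nonlinear least squares. Initialization:
#' `L = max(dockq)`, `x0 = median(x)`, `k = 0.05`, `b = min(dockq)`;
#' box constraints `L` in (0, 1.5], `k` in (0, 1], `b` in [0, 0.5].
#'
#' @param x numeric predictor values (`IF_plDDT * log(IF_contacts)`).
#' @param dockq observed DockQ scores in \[0, 1\].
#' @param log_base recorded in the returned parameters (the fit itself
#'   operates on the supplied x).
#' @return A [pdockq_params] with attributes `residual_mae` (mean
#'   absolute residual) and `n` (points fitted).
#' @export
fit_pdockq <- function(x, dockq, log_base = 10) {
  x <- as.numeric(x); dockq <- as.numeric(dockq)
  keep <- is.finite(x) & is.finite(dockq)
  x <- x[keep]; dockq <- dockq[keep]
  if (length(x) < 8L)
    stop("need at least 8 finite (x, dockq) points to fit")
  if (length(unique(x)) < 2L)
    stop("x values are all equal: sigmoid fit is unidentifiable")
  if (diff(range(dockq)) == 0)
    stop("fit did not converge: all dockq values identical (flat objective)")
  start <- list(L = max(dockq), x0 = stats::median(x), k = 0.05,
                b = min(dockq))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      dockq ~ L / (1 + exp(-k * (x - x0))) + b,
      data = data.frame(x = x, dockq = dockq),
      start = start,
      lower = c(L = 1e-9, x0 = -Inf, k = 1e-9, b = 0),
      upper = c(L = 1.5, x0 = Inf, k = 1, b = 0.5),
      control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-9)),
    error = function(e) {
      stop(sprintf("fit did not converge: %s (initialization L=%.3g x0=%.3g k=%.3g b=%.3g)",
                   conditionMessage(e), start$L, start$x0, start$k, start$b))
    })
  cf <- stats::coef(fit)
  out <- pdockq_params(L = cf[["L"]], x0 = cf[["x0"]], k = cf[["k"]],
                       b = cf[["b"]], log_base = log_base)
  attr(out, "residual_mae") <- mean(abs(stats::resid(fit)))
  attr(out, "n") <- length(x)
  out
}

#' Rank complex models
#'
#' Orders a set of models for the same chain pair by a confidence
#' criterion, descending: either pDockQ (default) or the number of
#' interface residues. Ties keep input order; the top-ranked model is
#' flagged.
#'
#' @param models named list of [interface_metrics] (names are model
#'   labels), or an unnamed list (labels `model_1`, ...).
#' @param criterion `"pdockq"` or `"n_if_residues"`.
#' @param params [pdockq_params] used when `criterion = "pdockq"`.
#' @return data.frame with columns `model_label`, `pdockq`,
#'   `n_if_residues`, `n_if_contacts`, `rank`, `top1`, ordered by rank.
#' @export
rank_models <- function(models, criterion = c("pdockq", "n_if_residues"),
                        params = pdockq_params()) {
  criterion <- match.arg(criterion)
  if (inherits(models, "interface_metrics")) models <- list(models)
  stopifnot(is.list(models), length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "interface_metrics")))
  labels <- names(models)
  if (is.null(labels)) labels <- paste0("model_", seq_along(models))
  df <- data.frame(
    model_label = labels,
    pdockq = vapply(models, pdockq_score, numeric(1), params = params),
    n_if_residues = vapply(models, function(m) m$n_if_residues, integer(1)),
    n_if_contacts = vapply(models, function(m) m$n_if_contacts, integer(1)),
    stringsAsFactors = FALSE)
  key <- if (criterion == "pdockq") df$pdockq else df$n_if_residues
  ord <- order(-key)                     # stable: ties keep input order
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$top1 <- df$rank == 1L
  rownames(df) <- NULL
  df
}
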