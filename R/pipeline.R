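#' Pipeline run configuration
#'
#' Bundles the thresholds and options shared by the pipeline entry
#' points. The pDockQ interaction-call threshold defaults to 0.5; this
#' is a placeholder operating point, not a calibrated value — calibrate
#' on your own data via [roc_curve] (e.g. maximizing Youden's J) when a
#' hard call is needed.
#'
#' @param chain_a_id,chain_b_id chain identifiers in model PDB files.
#' @param contact_cutoff interface Cbeta cutoff, Angstrom.
#' @param dockq_threshold DockQ acceptability threshold.
#' @param pdockq_threshold pDockQ above which a model is called an
#'   interaction.
#' @param max_gap_fraction,identity_threshold,coverage_threshold MSA
#'   filtering and Neff clustering options (see [filter_gapped_rows],
#'   [compute_neff]).
#' @param params a [pdockq_params].
#' @param criterion ranking criterion for [rank_models].
#' @param strict passed to [read_complex].
#' @return list of class `run_config`.
#' @export
run_config <- function(chain_a_id = "A", chain_b_id = "B",
                       contact_cutoff = 8.0, dockq_threshold = 0.23,
                       pdockq_threshold = 0.5, max_gap_fraction = 0.9,
                       identity_threshold = 0.62, coverage_threshold = 0.9,
                       params = pdockq_params(),
                       criterion = c("pdockq", "n_if_residues"),
                       strict = FALSE) {
  criterion <- match.arg(criterion)
  stopifnot(contact_cutoff > 0, dockq_threshold > 0, pdockq_threshold > 0)
  structure(list(chain_a_id = chain_a_id, chain_b_id = chain_b_id,
                 contact_cutoff = contact_cutoff,
                 dockq_threshold = dockq_threshold,
                 pdockq_threshold = pdockq_threshold,
                 max_gap_fraction = max_gap_fraction,
                 identity_threshold = identity_threshold,
                 coverage_threshold = coverage_threshold,
                 params = params, criterion = criterion, strict = strict),
            class = "run_config")
}

#' Prepare fused alignments for a chain pair
#'
#' The MSA leg of the pipeline: reads the two per-chain a3m files,
#' removes rows with more than `max_gap_fraction` gaps, pairs hits by
#' organism, block-diagonalizes the two alignments, fuses the paired
#' and block alignments over the shared concatenated query, and writes
#' `paired.a3m`, `block.a3m`, `fused.a3m` plus a JSON report with row
#' counts, organisms paired and Neff of the paired and fused
#' alignments.
#'
#' @param msa_a_path,msa_b_path per-chain a3m files.
#' @param out_dir output directory (created if needed).
#' @param config a [run_config].
#' @return the report, invisibly (a list).
#' @export
run_prepare <- function(msa_a_path, msa_b_path, out_dir = ".",
                        config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  msa_a <- filter_gapped_rows(read_a3m(msa_a_path), config$max_gap_fraction)
  msa_b <- filter_gapped_rows(read_a3m(msa_b_path), config$max_gap_fraction)
  paired <- pair_by_organism(msa_a, msa_b)
  if (n_rows(paired) == 1L)
    warning("no shared organisms: paired alignment contains only the query")
  block <- block_diagonalize(msa_a, msa_b)
  fused <- fuse_msas(list(paired, block))
  write_a3m(paired, file.path(out_dir, "paired.a3m"))
  write_a3m(block, file.path(out_dir, "block.a3m"))
  write_a3m(fused, file.path(out_dir, "fused.a3m"))
  report <- list(
    input_a = msa_a_path, input_b = msa_b_path,
    rows_a = n_rows(msa_a), rows_b = n_rows(msa_b),
    paired_rows = n_rows(paired), block_rows = n_rows(block),
    fused_rows = n_rows(fused),
    organisms_paired = attr(paired, "provenance")$organism_id,
    neff_paired = compute_neff(paired, config$identity_threshold,
                               config$coverage_threshold)$n_clusters,
    neff_fused = compute_neff(fused, config$identity_threshold,
                              config$coverage_threshold)$n_clusters)
  jsonlite::write_json(report, file.path(out_dir, "prepare_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

#' Assess and rank predicted complex models
#'
#' The scoring leg of the pipeline: for each model PDB, extracts
#' interface metrics, computes the combined metric x and pDockQ, makes
#' an interaction call (pDockQ at or above the configured threshold),
#' and — when a native structure is supplied — scores the model with
#' DockQ. Rows are sorted by the configured ranking criterion
#' (descending, stable) with the top model flagged.
#'
#' @param model_paths character vector of model PDB paths.
#' @param native_path optional native PDB for DockQ scoring.
#' @param config a [run_config].
#' @param out_csv optional path for the report CSV.
#' @return data.frame, one row per model.
#' @export
run_assess <- function(model_paths, native_path = NULL,
                       config = run_config(), out_csv = NULL) {
  stopifnot(inherits(config, "run_config"), length(model_paths) >= 1L)
  native <- if (!is.null(native_path))
    read_complex(native_path, config$chain_a_id, config$chain_b_id,
                 strict = config$strict)
  rows <- lapply(model_paths, function(p) {
    cs <- tryCatch(
      read_complex(p, config$chain_a_id, config$chain_b_id,
                   strict = config$strict),
      error = function(e) { warning(sprintf("skipping %s: %s", p,
                                            conditionMessage(e))); NULL })
    if (is.null(cs)) return(NULL)
    m <- interface_metrics(cs, cutoff = config$contact_cutoff)
    row <- data.frame(
      model_label = basename(p),
      n_if_contacts = m$n_if_contacts, n_if_residues = m$n_if_residues,
      if_plddt = m$if_plddt, min_chain_plddt = m$min_chain_plddt,
      avg_plddt = m$avg_plddt,
      x = pdockq_x(m, log_base = config$params$log_base),
      pdockq = pdockq_score(m, config$params),
      stringsAsFactors = FALSE)
    row$interaction_call <- row$pdockq >= config$pdockq_threshold
    if (!is.null(native)) {
      dq <- dockq_score(cs, native,
                        acceptable_threshold = config$dockq_threshold)
      row$fnat <- dq$fnat; row$irms <- dq$irms; row$lrms <- dq$lrms
      row$dockq <- dq$dockq; row$acceptable <- dq$acceptable
    }
    row
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no model could be parsed")
  df <- do.call(rbind, rows)
  key <- if (config$criterion == "pdockq") df$pdockq else df$n_if_residues
  df <- df[order(-key), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$top1 <- df$rank == 1L
  rownames(df) <- NULL
  if (!is.null(out_csv)) utils::write.csv(df, out_csv, row.names = FALSE)
  df
}
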