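#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of one point set onto another: returns
#' the proper rotation (determinant +1) and translation minimizing the
#' RMSD between `moving` and `fixed`, together with that minimal RMSD.
#' The transform maps row-vector coordinates as
#' `aligned = moving %*% rotation + translation`.
#'
#' @param fixed,moving n x 3 coordinate matrices (same n, n >= 3,
#'   non-collinear).
#' @return list with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (Angstrom).
#' @export
superpose <- function(fixed, moving) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  stopifnot(ncol(fixed) == 3L, ncol(moving) == 3L)
  if (nrow(fixed) != nrow(moving))
    stop("fixed and moving must contain the same number of points")
  if (nrow(fixed) < 3L)
    stop("superposition requires at least 3 points")
  cf <- colMeans(fixed); cm <- colMeans(moving)
  Fc <- sweep(fixed, 2L, cf); Mc <- sweep(moving, 2L, cm)
  if (svd(Mc)$d[2L] < 1e-8 * max(1, svd(Mc)$d[1L]) ||
      svd(Fc)$d[2L] < 1e-8 * max(1, svd(Fc)$d[1L]))
    stop("degenerate geometry: points are (near-)collinear")
  s <- svd(crossprod(Mc, Fc))
  d <- sign(det(tcrossprod(s$u, s$v)))
  if (d == 0) d <- 1
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  aligned <- Mc %*% rot
  rmsd <- sqrt(mean(rowSums((aligned - Fc)^2)))
  list(rotation = rot, translation = cf - drop(cm %*% rot), rmsd = rmsd)
}

apply_superposition <- function(coords, sp) {
  sweep(as.matrix(coords) %*% sp$rotation, 2L, -sp$translation)
}

#' Combine DockQ components
#'
#' The continuous docking-quality score from its three CAPRI-derived
#' components: `dockq = (fnat + 1/(1+(irms/1.5)^2) + 1/(1+(lrms/8.5)^2)) / 3`.
#'
#' @param fnat fraction of native inter-chain contacts preserved.
#' @param irms interface backbone RMSD (Angstrom).
#' @param lrms ligand backbone RMSD after receptor superposition.
#' @return DockQ in \[0, 1\].
#' @export
dockq_combine <- function(fnat, irms, lrms) {
  (fnat + 1 / (1 + (irms / 1.5)^2) + 1 / (1 + (lrms / 8.5)^2)) / 3
}

# atoms carried per residue: backbone N, CA, C plus the Cbeta
residue_atoms <- function(df) {
  cols <- list(CB = c("x", "y", "z"), N = c("n_x", "n_y", "n_z"),
               CA = c("ca_x", "ca_y", "ca_z"), C = c("c_x", "c_y", "c_z"))
  out <- lapply(names(cols), function(a) {
    cc <- cols[[a]]
    if (!all(cc %in% names(df))) return(NULL)
    m <- as.matrix(df[, cc])
    ok <- rowSums(is.finite(m)) == 3L
    if (!any(ok)) return(NULL)
    data.frame(res_index = which(ok), atom = a,
               x = m[ok, 1L], y = m[ok, 2L], z = m[ok, 3L])
  })
  do.call(rbind, out)
}

# unique inter-chain residue pairs with any supplied-atom pair <= cutoff
residue_contact_pairs <- function(cs, cutoff) {
  aa <- residue_atoms(cs$chain_a); ab <- residue_atoms(cs$chain_b)
  d <- dist_cross(as.matrix(aa[, c("x", "y", "z")]),
                  as.matrix(ab[, c("x", "y", "z")]))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(data.frame(res_a = character(0), res_b = character(0)))
  pairs <- unique(data.frame(
    res_a = cs$chain_a$res_id[aa$res_index[hit[, 1L]]],
    res_b = cs$chain_b$res_id[ab$res_index[hit[, 2L]]],
    stringsAsFactors = FALSE))
  pairs[order(match(pairs$res_a, cs$chain_a$res_id),
              match(pairs$res_b, cs$chain_b$res_id)), , drop = FALSE]
}

backbone_coords <- function(df, res_ids) {
  idx <- match(res_ids, df$res_id)
  blocks <- lapply(list(c("n_x", "n_y", "n_z"), c("ca_x", "ca_y", "ca_z"),
                        c("c_x", "c_y", "c_z")), function(cc) {
    if (!all(cc %in% names(df))) return(NULL)
    m <- as.matrix(df[idx, cc, drop = FALSE])
    rownames(m) <- paste(res_ids, cc[1L])
    m
  })
  m <- do.call(rbind, blocks)
  m[rowSums(is.finite(m)) == 3L, , drop = FALSE]
}

#' Score a model against its native complex (DockQ)
#'
#' Self-contained DockQ: compares a predicted two-chain model with the
#' native structure through three CAPRI-derived measures — Fnat, the
#' fraction of native inter-chain residue contacts (any supplied-atom
#' pair within `fnat_cutoff`) preserved in the model; iRMS, the
#' backbone RMSD over the native interface residues (defined at
#' `interface_cutoff`) after least-squares superposition on those
#' residues; and LRMS, the ligand (shorter chain) backbone RMSD after
#' superposition on the receptor (longer chain) backbone — combined via
#' [dockq_combine]. A model with DockQ >= 0.23 is "acceptable".
#'
#' Model and native must share chain correspondence and residue
#' numbering; the atom set is backbone N, CA, C plus Cbeta (the atoms
#' this pipeline carries), not all heavy atoms.
#'
#' @param model,native [complex_structure] objects with matching
#'   residue identifiers.
#' @param fnat_cutoff contact cutoff for Fnat (default 5 Angstrom).
#' @param interface_cutoff interface definition for iRMS (default 10).
#' @param acceptable_threshold DockQ threshold for the `acceptable`
#'   flag (default 0.23).
#' @return A list of class `dockq_result`: `fnat`, `irms`, `lrms`,
#'   `dockq`, `acceptable`, plus the native/preserved contact counts.
#' @export
dockq_score <- function(model, native, fnat_cutoff = 5.0,
                        interface_cutoff = 10.0,
                        acceptable_threshold = 0.23) {
  stopifnot(inherits(model, "complex_structure"),
            inherits(native, "complex_structure"))
  for (side in c("chain_a", "chain_b")) {
    missing <- setdiff(native[[side]]$res_id, model[[side]]$res_id)
    if (length(missing))
      stop(sprintf("model lacks native residues in %s: %s",
                   side, paste(missing, collapse = ", ")))
  }

  native_contacts <- residue_contact_pairs(native, fnat_cutoff)
  if (nrow(native_contacts) == 0L)
    stop("native structure has no inter-chain contacts: no interface to score")
  model_contacts <- residue_contact_pairs(model, fnat_cutoff)
  key <- function(p) paste(p$res_a, p$res_b, sep = "\r")
  preserved <- sum(key(native_contacts) %in% key(model_contacts))
  fnat <- preserved / nrow(native_contacts)

  # iRMS: backbone over native interface residues (10 A definition)
  if10 <- residue_contact_pairs(native, interface_cutoff)
  if_a <- unique(if10$res_a); if_b <- unique(if10$res_b)
  nat_bb <- rbind(backbone_coords(native$chain_a, if_a),
                  backbone_coords(native$chain_b, if_b))
  mod_bb <- rbind(backbone_coords(model$chain_a, if_a),
                  backbone_coords(model$chain_b, if_b))
  common <- intersect(rownames(nat_bb), rownames(mod_bb))
  irms <- superpose(nat_bb[common, , drop = FALSE],
                    mod_bb[common, , drop = FALSE])$rmsd

  # LRMS: superpose on receptor (longer native chain), measure ligand
  rec <- if (nrow(native$chain_b) > nrow(native$chain_a)) "chain_b" else "chain_a"
  lig <- if (rec == "chain_a") "chain_b" else "chain_a"
  nat_rec <- backbone_coords(native[[rec]], native[[rec]]$res_id)
  mod_rec <- backbone_coords(model[[rec]], native[[rec]]$res_id)
  cr <- intersect(rownames(nat_rec), rownames(mod_rec))
  sp <- superpose(nat_rec[cr, , drop = FALSE], mod_rec[cr, , drop = FALSE])
  nat_lig <- backbone_coords(native[[lig]], native[[lig]]$res_id)
  mod_lig <- backbone_coords(model[[lig]], native[[lig]]$res_id)
  cl <- intersect(rownames(nat_lig), rownames(mod_lig))
  mod_lig_fit <- apply_superposition(mod_lig[cl, , drop = FALSE], sp)
  lrms <- sqrt(mean(rowSums((mod_lig_fit - nat_lig[cl, , drop = FALSE])^2)))

  dockq <- dockq_combine(fnat, irms, lrms)
  structure(list(fnat = fnat, irms = irms, lrms = lrms, dockq = dockq,
                 acceptable = dockq >= acceptable_threshold,
                 n_native_contacts = nrow(native_contacts),
                 n_preserved_contacts = preserved),
            class = "dockq_result")
}

#' @export
print.dockq_result <- function(x, ...) {
  cat(sprintf(
    "DockQ = %.3f (Fnat %.3f, iRMS %.2f A, LRMS %.2f A) — %s\n",
    x$dockq, x$fnat, x$irms, x$lrms,
    if (x$acceptable) "acceptable" else "incorrect"))
  invisible(x)
}
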