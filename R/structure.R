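#' Construct a two-chain complex structure
#'
#' Container for a heterodimeric complex: two ordered residue tables,
#' one per chain, each carrying a Cbeta coordinate and a per-residue
#' confidence (plDDT, read from the PDB B-factor column for predicted
#' models).
#'
#' @param chain_a,chain_b data.frames with one row per residue and
#'   columns `res_id` (character residue identifier: PDB number plus
#'   any insertion code), `resno` (integer), `resname` (3-letter code),
#'   `x`, `y`, `z` (Cbeta coordinate, Angstrom), `plddt`, `cb_virtual`
#'   (logical: Cbeta constructed rather than read), and optionally
#'   backbone coordinates `n_x..c_z`.
#' @param chain_ids character vector of the two (distinct) chain
#'   identifiers.
#' @param source label or path recording where the structure came from.
#' @return An object of class `complex_structure`.
#' @export
complex_structure <- function(chain_a, chain_b, chain_ids = c("A", "B"),
                              source = "constructed") {
  stopifnot(is.data.frame(chain_a), is.data.frame(chain_b),
            nrow(chain_a) >= 1L, nrow(chain_b) >= 1L,
            length(chain_ids) == 2L, chain_ids[1L] != chain_ids[2L])
  needed <- c("res_id", "x", "y", "z", "plddt")
  for (df in list(chain_a, chain_b)) {
    miss <- setdiff(needed, names(df))
    if (length(miss))
      stop("chain table lacks columns: ", paste(miss, collapse = ", "))
    if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
      stop("non-finite Cbeta coordinates")
  }
  structure(list(chain_a = chain_a, chain_b = chain_b,
                 chain_ids = as.character(chain_ids), source = source),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("complex_structure: chain %s (%d res) + chain %s (%d res) [%s]\n",
              x$chain_ids[1L], nrow(x$chain_a),
              x$chain_ids[2L], nrow(x$chain_b), x$source))
  invisible(x)
}

# idealized Cbeta from backbone N, CA, C (standard tetrahedral construction)
virtual_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- c(b[2] * cc[3] - b[3] * cc[2],
         b[3] * cc[1] - b[1] * cc[3],
         b[1] * cc[2] - b[2] * cc[1])
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

#' Read a two-chain complex from a PDB file
#'
#' Reads ATOM records (first MODEL only) for the two requested chains.
#' Per-residue confidence is taken from the B-factor column of the
#' Cbeta atom (predicted models store plDDT there). For residues
#' without a CB atom (glycine, or incomplete side chains) a virtual
#' Cbeta is constructed from ideal N/CA/C geometry when the backbone is
#' present, falling back to the CA coordinate; such residues are
#' flagged `cb_virtual`. When several alternate locations exist the
#' highest-occupancy one is kept.
#'
#' @param path PDB file path.
#' @param chain_a_id,chain_b_id chain identifiers of the two chains.
#' @param strict if `TRUE`, residues lacking a real CB atom are dropped
#'   (with a message) instead of receiving a virtual Cbeta.
#' @return A [complex_structure].
#' @export
read_complex <- function(path, chain_a_id = "A", chain_b_id = "B",
                         strict = FALSE) {
  stopifnot(chain_a_id != chain_b_id)
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  have <- unique(at$chain)
  for (cid in c(chain_a_id, chain_b_id)) {
    if (!cid %in% have)
      stop(sprintf("chain '%s' not found in %s (available: %s)",
                   cid, path, paste(have, collapse = ", ")))
  }
  # highest-occupancy altLoc per (chain, residue, atom); ties keep file order
  occ <- ifelse(is.na(at$o), 1, at$o)
  at <- at[order(-occ), , drop = FALSE]
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  at <- at[!duplicated(key), , drop = FALSE]
  at <- at[order(as.integer(rownames(at))), , drop = FALSE]

  build_chain <- function(cid) {
    ca <- at[at$chain == cid, , drop = FALSE]
    rid_all <- paste0(ca$resno,
                      ifelse(is.na(ca$insert) | ca$insert == "", "", ca$insert))
    rids <- unique(rid_all)
    rows <- lapply(rids, function(rid) {
      ra <- ca[rid_all == rid, , drop = FALSE]
      get_atom <- function(name) {
        i <- which(ra$elety == name)[1L]
        if (is.na(i)) return(NULL)
        c(ra$x[i], ra$y[i], ra$z[i])
      }
      cb <- get_atom("CB"); bb_n <- get_atom("N")
      bb_ca <- get_atom("CA"); bb_c <- get_atom("C")
      virt <- FALSE
      if (is.null(cb)) {
        if (strict) {
          message(sprintf("strict mode: dropping residue %s/%s (no CB atom)",
                          cid, rid))
          return(NULL)
        }
        if (!is.null(bb_n) && !is.null(bb_ca) && !is.null(bb_c)) {
          cb <- virtual_cb(bb_n, bb_ca, bb_c)
        } else if (!is.null(bb_ca)) {
          cb <- bb_ca
        } else {
          warning(sprintf("skipping residue %s/%s: neither CB nor backbone",
                          cid, rid))
          return(NULL)
        }
        virt <- TRUE
      }
      # plDDT from the B-factor of the atom the Cbeta came from
      bsrc <- if (virt) "CA" else "CB"
      bi <- which(ra$elety == bsrc)[1L]
      if (is.na(bi)) bi <- 1L
      opt <- function(v) if (is.null(v)) rep(NA_real_, 3L) else v
      data.frame(res_id = rid, resno = ra$resno[1L], resname = ra$resid[1L],
                 x = cb[1L], y = cb[2L], z = cb[3L],
                 plddt = ca$b[which(rid_all == rid)][bi],
                 cb_virtual = virt,
                 n_x = opt(bb_n)[1L], n_y = opt(bb_n)[2L], n_z = opt(bb_n)[3L],
                 ca_x = opt(bb_ca)[1L], ca_y = opt(bb_ca)[2L], ca_z = opt(bb_ca)[3L],
                 c_x = opt(bb_c)[1L], c_y = opt(bb_c)[2L], c_z = opt(bb_c)[3L],
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (is.null(df) || nrow(df) == 0L)
      stop(sprintf("chain '%s' of %s has no usable residues", cid, path))
    rownames(df) <- NULL
    df
  }

  complex_structure(build_chain(chain_a_id), build_chain(chain_b_id),
                    chain_ids = c(chain_a_id, chain_b_id), source = path)
}

# pairwise Euclidean distance matrix between two coordinate matrices
dist_cross <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

chain_coords <- function(df) as.matrix(df[, c("x", "y", "z")])

#' Inter-chain Cbeta contacts
#'
#' All residue pairs (one from each chain) whose Cbeta atoms are within
#' `cutoff` Angstrom of each other — the interface definition used
#' throughout the package. Each unordered inter-chain pair appears
#' once, ordered by chain-A residue index then chain-B index.
#'
#' @param cs a [complex_structure].
#' @param cutoff Cbeta-Cbeta distance cutoff in Angstrom (default 8).
#' @return data.frame with columns `index_a`, `index_b` (row indices in
#'   the chain tables), `res_a`, `res_b` (residue ids) and `distance`.
#' @export
interface_contacts <- function(cs, cutoff = 8.0) {
  stopifnot(inherits(cs, "complex_structure"), cutoff > 0)
  d <- dist_cross(chain_coords(cs$chain_a), chain_coords(cs$chain_b))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  data.frame(index_a = as.integer(hit[, 1L]),
             index_b = as.integer(hit[, 2L]),
             res_a = cs$chain_a$res_id[hit[, 1L]],
             res_b = cs$chain_b$res_id[hit[, 2L]],
             distance = d[hit],
             stringsAsFactors = FALSE)
}

#' Interface contact and confidence metrics
#'
#' Summarizes a predicted two-chain model's interface: the number of
#' Cbeta-Cbeta contacts within `cutoff` (IF_contacts), the number of
#' residues participating in at least one contact summed over both
#' chains (IF_residues), the mean plDDT over those interface residues
#' (IF_plDDT), the minimum over chains of the chain-mean plDDT, and the
#' mean plDDT over all residues.
#'
#' @param cs a [complex_structure].
#' @param cutoff interface distance cutoff in Angstrom (default 8).
#' @return A list of class `interface_metrics` with elements
#'   `n_if_contacts`, `n_if_residues`, `if_plddt`, `min_chain_plddt`,
#'   `avg_plddt`, `empty_interface`. When the interface is empty,
#'   `if_plddt` is 0 and `empty_interface` is `TRUE`.
#' @export
interface_metrics <- function(cs, cutoff = 8.0) {
  stopifnot(inherits(cs, "complex_structure"))
  contacts <- interface_contacts(cs, cutoff = cutoff)
  ia <- unique(contacts$index_a)
  ib <- unique(contacts$index_b)
  empty <- nrow(contacts) == 0L
  if_plddt <- if (empty) 0 else
    mean(c(cs$chain_a$plddt[ia], cs$chain_b$plddt[ib]))
  structure(list(
    n_if_contacts = nrow(contacts),
    n_if_residues = length(ia) + length(ib),
    if_plddt = if_plddt,
    min_chain_plddt = min(mean(cs$chain_a$plddt), mean(cs$chain_b$plddt)),
    avg_plddt = mean(c(cs$chain_a$plddt, cs$chain_b$plddt)),
    empty_interface = empty), class = "interface_metrics")
}

#' @export
print.interface_metrics <- function(x, ...) {
  cat(sprintf(
    "interface_metrics: %d contacts, %d residues, IF_plDDT %.2f, min chain plDDT %.2f, avg plDDT %.2f%s\n",
    x$n_if_contacts, x$n_if_residues, x$if_plddt, x$min_chain_plddt,
    x$avg_plddt, if (x$empty_interface) " (empty interface)" else ""))
  invisible(x)
}
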