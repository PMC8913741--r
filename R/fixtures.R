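# Seeded generators for every input the analysis modules consume:
# toy two-chain PDB complexes with a provable number of interface
# contacts, rigid-body decoy series, organism-annotated a3m pairs and
# sigmoid-shaped (x, DockQ) datasets. All are bit-reproducible under a
# fixed seed; none attempt physical realism — geometry is lattice-based
# so planted quantities are exact by construction.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# write one chain's residues (ALA with full backbone + CB) via bio3d
toy_chain_atoms <- function(cb, chain_id, plddt, resno_offset = 0L) {
  n <- nrow(cb)
  # backbone placed at fixed offsets from the Cbeta: non-collinear,
  # rigid per residue, so virtual-Cbeta reconstruction stays sane
  offs <- list(N = c(-1.2, -2.0, 0.4), CA = c(0.0, -1.5, 0.0),
               C = c(1.2, -2.0, -0.4), CB = c(0, 0, 0))
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(names(offs), function(a) {
      p <- cb[i, ] + offs[[a]]
      data.frame(elety = a, x = p[1L], y = p[2L], z = p[3L],
                 resno = i + resno_offset, chain = chain_id,
                 b = plddt[i])
    }))
  }))
  atoms
}

#' Generate a toy two-chain complex PDB
#'
#' Places both chains on a lattice (8 Angstrom spacing along x) such
#' that an all-pairs 8 Angstrom Cbeta scan yields exactly
#' `planted_contacts` one-to-one contacts: the first `planted_contacts`
#' chain-B residues sit 6 Angstrom from their chain-A counterparts and
#' every other inter-chain Cbeta pair is at least 10 Angstrom apart.
#' Residues are written as alanine with full backbone (N, CA, C, CB);
#' B-factors carry per-residue plDDT drawn from a clamped normal and
#' rounded to the 2 decimals the PDB format stores. Chain B starts at
#' residue number `n_res_a + 201` so readers must tolerate a numbering
#' gap between chains.
#'
#' @param n_res_a,n_res_b residue counts per chain.
#' @param planted_contacts number of interface contacts to plant; must
#'   not exceed `min(n_res_a, n_res_b)` (one-to-one geometry).
#' @param plddt_mean,plddt_sd length-2 numeric: per-chain mean/sd of
#'   the plDDT profile.
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   files.
#' @param path output PDB path (default a tempfile).
#' @return list with `path` and `expected` (the planted quantities:
#'   `n_contacts`, `n_if_residues`, per-chain plDDT vectors).
#' @export
make_toy_complex <- function(n_res_a = 10L, n_res_b = 10L,
                             planted_contacts = 5L,
                             plddt_mean = c(90, 90), plddt_sd = c(0, 0),
                             seed = 1L,
                             path = tempfile(fileext = ".pdb")) {
  stopifnot(n_res_a >= 1L, n_res_b >= 1L, planted_contacts >= 0L)
  if (planted_contacts > min(n_res_a, n_res_b))
    stop(sprintf(
      "infeasible contact count for the one-to-one lattice geometry: %d > min(%d, %d)",
      planted_contacts, n_res_a, n_res_b))
  plddt_mean <- rep_len(plddt_mean, 2L); plddt_sd <- rep_len(plddt_sd, 2L)
  withr::with_seed(seed, {
    pl_a <- round(pmin(100, pmax(0, stats::rnorm(n_res_a, plddt_mean[1L], plddt_sd[1L]))), 2)
    pl_b <- round(pmin(100, pmax(0, stats::rnorm(n_res_b, plddt_mean[2L], plddt_sd[2L]))), 2)
  })
  spacing <- 8
  cb_a <- cbind(spacing * (seq_len(n_res_a) - 1L), 0, 0)
  y_b <- ifelse(seq_len(n_res_b) <= planted_contacts, 6, 24)
  cb_b <- cbind(spacing * (seq_len(n_res_b) - 1L), y_b, 0)

  atoms <- rbind(toy_chain_atoms(cb_a, "A", pl_a),
                 toy_chain_atoms(cb_b, "B", pl_b,
                                 resno_offset = n_res_a + 200L))
  xyz <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
  na <- nrow(atoms)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = atoms$resno, resid = rep("ALA", na),
                   eleno = seq_len(na), elety = atoms$elety,
                   chain = atoms$chain, o = rep(1, na), b = atoms$b)
  list(path = path,
       expected = list(n_contacts = planted_contacts,
                       n_if_residues = 2L * planted_contacts,
                       plddt_a = pl_a, plddt_b = pl_b))
}

#' Generate a rigid-body decoy series from a native complex
#'
#' Reads the native PDB and, for each offset, rigidly translates every
#' chain-B atom along +y by that amount, writing one decoy per offset.
#' Offset 0 reproduces the native coordinates, and increasing offsets
#' progressively destroy the interface, so DockQ against the native is
#' non-increasing along the series.
#'
#' @param native_path path to the native PDB (two chains A/B).
#' @param offsets non-negative, ascending translation offsets in
#'   Angstrom.
#' @param dir output directory for the decoy files.
#' @return character vector of decoy PDB paths (one per offset).
#' @export
make_decoy_series <- function(native_path, offsets,
                              dir = tempfile("decoys")) {
  stopifnot(all(offsets >= 0), !is.unsorted(offsets))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- suppressWarnings(bio3d::read.pdb(native_path, verbose = FALSE))
  sel_b <- pdb$atom$chain == "B"
  vapply(seq_along(offsets), function(i) {
    at <- pdb$atom
    at$y[sel_b] <- at$y[sel_b] + offsets[i]
    out <- file.path(dir, sprintf("decoy_%03d.pdb", i))
    bio3d::write.pdb(file = out,
                     xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                     resno = at$resno, resid = at$resid,
                     eleno = at$eleno, elety = at$elety,
                     chain = at$chain, o = at$o, b = at$b)
    out
  }, character(1))
}

mutate_sequence <- function(query_chars, rate = 0.3, gap_rate = 0.1) {
  n <- length(query_chars)
  s <- query_chars
  mut <- stats::runif(n) < rate
  s[mut] <- sample(AA_LETTERS, sum(mut), replace = TRUE)
  gap <- stats::runif(n) < gap_rate
  s[gap] <- "-"
  paste(s, collapse = "")
}

#' Generate an organism-annotated a3m pair for two chains
#'
#' Builds two toy alignments whose hit headers carry `OX=` taxonomy
#' tokens from the supplied organism lists (an `NA` entry produces a
#' hit without an `OX=` token). Hits are mutated copies of the chain
#' query with occasional gaps. The number of organism pairs that
#' [pair_by_organism] should produce is emitted as metadata.
#'
#' @param organisms_a,organisms_b integer vectors of taxon ids, one per
#'   hit, in rank order (`NA` allowed).
#' @param length_a,length_b query lengths of the two chains.
#' @param seed integer seed.
#' @param mutation_rate,gap_rate per-position substitution and gap
#'   probabilities for hits.
#' @return list with `a3m_a`, `a3m_b` ([msa] objects) and
#'   `expected_pairs` (the count of shared organisms).
#' @export
make_toy_msa_pair <- function(organisms_a, organisms_b,
                              length_a = 40L, length_b = 50L, seed = 1L,
                              mutation_rate = 0.3, gap_rate = 0.1) {
  stopifnot(length_a >= 1L, length_b >= 1L)
  build <- function(orgs, len, tag) {
    q <- sample(AA_LETTERS, len, replace = TRUE)
    headers <- sprintf("query_%s", tag)
    seqs <- paste(q, collapse = "")
    for (i in seq_along(orgs)) {
      ox <- if (is.na(orgs[i])) "" else sprintf(" OX=%d", orgs[i])
      headers <- c(headers, sprintf("hit_%s_%d%s", tag, i, ox))
      seqs <- c(seqs, mutate_sequence(q, mutation_rate, gap_rate))
    }
    msa(headers, seqs)
  }
  withr::with_seed(seed, {
    a <- build(organisms_a, length_a, "a")
    b <- build(organisms_b, length_b, "b")
  })
  shared <- intersect(unique(organisms_a[!is.na(organisms_a)]),
                      unique(organisms_b[!is.na(organisms_b)]))
  list(a3m_a = a, a3m_b = b, expected_pairs = length(shared))
}

#' Generate a sigmoid-shaped (x, DockQ) dataset
#'
#' Samples x uniformly on `x_range`, evaluates the pDockQ sigmoid with
#' the given parameters and adds Gaussian noise of standard deviation
#' `noise_sd`, clipping the result to the valid DockQ range \[0, 1\].
#' Used to exercise parameter recovery by [fit_pdockq].
#'
#' @param params a [pdockq_params] (defaults to the published fit).
#' @param n number of points (>= 8).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param x_range length-2 numeric interval for x.
#' @param seed integer seed.
#' @return list with numeric vectors `x` and `dockq`.
#' @export
make_sigmoid_dataset <- function(params = pdockq_params(), n = 1481L,
                                 noise_sd = 0.1, x_range = c(50, 250),
                                 seed = 1L) {
  stopifnot(inherits(params, "pdockq_params"), n >= 8L, noise_sd >= 0)
  withr::with_seed(seed, {
    x <- stats::runif(n, x_range[1L], x_range[2L])
    y <- pdockq_sigmoid(x, params) + stats::rnorm(n, 0, noise_sd)
  })
  list(x = x, dockq = pmin(1, pmax(0, y)))
}
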