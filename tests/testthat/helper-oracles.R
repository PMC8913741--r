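# Independent oracles and generators used across the suite. These stay
# deliberately naive (loops, exhaustive enumeration) so they cannot
# share a defect with the vectorized implementation they check.

# complex_structure with uniformly random Cbeta clouds
random_complex <- function(n_a, n_b, spread = 15, seed = 1) {
  withr::with_seed(seed, {
    ca <- matrix(stats::runif(n_a * 3, 0, spread), ncol = 3)
    cb <- matrix(stats::runif(n_b * 3, 0, spread), ncol = 3)
    pa <- stats::runif(n_a, 50, 100)
    pb <- stats::runif(n_b, 50, 100)
  })
  mk <- function(m, p) data.frame(
    res_id = as.character(seq_len(nrow(m))), resno = seq_len(nrow(m)),
    resname = "ALA", x = m[, 1], y = m[, 2], z = m[, 3], plddt = p,
    cb_virtual = FALSE, stringsAsFactors = FALSE)
  complex_structure(mk(ca, pa), mk(cb, pb))
}

# all-pairs double-loop contact scan
brute_force_contacts <- function(cs, cutoff = 8) {
  out <- NULL
  for (i in seq_len(nrow(cs$chain_a))) {
    for (j in seq_len(nrow(cs$chain_b))) {
      d <- sqrt(sum((unlist(cs$chain_a[i, c("x", "y", "z")]) -
                     unlist(cs$chain_b[j, c("x", "y", "z")]))^2))
      if (d <= cutoff) out <- rbind(out, data.frame(index_a = i, index_b = j))
    }
  }
  out
}

# concordant-pair probability (Mann-Whitney), half credit for ties
brute_force_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# coarse Euler-angle grid followed by Nelder-Mead refinement; never
# touches the SVD path under test
grid_superpose_rmsd <- function(fixed, moving) {
  cf <- colMeans(fixed); cm <- colMeans(moving)
  Fc <- sweep(fixed, 2, cf); Mc <- sweep(moving, 2, cm)
  rot_euler <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  objective <- function(ang) {
    sqrt(mean(rowSums((Mc %*% t(rot_euler(ang)) - Fc)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a in grid) for (b in grid) for (c in grid) {
    v <- objective(c(a, b, c))
    if (v < best) { best <- v; best_ang <- c(a, b, c) }
  }
  opt <- stats::optim(best_ang, objective, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# rigid-body motion applied to both chains of a complex_structure
transform_complex <- function(cs, rotation, translation) {
  move <- function(df) {
    m <- as.matrix(df[, c("x", "y", "z")]) %*% rotation
    df$x <- m[, 1] + translation[1]
    df$y <- m[, 2] + translation[2]
    df$z <- m[, 3] + translation[3]
    df
  }
  cs$chain_a <- move(cs$chain_a); cs$chain_b <- move(cs$chain_b)
  cs
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, byrow = TRUE)
}

# interface_metrics literal for confidence-score tests
fake_metrics <- function(if_plddt, n_if_contacts, n_if_residues = 2L) {
  structure(list(n_if_contacts = as.integer(n_if_contacts),
                 n_if_residues = as.integer(n_if_residues),
                 if_plddt = if_plddt, min_chain_plddt = if_plddt,
                 avg_plddt = if_plddt,
                 empty_interface = n_if_contacts == 0L),
            class = "interface_metrics")
}
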