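#' Pairwise residue similarity
#'
#' Fixed weighted overlap of physicochemical features and conservation used to
#' fill the assignment matrix: a Gaussian on the hydropathy difference (30%),
#' charge-class agreement (20%), polarity agreement (15%), aromaticity
#' agreement (10%), side-chain size ratio (10%) and the conservation product
#' (15%).  The result is clamped to \[0, 1\].
#'
#' @param fa,fb Single rows of a [residue_features()] table (or named lists
#'   with the same fields).
#' @return Similarity in \[0, 1\].
#' @export
residue_similarity <- function(fa, fb) {
  sim <- 0.30 * exp(-(fa$hydrophobicity - fb$hydrophobicity)^2 / 18) +
    0.20 * (fa$charge_class == fb$charge_class) +
    0.15 * (fa$polar == fb$polar) +
    0.10 * (fa$aromatic == fb$aromatic) +
    0.10 * pmin(fa$side_chain_size, fb$side_chain_size) /
      pmax(fa$side_chain_size, fb$side_chain_size, 1) +
    0.15 * (fa$conservation * fb$conservation)
  pmin(pmax(sim, 0), 1)
}

#' Residue-by-residue similarity matrix of two pockets
#'
#' @param pocket_a,pocket_b [new_pocket()] objects.
#' @return An nA x nB matrix of [residue_similarity()] values in \[0, 1\].
#' @export
residue_similarity_matrix <- function(pocket_a, pocket_b) {
  ra <- pocket_a$residues
  rb <- pocket_b$residues
  na <- nrow(ra)
  nb <- nrow(rb)
  m <- matrix(0, na, nb)
  for (j in seq_len(nb)) {
    m[, j] <- residue_similarity(ra, rb[j, ])
  }
  rownames(m) <- paste(ra$chain, ra$resnum, ra$res_name, sep = "_")
  colnames(m) <- paste(rb$chain, rb$resnum, rb$res_name, sep = "_")
  m
}

# Kuhn-Munkres (Hungarian) algorithm for the square minimum-cost assignment
# problem, via dual potentials and shortest augmenting paths; O(n^3).
hungarian_min <- function(a) {
  n <- nrow(a)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1) # p[j]: row matched to column j (0 = free); n+1 virtual
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- a[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1) break
    }
  }
  match_col <- integer(n)
  for (j in seq_len(n)) match_col[p[j]] <- j
  match_col
}

#' Optimal assignment over a similarity matrix
#'
#' Maximum-total-similarity one-to-one matching of size `min(nA, nB)`, solved
#' with the Kuhn-Munkres algorithm.  Rectangular matrices are padded with
#' zeros and the padded pairs discarded.  Ties are resolved deterministically
#' in favor of low (row, column) index pairings via an infinitesimal
#' perturbation.
#'
#' @param matrix An nA x nB matrix of similarities in \[0, 1\].
#' @return Tibble with columns `row`, `col`, `similarity`, sorted by `row`,
#'   with the matching total in attribute `total`.
#' @export
optimal_assignment <- function(matrix) {
  m <- as.matrix(matrix)
  if (length(m) == 0 || nrow(m) == 0 || ncol(m) == 0) {
    abort("similarity matrix must be non-empty")
  }
  na <- nrow(m)
  nb <- ncol(m)
  n <- max(na, nb)
  # tie-break perturbation: favors pairing low row indices with low column
  # indices; too small to flip genuinely different totals
  eps <- 1e-10 / (n * n)
  pert <- outer(na:1, nb:1) * eps
  sq <- matrix(0, n, n)
  sq[seq_len(na), seq_len(nb)] <- m + pert
  cost <- max(sq) - sq
  match_col <- hungarian_min(cost)
  rows <- seq_len(na)
  cols <- match_col[rows]
  keep <- cols <= nb
  out <- tibble(
    row = rows[keep], col = cols[keep],
    similarity = m[cbind(rows[keep], cols[keep])]
  ) %>% arrange(.data$row)
  attr(out, "total") <- sum(out$similarity)
  out
}

#' Pocket alignment object
#'
#' A residue pairing from optimal assignment after geometric pruning: the
#' kept pairs, the rigid transform superposing pocket A onto pocket B, and
#' the aligned Calpha RMSD.
#'
#' @param pairs Tibble with columns `row`, `col`, `similarity`.
#' @param transform A [rigid_transform()] (A onto B).
#' @param aligned_rmsd Calpha RMSD over kept pairs (Angstrom).
#' @param failed Flag: geometric consistency could not be reached.
#' @return An object of class `pocket_alignment`.
#' @export
pocket_alignment <- function(pairs, transform, aligned_rmsd, failed = FALSE) {
  if (anyDuplicated(pairs$row) || anyDuplicated(pairs$col)) {
    abort("alignment pairs must form a partial matching")
  }
  structure(
    list(
      pairs = as_tibble(pairs), transform = transform,
      aligned_rmsd = aligned_rmsd, n_aligned = nrow(pairs), failed = failed
    ),
    class = "pocket_alignment"
  )
}

#' @export
print.pocket_alignment <- function(x, ...) {
  if (x$failed) {
    cat("<pocket_alignment> FAILED (no geometrically consistent core)\n")
  } else {
    cat(sprintf(
      "<pocket_alignment> %d pairs, Calpha RMSD %.2f A\n",
      x$n_aligned, x$aligned_rmsd
    ))
  }
  invisible(x)
}

#' Geometric pruning of an assignment
#'
#' Iteratively superposes the currently kept pairs (Kabsch) and drops the
#' single worst pair whose post-fit Calpha distance exceeds
#' `distance_cutoff`, until all pairs fit or only `min_pairs` remain.  If the
#' floor is reached while the worst distance still exceeds the cutoff, the
#' result is flagged as failed rather than raising an error.
#'
#' @param pairs Tibble from [optimal_assignment()].
#' @param coords_a,coords_b Calpha coordinate matrices of the two pockets.
#' @param distance_cutoff Post-fit distance cutoff in Angstrom (default 6).
#' @param min_pairs Minimum pair count to retain (default 5).
#' @return A [pocket_alignment()].
#' @export
geometric_prune <- function(pairs, coords_a, coords_b, distance_cutoff = 6,
                            min_pairs = 5) {
  if (nrow(pairs) < min_pairs) {
    abort(sprintf("need at least %d pairs to prune", min_pairs))
  }
  kept <- pairs
  repeat {
    pa <- coords_a[kept$row, , drop = FALSE]
    pb <- coords_b[kept$col, , drop = FALSE]
    fit <- suppressWarnings(kabsch_superpose(pa, pb))
    d <- sqrt(rowSums((apply_transform(fit$transform, pa) - pb)^2))
    worst <- which.max(d)
    if (d[worst] <= distance_cutoff) {
      return(pocket_alignment(kept, fit$transform, fit$rmsd))
    }
    if (nrow(kept) <= min_pairs) {
      return(pocket_alignment(kept, fit$transform, fit$rmsd, failed = TRUE))
    }
    kept <- kept[-worst, , drop = FALSE]
  }
}

#' eMS-like similarity score of a pocket alignment
#'
#' Normalized similarity of the kept residue pairs,
#' `2 * sum(pair similarities) / (nA + nB)`, attenuated by the geometric
#' factor `1 / (1 + (RMSD / 4)^2)` so the score halves at 4 Angstrom aligned
#' Calpha RMSD.  Failed alignments score 0.
#'
#' @param alignment A [pocket_alignment()].
#' @param pocket_a,pocket_b The aligned pockets.
#' @param threshold Significance threshold on the score (default 0.80).
#' @return An object of class `ems_result` with fields `ems_score`,
#'   `significant` and `alignment`.
#' @export
ems_score <- function(alignment, pocket_a, pocket_b, threshold = 0.80) {
  if (alignment$failed) {
    score <- 0
  } else {
    na <- nrow(pocket_a$residues)
    nb <- nrow(pocket_b$residues)
    base <- 2 * sum(alignment$pairs$similarity) / (na + nb)
    geom <- 1 / (1 + (alignment$aligned_rmsd / 4)^2)
    score <- min(max(base * geom, 0), 1)
  }
  structure(
    list(
      ems_score = score,
      significant = score >= threshold,
      threshold = threshold,
      alignment = alignment
    ),
    class = "ems_result"
  )
}

#' @export
print.ems_result <- function(x, ...) {
  cat(sprintf(
    "<ems_result> eMS %.3f (%ssignificant at %.2f), %d aligned pairs, RMSD %.2f A\n",
    x$ems_score, if (x$significant) "" else "not ", x$threshold,
    x$alignment$n_aligned, x$alignment$aligned_rmsd
  ))
  invisible(x)
}

#' @export
tidy.ems_result <- function(x, ...) {
  tibble(
    ems_score = x$ems_score, significant = x$significant,
    n_aligned = x$alignment$n_aligned,
    aligned_rmsd = x$alignment$aligned_rmsd,
    failed = x$alignment$failed
  )
}

#' @export
glance.ems_result <- function(x, ...) tidy(x)

#' Match two binding pockets
#'
#' The full sequence-order-independent comparison: build the residue
#' similarity matrix, solve the assignment problem, prune to a geometrically
#' consistent core, and score.  The score is symmetric in its arguments to
#' within numerical precision.
#'
#' @param pocket_a,pocket_b [new_pocket()] objects with at least 5 residues.
#' @param threshold Significance threshold (default 0.80).
#' @param distance_cutoff,min_pairs Pruning parameters; see
#'   [geometric_prune()].
#' @return An `ems_result`.
#' @export
match_pockets <- function(pocket_a, pocket_b, threshold = 0.80,
                          distance_cutoff = 6, min_pairs = 5) {
  if (nrow(pocket_a$residues) < 5 || nrow(pocket_b$residues) < 5) {
    abort("pockets need at least 5 residues for alignment")
  }
  m <- residue_similarity_matrix(pocket_a, pocket_b)
  pairs <- optimal_assignment(m)
  aln <- geometric_prune(
    pairs, pocket_coords(pocket_a), pocket_coords(pocket_b),
    distance_cutoff = distance_cutoff,
    min_pairs = min(min_pairs, nrow(pairs))
  )
  ems_score(aln, pocket_a, pocket_b, threshold = threshold)
}
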