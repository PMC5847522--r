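#' Rigid-body transforms
#'
#' A proper rotation (determinant +1) plus a translation, applied as
#' `x %*% t(rotation) + translation`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Numeric 3-vector (Angstrom).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    abort("rotation must be orthonormal with determinant +1")
  }
  structure(
    list(rotation = rotation, translation = as.numeric(translation)),
    class = "rigid_transform"
  )
}

#' Apply a rigid transform to coordinates
#' @param transform A [rigid_transform()].
#' @param xyz An n x 3 coordinate matrix.
#' @return The transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, xyz) {
  xyz <- rbind(as.matrix(xyz))
  sweep(xyz %*% t(transform$rotation), 2, -transform$translation)
}

#' Compose two rigid transforms (`b` after `a`)
#' @param a,b `rigid_transform` objects.
#' @return The composite transform.
#' @export
compose_transforms <- function(b, a) {
  rigid_transform(
    rotation = b$rotation %*% a$rotation,
    translation = as.numeric(b$rotation %*% a$translation) + b$translation
  )
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired point sets; reflections are excluded.  Point `i` of `moving` must
#' correspond to point `i` of `fixed`.
#'
#' @param moving,fixed n x 3 coordinate matrices, n >= 3.
#' @return An object of class `superposition`: the transform mapping `moving`
#'   onto `fixed`, the post-fit RMSD (Angstrom) and the number of points.
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- rbind(as.matrix(moving))
  fixed <- rbind(as.matrix(fixed))
  if (nrow(moving) != nrow(fixed)) abort("point counts differ")
  n <- nrow(moving)
  if (n < 3) abort("at least 3 point pairs are required")
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  p <- sweep(moving, 2, cm)
  q <- sweep(fixed, 2, cf)
  h <- crossprod(p, q)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    warn("(nearly) collinear points: superposition is not unique")
  }
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cf - as.numeric(rot %*% cm)
  tr <- rigid_transform(rot, trans)
  moved <- apply_transform(tr, moving)
  structure(
    list(
      transform = tr,
      rmsd = sqrt(mean(rowSums((moved - fixed)^2))),
      n_points = n
    ),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d points, RMSD %.3f A\n", x$n_points, x$rmsd))
  invisible(x)
}

#' @export
tidy.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_points = x$n_points)
}

#' RMSD between paired coordinate sets
#'
#' @param a,b n x 3 coordinate matrices with fixed correspondence.
#' @param superpose If `TRUE`, apply the optimal rigid superposition first;
#'   otherwise compute the raw deviation in the shared frame.
#' @return RMSD in Angstrom.
#' @export
rmsd_paired <- function(a, b, superpose = FALSE) {
  a <- rbind(as.matrix(a))
  b <- rbind(as.matrix(b))
  if (nrow(a) != nrow(b)) abort("point counts differ")
  if (superpose) {
    kabsch_superpose(a, b)$rmsd
  } else {
    sqrt(mean(rowSums((a - b)^2)))
  }
}

# fragment-seeded iterative superposition search shared by the TM-score and
# GDT machinery: seed a fit on every contiguous fragment of the pairing, then
# alternate include-refit until the included subset is stable
seeded_fits <- function(mod, ref, seed_lengths, include_rule) {
  n <- nrow(mod)
  best <- NULL
  best_val <- -Inf
  for (len in unique(pmin(pmax(seed_lengths, 3L), n))) {
    starts <- seq.int(1L, n - len + 1L)
    for (s in starts) {
      idx <- s:(s + len - 1L)
      for (iter in 1:20) {
        fit <- kabsch_superpose(mod[idx, , drop = FALSE], ref[idx, , drop = FALSE])
        moved <- apply_transform(fit$transform, mod)
        d <- sqrt(rowSums((moved - ref)^2))
        keep <- include_rule(d)
        if (sum(keep) < 3) break
        new_idx <- which(keep)
        val <- attr(keep, "value") %||% sum(keep)
        if (val > best_val) {
          best_val <- val
          best <- list(d = d, transform = fit$transform, value = val)
        }
        if (length(new_idx) == length(idx) && all(new_idx == idx)) break
        idx <- new_idx
      }
    }
  }
  best
}

#' TM-score of a paired superposition
#'
#' Template-modeling score over a supplied residue pairing, maximized over
#' superpositions found by a fragment-seeded iterative search (seeds of the
#' full alignment length, half of it, and 4 residues, extended by the d0
#' inclusion rule until stable).
#'
#' @param model,reference Calpha coordinate matrices.
#' @param pairing Two-column matrix of (model index, reference index) pairs;
#'   defaults to the identity pairing.
#' @param norm_length Normalization length, at least 16 (default: number of
#'   reference residues, the convention that the score is normalized by the
#'   target).
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, reference, pairing = NULL, norm_length = nrow(reference)) {
  model <- as.matrix(model)
  reference <- as.matrix(reference)
  if (is.null(pairing)) {
    if (nrow(model) != nrow(reference)) abort("identity pairing needs equal lengths")
    pairing <- cbind(seq_len(nrow(model)), seq_len(nrow(reference)))
  }
  pairing <- rbind(as.matrix(pairing))
  if (nrow(pairing) == 0) abort("pairing must be non-empty")
  if (norm_length <= 15) abort("norm_length must be at least 16 (d0 > 0)")
  d0 <- 1.24 * (norm_length - 15)^(1 / 3) - 1.8
  mod <- model[pairing[, 1], , drop = FALSE]
  ref <- reference[pairing[, 2], , drop = FALSE]
  n <- nrow(mod)
  score_of <- function(d) sum(1 / (1 + (d / d0)^2)) / norm_length
  include <- function(d) {
    keep <- d < pmax(d0, 0.5)
    attr(keep, "value") <- score_of(d)
    keep
  }
  best <- seeded_fits(mod, ref, c(n, ceiling(n / 2), 4L), include)
  if (is.null(best)) {
    # fall back to the global fit when no seed stabilizes
    fit <- kabsch_superpose(mod, ref)
    d <- sqrt(rowSums((apply_transform(fit$transform, mod) - ref)^2))
    return(score_of(d))
  }
  best$value
}

#' GDT-TS of a paired superposition
#'
#' Mean over the thresholds 1, 2, 4 and 8 Angstrom of the maximal fraction of
#' paired residues superposable under that threshold, using the same
#' fragment-seeded search as [tm_score()] restricted to each threshold.
#'
#' @inheritParams tm_score
#' @param thresholds Distance thresholds in Angstrom.
#' @return GDT-TS in \[0, 1\].
#' @export
gdt_ts <- function(model, reference, pairing = NULL, thresholds = c(1, 2, 4, 8)) {
  model <- as.matrix(model)
  reference <- as.matrix(reference)
  if (is.null(pairing)) {
    if (nrow(model) != nrow(reference)) abort("identity pairing needs equal lengths")
    pairing <- cbind(seq_len(nrow(model)), seq_len(nrow(reference)))
  }
  pairing <- rbind(as.matrix(pairing))
  if (nrow(pairing) == 0) abort("pairing must be non-empty")
  mod <- model[pairing[, 1], , drop = FALSE]
  ref <- reference[pairing[, 2], , drop = FALSE]
  n <- nrow(mod)
  frac <- map_dbl(thresholds, function(thr) {
    include <- function(d) {
      keep <- d <= thr
      attr(keep, "value") <- sum(keep)
      keep
    }
    best <- seeded_fits(mod, ref, c(n, ceiling(n / 2), 4L), include)
    if (is.null(best)) {
      fit <- kabsch_superpose(mod, ref)
      d <- sqrt(rowSums((apply_transform(fit$transform, mod) - ref)^2))
      return(sum(d <= thr) / n)
    }
    best$value / n
  })
  mean(frac)
}

#' Matthews correlation coefficient between residue sets
#'
#' Binary-classification MCC of predicted versus actual membership within a
#' universe of residues; returns 0 when any confusion-matrix marginal is
#' empty.
#'
#' @param predicted,actual Vectors of residue identifiers; must be subsets of
#'   `universe`.
#' @param universe Vector of all residue identifiers under consideration.
#' @return MCC in \[-1, 1\].
#' @export
mcc_sets <- function(predicted, actual, universe) {
  predicted <- unique(predicted)
  actual <- unique(actual)
  universe <- unique(universe)
  if (!all(predicted %in% universe) || !all(actual %in% universe)) {
    abort("predicted and actual must be subsets of the universe")
  }
  tp <- length(intersect(predicted, actual))
  fp <- length(setdiff(predicted, actual))
  fn <- length(setdiff(actual, predicted))
  tn <- length(universe) - tp - fp - fn
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}
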