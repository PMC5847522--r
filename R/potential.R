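#' Default atom typing for the statistical potential
#'
#' Protein heavy atoms are typed by element and backbone/side-chain
#' membership; ligand heavy atoms by element with aromatic carbon and
#' nitrogen distinguished.  Unknown atoms map to a catch-all type.  The
#' scheme is deliberately coarse so that synthetic training corpora populate
#' every pair.
#'
#' @return An object of class `atom_typing` with fields `protein_types`,
#'   `ligand_types`, `n_types` and the two mapper functions.
#' @export
default_atom_typing <- function() {
  protein_types <- c("p.C.bb", "p.N.bb", "p.O.bb", "p.C.sc", "p.N.sc",
    "p.O.sc", "p.S.sc", "p.other")
  ligand_types <- c("l.C.ar", "l.C", "l.N.ar", "l.N", "l.O", "l.S", "l.P",
    "l.hal", "l.other")
  protein_map <- function(res_name, atom_name) {
    atom_name <- toupper(trimws(atom_name))
    elem <- substr(sub("^[0-9]+", "", atom_name), 1, 1)
    bb <- atom_name %in% c("N", "CA", "C", "O", "OXT")
    ifelse(bb & elem == "C", "p.C.bb",
      ifelse(bb & elem == "N", "p.N.bb",
        ifelse(bb & elem == "O", "p.O.bb",
          ifelse(elem == "C", "p.C.sc",
            ifelse(elem == "N", "p.N.sc",
              ifelse(elem == "O", "p.O.sc",
                ifelse(elem == "S", "p.S.sc", "p.other")))))))
  }
  ligand_map <- function(element, aromatic) {
    element <- toupper(element)
    ifelse(element == "C" & aromatic, "l.C.ar",
      ifelse(element == "C", "l.C",
        ifelse(element == "N" & aromatic, "l.N.ar",
          ifelse(element == "N", "l.N",
            ifelse(element == "O", "l.O",
              ifelse(element == "S", "l.S",
                ifelse(element == "P", "l.P",
                  ifelse(element %in% c("F", "CL", "BR", "I"), "l.hal",
                    "l.other"))))))))
  }
  structure(
    list(
      protein_types = protein_types, ligand_types = ligand_types,
      n_types = length(protein_types) + length(ligand_types),
      protein_map = protein_map, ligand_map = ligand_map
    ),
    class = "atom_typing"
  )
}

#' Distance binning for the statistical potential
#'
#' Half-open bins `[edge_k, edge_{k+1})`; pairs at or beyond the last edge
#' (`r_cut`) are ignored.
#'
#' @param width Bin width in Angstrom (default 0.5).
#' @param r_cut Distance cutoff in Angstrom (default 14.5).
#' @param r_min Lower edge of the first bin (default 0).
#' @return An object of class `distance_binning`.
#' @export
distance_binning <- function(width = 0.5, r_cut = 14.5, r_min = 0) {
  edges <- seq(r_min, r_cut, by = width)
  if (length(edges) < 3 || any(diff(edges) <= 0)) {
    abort("bin edges must be strictly increasing")
  }
  structure(
    list(
      edges = edges, width = diff(edges), r_cut = r_cut,
      centers = (head(edges, -1) + tail(edges, -1)) / 2,
      n_bins = length(edges) - 1
    ),
    class = "distance_binning"
  )
}

bin_of <- function(binning, d) {
  b <- findInterval(d, binning$edges, rightmost.closed = FALSE)
  b[d >= binning$r_cut | b < 1] <- NA_integer_
  b
}

protein_heavy_typed <- function(structure, typing) {
  a <- structure$atoms %>% filter(.data$element != "H")
  list(
    xyz = as.matrix(a[, c("x", "y", "z")]),
    type = typing$protein_map(a$res_name, a$name)
  )
}

ligand_heavy_typed <- function(pose, typing) {
  list(
    xyz = mol_coords(pose),
    type = typing$ligand_map(pose$atoms$element, pose$atoms$aromatic)
  )
}

#' Count protein-ligand atom-pair contacts by distance bin
#'
#' Every protein-heavy-atom/ligand-heavy-atom pair within the cutoff is
#' counted into its distance bin; pairs at or beyond `r_cut` are ignored.
#'
#' @param complexes Non-empty list of `list(structure =, pose =)` entries.
#' @param typing An [default_atom_typing()] scheme.
#' @param binning A [distance_binning()].
#' @return An object of class `contact_counts` wrapping the 3-way count array
#'   `counts[protein type, ligand type, bin]`.
#' @export
count_contacts <- function(complexes, typing = default_atom_typing(),
                           binning = distance_binning()) {
  if (!length(complexes)) abort("at least one complex is required")
  counts <- array(
    0,
    dim = c(length(typing$protein_types), length(typing$ligand_types),
      binning$n_bins),
    dimnames = list(typing$protein_types, typing$ligand_types, NULL)
  )
  for (cx in complexes) {
    p <- protein_heavy_typed(cx$structure, typing)
    l <- ligand_heavy_typed(cx$pose, typing)
    d2 <- outer(rowSums(p$xyz^2), rowSums(l$xyz^2), "+") - 2 * p$xyz %*% t(l$xyz)
    d <- sqrt(pmax(d2, 0))
    bins <- matrix(bin_of(binning, d), nrow(d), ncol(d))
    ok <- which(!is.na(bins), arr.ind = TRUE)
    if (nrow(ok)) {
      pi_ <- match(p$type[ok[, 1]], typing$protein_types)
      li <- match(l$type[ok[, 2]], typing$ligand_types)
      bi <- bins[ok]
      tab <- table(factor(
        paste(pi_, li, bi),
        levels = unique(paste(pi_, li, bi))
      ))
      key <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
      idx <- cbind(as.integer(key[, 1]), as.integer(key[, 2]), as.integer(key[, 3]))
      counts[idx] <- counts[idx] + as.numeric(tab)
    }
  }
  structure(
    list(counts = counts, typing = typing, binning = binning,
      n_complexes = length(complexes)),
    class = "contact_counts"
  )
}

#' Train a distance-scaled finite ideal-gas reference potential
#'
#' DFIRE-style energies: for each type pair and distance bin,
#' `u = -eta * ln[(N(i,j,r) + pc) / ((r/r_cut)^alpha * (dr/dr_cut) * (N(i,j,last bin) + pc))]`,
#' where `r` is the bin center and `r_cut` the center of the last bin (so the
#' last bin is the zero of the energy scale), `alpha` is the distance-scaling
#' exponent of the finite ideal-gas reference and the pseudocount keeps every
#' entry defined.
#'
#' @param counts A [count_contacts()] result.
#' @param alpha Distance-scaling exponent (default 1.61).
#' @param eta Energy scale in arbitrary units (default 1).
#' @param pseudocount Added to every observed and reference count (default 1).
#' @return An object of class `potential_table`.
#' @export
train_potential <- function(counts, alpha = 1.61, eta = 1.0, pseudocount = 1) {
  b <- counts$binning
  n_bins <- b$n_bins
  rc <- b$centers
  r_ref <- rc[n_bins]
  dr_ref <- b$width[n_bins]
  ref_shape <- (rc / r_ref)^alpha * (b$width / dr_ref) # per-bin reference
  n <- counts$counts
  n_last <- n[, , n_bins, drop = FALSE]
  u <- array(
    NA_real_, dim = dim(n),
    dimnames = dimnames(n)
  )
  for (k in seq_len(n_bins)) {
    u[, , k] <- -eta * log(
      (n[, , k] + pseudocount) /
        (ref_shape[k] * (n_last[, , 1] + pseudocount))
    )
  }
  structure(
    list(
      u = u, alpha = alpha, eta = eta, pseudocount = pseudocount,
      binning = b, typing = counts$typing
    ),
    class = "potential_table"
  )
}

#' @export
print.potential_table <- function(x, ...) {
  cat(sprintf(
    "<potential_table> %d x %d type pairs, %d bins to %.1f A, alpha = %.2f\n",
    dim(x$u)[1], dim(x$u)[2], x$binning$n_bins, x$binning$r_cut, x$alpha
  ))
  invisible(x)
}

#' @export
tidy.potential_table <- function(x, ...) {
  dn <- dimnames(x$u)
  expand.grid(
    protein_type = dn[[1]], ligand_type = dn[[2]],
    bin = seq_len(dim(x$u)[3]), stringsAsFactors = FALSE
  ) %>%
    as_tibble() %>%
    mutate(
      r = x$binning$centers[.data$bin],
      u = as.vector(x$u)
    )
}

#' @export
autoplot.potential_table <- function(object, pairs = NULL, ...) {
  df <- tidy(object)
  if (!is.null(pairs)) {
    df <- df %>% filter(paste(.data$protein_type, .data$ligand_type) %in% pairs)
  }
  ggplot(df, aes(x = .data$r, y = .data$u)) +
    geom_line() +
    facet_wrap(~ paste(protein_type, ligand_type), scales = "free_y") +
    labs(x = "distance (A)", y = "u (arbitrary units)") +
    theme_minimal()
}

#' Score a protein-ligand complex with a trained potential
#'
#' Sum of the tabulated pair energies over all protein-heavy/ligand-heavy
#' atom pairs within the cutoff; lower is more favorable.  A ligand beyond
#' the cutoff of every protein atom scores 0.
#'
#' @param structure A [mol_structure()].
#' @param pose A `small_mol` with coordinates in the structure's frame.
#' @param table A [train_potential()] result.
#' @return Energy in the table's (arbitrary) units.
#' @export
score_complex <- function(structure, pose, table) {
  typing <- table$typing
  p <- protein_heavy_typed(structure, typing)
  l <- ligand_heavy_typed(pose, typing)
  d2 <- outer(rowSums(p$xyz^2), rowSums(l$xyz^2), "+") - 2 * p$xyz %*% t(l$xyz)
  d <- sqrt(pmax(d2, 0))
  bins <- matrix(bin_of(table$binning, d), nrow(d), ncol(d))
  ok <- which(!is.na(bins), arr.ind = TRUE)
  if (!nrow(ok)) return(0)
  pi_ <- match(p$type[ok[, 1]], typing$protein_types)
  li <- match(l$type[ok[, 2]], typing$ligand_types)
  sum(table$u[cbind(pi_, li, bins[ok])])
}

#' Compare source and destination complex energies
#'
#' For repositioning records that carry one source-complex energy and one or
#' more destination-complex energies, computes the Pearson correlation
#' between source energies and mean destination energies, the least-squares
#' slope, and the standard error of each destination mean.
#'
#' @param records Data frame with columns `source_energy` (numeric) and
#'   `destination_energies` (list of numeric vectors), at least 3 rows.
#' @return An object of class `sd_comparison`.
#' @export
compare_source_destination <- function(records) {
  df <- as_tibble(records)
  if (!all(c("source_energy", "destination_energies") %in% names(df))) {
    abort("records need columns source_energy and destination_energies")
  }
  if (nrow(df) < 3) abort("at least 3 records are required")
  df <- df %>%
    mutate(
      dest_mean = map_dbl(.data$destination_energies, mean),
      dest_se = map_dbl(.data$destination_energies, function(x) {
        if (length(x) < 2) 0 else sd(x) / sqrt(length(x))
      })
    )
  if (sd(df$source_energy) == 0 || sd(df$dest_mean) == 0) {
    abort("degenerate variance: energies are constant")
  }
  fit <- lm(dest_mean ~ source_energy, data = df)
  structure(
    list(
      data = df,
      correlation = cor(df$source_energy, df$dest_mean),
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      n = nrow(df)
    ),
    class = "sd_comparison"
  )
}

#' @export
print.sd_comparison <- function(x, ...) {
  cat(sprintf(
    "<sd_comparison> n = %d, Pearson r = %.3f, slope = %.3f\n",
    x$n, x$correlation, x$slope
  ))
  invisible(x)
}

#' @export
tidy.sd_comparison <- function(x, ...) {
  x$data %>% select("source_energy", "dest_mean", "dest_se")
}

#' @export
glance.sd_comparison <- function(x, ...) {
  tibble(
    n = x$n, correlation = x$correlation, slope = x$slope,
    intercept = x$intercept
  )
}

#' @export
autoplot.sd_comparison <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$source_energy, y = .data$dest_mean)) +
    geom_errorbar(
      aes(ymin = .data$dest_mean - .data$dest_se,
        ymax = .data$dest_mean + .data$dest_se),
      width = 0, color = "grey60"
    ) +
    geom_point() +
    geom_abline(
      slope = object$slope, intercept = object$intercept,
      linetype = "dashed"
    ) +
    labs(
      x = "source complex energy", y = "mean destination complex energy",
      title = sprintf("Pearson r = %.2f", object$correlation)
    ) +
    theme_minimal()
}

#' Serialize a potential table to JSON
#' @param table A `potential_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_potential <- function(table, path) {
  obj <- list(
    alpha = table$alpha, eta = table$eta, pseudocount = table$pseudocount,
    edges = table$binning$edges,
    protein_types = table$typing$protein_types,
    ligand_types = table$typing$ligand_types,
    u = as.vector(table$u), dim = dim(table$u)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a potential table written by [write_potential()]
#' @param path JSON path.
#' @return A `potential_table`.
#' @export
read_potential <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  typing <- default_atom_typing()
  if (!identical(typing$protein_types, obj$protein_types) ||
      !identical(typing$ligand_types, obj$ligand_types)) {
    abort("potential file uses an unknown atom typing")
  }
  b <- distance_binning(
    width = obj$edges[2] - obj$edges[1],
    r_cut = obj$edges[length(obj$edges)], r_min = obj$edges[1]
  )
  u <- array(obj$u, dim = obj$dim,
    dimnames = list(obj$protein_types, obj$ligand_types, NULL))
  structure(
    list(u = u, alpha = obj$alpha, eta = obj$eta,
      pseudocount = obj$pseudocount, binning = b, typing = typing),
    class = "potential_table"
  )
}
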