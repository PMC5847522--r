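# Shared in-code fixtures: a tiny PDB text, bare molecules, simple geometry.

pdb_atom_line <- function(record, serial, name, res, chain, resnum, x, y, z,
                          occ = 1, element = substr(name, 1, 1)) {
  name_fmt <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf(
    "%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    record, serial, name_fmt, res, chain, resnum, x, y, z, occ, 0, element
  )
}

# three-ALA chain with one 5-heavy-atom ligand and two waters
write_tiny_pdb <- function(path) {
  lines <- c(
    pdb_atom_line("ATOM", 1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_atom_line("ATOM", 2, "CA", "ALA", "A", 1, 1.46, 0, 0),
    pdb_atom_line("ATOM", 3, "C", "ALA", "A", 1, 2.0, 1.4, 0),
    pdb_atom_line("ATOM", 4, "O", "ALA", "A", 1, 1.3, 2.4, 0, element = "O"),
    pdb_atom_line("ATOM", 5, "CB", "ALA", "A", 1, 2.0, -1.2, 0.9),
    pdb_atom_line("ATOM", 6, "N", "ALA", "A", 2, 3.3, 1.5, 0, element = "N"),
    pdb_atom_line("ATOM", 7, "CA", "ALA", "A", 2, 4.0, 2.8, 0),
    pdb_atom_line("ATOM", 8, "C", "ALA", "A", 2, 5.5, 2.6, 0),
    pdb_atom_line("ATOM", 9, "O", "ALA", "A", 2, 6.1, 1.5, 0, element = "O"),
    pdb_atom_line("ATOM", 10, "CB", "ALA", "A", 2, 3.6, 3.6, 1.2),
    pdb_atom_line("ATOM", 11, "N", "ALA", "A", 3, 6.1, 3.7, 0, element = "N"),
    pdb_atom_line("ATOM", 12, "CA", "ALA", "A", 3, 7.5, 3.8, 0.4),
    pdb_atom_line("ATOM", 13, "C", "ALA", "A", 3, 8.4, 4.6, -0.5),
    pdb_atom_line("ATOM", 14, "O", "ALA", "A", 3, 8.0, 5.6, -1.1, element = "O"),
    pdb_atom_line("ATOM", 15, "CB", "ALA", "A", 3, 7.6, 4.4, 1.8),
    pdb_atom_line("HETATM", 16, "C1", "LIG", "A", 101, 3.0, 0.5, 3.0),
    pdb_atom_line("HETATM", 17, "C2", "LIG", "A", 101, 4.4, 0.9, 3.2),
    pdb_atom_line("HETATM", 18, "O1", "LIG", "A", 101, 5.0, 1.8, 2.4, element = "O"),
    pdb_atom_line("HETATM", 19, "N1", "LIG", "A", 101, 5.1, 0.3, 4.2, element = "N"),
    pdb_atom_line("HETATM", 20, "C3", "LIG", "A", 101, 6.5, 0.6, 4.4),
    pdb_atom_line("HETATM", 21, "O", "HOH", "A", 201, 9, 9, 9, element = "O"),
    pdb_atom_line("HETATM", 22, "O", "HOH", "A", 202, 10, 10, 10, element = "O"),
    "END"
  )
  writeLines(lines, path)
  path
}

# bare molecule straight from coordinates (no chemistry needed)
coords_mol <- function(xyz, elements = NULL, id = "m", aromatic = FALSE) {
  xyz <- rbind(as.matrix(xyz))
  n <- nrow(xyz)
  if (is.null(elements)) elements <- rep("C", n)
  small_molecule(
    tibble::tibble(
      element = elements, charge = 0L,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      aromatic = rep_len(aromatic, n), h_count = 0L
    ),
    tibble::tibble(i = integer(), j = integer(), order = integer(),
      aromatic = logical()),
    id = id
  )
}

rotz90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# exhaustive maximum-total assignment oracle (enumeration over injections)
brute_force_assignment <- function(m) {
  na <- nrow(m)
  nb <- ncol(m)
  if (na > nb) return(brute_force_assignment(t(m)))
  all_injections <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    unlist(
      lapply(seq_along(v), function(i) {
        lapply(all_injections(v[-i], k - 1), function(r) c(v[i], r))
      }),
      recursive = FALSE
    )
  }
  best <- -Inf
  for (p in all_injections(seq_len(nb), na)) {
    best <- max(best, sum(m[cbind(seq_len(na), p)]))
  }
  best
}

# brute-force BEDROC: exponential rank sum normalized by the extreme rankings
brute_force_bedroc <- function(active_ranks, n_total, alpha) {
  n <- length(active_ranks)
  s <- sum(exp(-alpha * active_ranks / n_total))
  s_max <- sum(exp(-alpha * seq_len(n) / n_total))
  s_min <- sum(exp(-alpha * ((n_total - n + 1):n_total) / n_total))
  (s - s_min) / (s_max - s_min)
}

case_from_ranks <- function(active_ranks, n_total, query_id = "q") {
  recognition_case(
    tibble::tibble(
      candidate_id = sprintf("c%04d", seq_len(n_total)),
      score = n_total:1,
      is_active = seq_len(n_total) %in% active_ranks
    ),
    query_id = query_id
  )
}

# exact expectation of BEDROC under a uniform random ranking: the metric is
# the min-max normalized exponential rank sum, and expectation is linear
exact_random_bedroc <- function(n_total, n_active, alpha) {
  r <- seq_len(n_total)
  e_s <- n_active * mean(exp(-alpha * r / n_total))
  s_max <- sum(exp(-alpha * seq_len(n_active) / n_total))
  s_min <- sum(exp(-alpha * ((n_total - n_active + 1):n_total) / n_total))
  (e_s - s_min) / (s_max - s_min)
}
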