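# Deterministic synthetic fixtures.  Every generator routes all randomness
# through one Mersenne-Twister stream seeded by its `seed` argument, so
# identical specs yield byte-identical artifacts on any platform.  Toy
# "proteins" are Calpha+Cbeta skeletons: enough geometry for contacts,
# clashes and features without rotamer chemistry.

# sampling alphabet for toy pockets: glycine is excluded because its empty
# side chain makes even a GLY-GLY pair imperfect under the size-ratio term,
# and the generators promise ems = 1 for an exact copy
aa3_codes <- function() setdiff(names(KD_HYDROPATHY), "GLY")

random_unit_vectors <- function(n) {
  v <- matrix(rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

build_toy_structure <- function(id, res_name, ca, cb) {
  n <- nrow(ca)
  atoms <- bind_rows(
    tibble(
      serial = 2L * seq_len(n) - 1L, name = "CA", altloc = "",
      res_name = res_name, chain = "A", resnum = seq_len(n), icode = "",
      x = ca[, 1], y = ca[, 2], z = ca[, 3],
      occupancy = 1, element = "C", hetero = FALSE
    ),
    tibble(
      serial = 2L * seq_len(n), name = "CB", altloc = "",
      res_name = res_name, chain = "A", resnum = seq_len(n), icode = "",
      x = cb[, 1], y = cb[, 2], z = cb[, 3],
      occupancy = 1, element = "C", hetero = FALSE
    )
  ) %>% arrange(.data$serial)
  # glycine has no Cbeta
  atoms <- atoms %>% filter(!(.data$name == "CB" & .data$res_name == "GLY"))
  mol_structure(atoms, id = id)
}

#' Generate a toy pocket
#'
#' Places `n_residues` Calpha atoms on a jittered sphere of radius 8 Angstrom
#' around the origin, with residue types (hence features) drawn at random;
#' Cbeta pseudo-atoms point outward.  Deterministic under `seed`.
#'
#' @param n_residues Number of binding residues (>= 5).
#' @param seed Integer seed.
#' @param radius Sphere radius in Angstrom (default 8).
#' @param jitter Radial jitter standard deviation in Angstrom (default 1).
#' @param target_id Identifier for the pocket and its backing structure.
#' @return List with elements `pocket` (a [new_pocket()]) and `structure`
#'   (the backing [mol_structure()]).
#' @export
make_toy_pocket <- function(n_residues = 13, seed = 1, radius = 8, jitter = 1,
                            target_id = paste0("toy", seed)) {
  if (n_residues < 5) abort("a toy pocket needs at least 5 residues")
  with_seed(seed, {
    dirs <- random_unit_vectors(n_residues)
    r <- radius + rnorm(n_residues, sd = jitter)
    ca <- dirs * r
    cb <- dirs * (r + 1.5)
    res_name <- sample(aa3_codes(), n_residues, replace = TRUE)
    st <- build_toy_structure(target_id, res_name, ca, cb)
    res <- tibble(
      chain = "A", resnum = seq_len(n_residues), icode = "",
      res_name = res_name,
      ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3]
    )
    res <- bind_cols(res, residue_features(res_name))
    list(
      pocket = new_pocket(target_id, res, center = c(0, 0, 0), confidence = 100),
      structure = st
    )
  })
}

#' Derive a similar pocket from a parent
#'
#' Keeps `ceiling(overlap * n)` of the parent's residues (with optional
#' coordinate and feature noise) and replaces the rest with fresh random
#' residues on the sphere.  With `overlap = 1` and zero noise the derived
#' pocket matches its parent with an eMS score of 1.
#'
#' @param parent A [new_pocket()] (typically from [make_toy_pocket()]).
#' @param overlap Fraction of residues kept, in \[0, 1\].
#' @param feature_noise Feature perturbation scale (>= 0): hydropathy jitter
#'   of sd `3 * feature_noise` plus flips of the categorical features with
#'   probability `min(feature_noise, 1) / 2`.
#' @param coord_noise Calpha coordinate jitter sd in Angstrom.
#' @param seed Integer seed.
#' @param target_id Identifier of the derived pocket.
#' @return A [new_pocket()].
#' @export
derive_similar_pocket <- function(parent, overlap = 1, feature_noise = 0,
                                  coord_noise = 0, seed = 1,
                                  target_id = paste0(parent$target_id, "_d", seed)) {
  if (overlap < 0 || overlap > 1) abort("overlap must lie in [0, 1]")
  n <- nrow(parent$residues)
  n_keep <- ceiling(overlap * n)
  with_seed(seed, {
    res <- parent$residues
    keep_idx <- if (n_keep > 0) sort(sample.int(n, n_keep)) else integer()
    res <- res[keep_idx, , drop = FALSE]
    if (nrow(res) && coord_noise > 0) {
      res$ca_x <- res$ca_x + rnorm(nrow(res), sd = coord_noise)
      res$ca_y <- res$ca_y + rnorm(nrow(res), sd = coord_noise)
      res$ca_z <- res$ca_z + rnorm(nrow(res), sd = coord_noise)
    }
    if (nrow(res) && feature_noise > 0) {
      p_flip <- min(feature_noise, 1) / 2
      res$hydrophobicity <- res$hydrophobicity + rnorm(nrow(res), sd = 3 * feature_noise)
      flip <- runif(nrow(res)) < p_flip
      res$charge_class[flip] <- sample(c(-1, 0, 1), sum(flip), replace = TRUE)
      flip <- runif(nrow(res)) < p_flip
      res$polar[flip] <- !res$polar[flip]
      flip <- runif(nrow(res)) < p_flip
      res$aromatic[flip] <- !res$aromatic[flip]
    }
    n_new <- n - nrow(res)
    if (n_new > 0) {
      dirs <- random_unit_vectors(n_new)
      r <- 8 + rnorm(n_new)
      ca <- dirs * r
      rn <- sample(aa3_codes(), n_new, replace = TRUE)
      fresh <- tibble(
        chain = "A", resnum = n + seq_len(n_new), icode = "",
        res_name = rn, ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3]
      )
      fresh <- bind_cols(fresh, residue_features(rn))
      res <- bind_rows(res, fresh)
    }
    new_pocket(target_id, res, center = parent$center,
      confidence = parent$confidence)
  })
}

#' Generate a screening library with planted enrichment
#'
#' Builds one recognition case (candidate compounds with binary activity
#' labels and scores) and a pair of rank lists emulating the same library
#' docked against two pockets.  Actives receive a score bonus proportional
#' to `enrichment`; the two pockets' docking scores share a latent signal
#' calibrated so that Spearman's rho between the rank lists recovers
#' `rho_target` (via the bivariate-normal rank-correlation identity).
#'
#' @param n_total Library size.
#' @param n_active Number of planted actives (1 <= n_active < n_total).
#' @param enrichment Score bonus (in score-sd units) given to actives.
#' @param seed Integer seed.
#' @param rho_target Spearman correlation between the paired rank lists.
#' @param query_id Identifier stamped on the case and rank lists.
#' @return List with `case` ([recognition_case()]), `ranks_a`, `ranks_b`
#'   ([rank_list()] pair).
#' @export
make_screen_library <- function(n_total = 100, n_active = 5, enrichment = 2,
                                seed = 1, rho_target = 0.8,
                                query_id = paste0("q", seed)) {
  if (n_active < 1 || n_active >= n_total) {
    abort("need 1 <= n_active < n_total")
  }
  with_seed(seed, {
    is_active <- seq_len(n_total) <= n_active
    base <- rnorm(n_total)
    score_a <- base + enrichment * is_active
    rho_pearson <- 2 * sin(pi * min(max(rho_target, -1), 1) / 6)
    score_b <- rho_pearson * base + sqrt(1 - rho_pearson^2) * rnorm(n_total) +
      enrichment * is_active
    ids <- sprintf("cpd%04d", seq_len(n_total))
    case <- recognition_case(
      tibble(candidate_id = ids, score = score_a, is_active = is_active),
      query_id = query_id
    )
    list(
      case = case,
      ranks_a = rank_list(
        tibble(compound_id = ids, score = -score_a),
        target_id = paste0(query_id, "_a")
      ),
      ranks_b = rank_list(
        tibble(compound_id = ids, score = -score_b),
        target_id = paste0(query_id, "_b")
      )
    )
  })
}

#' Generate toy complexes for potential training
#'
#' Each complex is a sparse pseudo-protein (single-residue sites spaced far
#' apart, a mix of backbone-like and side-chain-like atom types) with ligand
#' atoms placed around the sites.  Background protein-ligand distances are
#' drawn from the finite ideal-gas reference density (proportional to
#' `r^alpha` up to the cutoff), so with no planted preference the trained
#' potential is flat; with probability `planted_pair_preference` each ligand
#' nitrogen is instead placed 3-4 Angstrom from a serine hydroxyl site,
#' enriching the (side-chain O, ligand N) pair at short range.
#'
#' @param n_complexes Number of complexes (>= 1).
#' @param planted_pair_preference Probability in \[0, 1\] of a short-range
#'   placement for the planted pair.
#' @param seed Integer seed.
#' @param n_sites Protein sites per complex (default 8).
#' @param n_ligand_atoms Ligand heavy atoms per complex (default 12).
#' @param alpha Reference exponent used for background distances (default
#'   1.61, matching [train_potential()]).
#' @param r_cut Distance cutoff (default 14.5).
#' @return List of `list(structure =, pose =)` entries; the planted type pair
#'   is recorded in attribute `planted_pair`.
#' @export
make_toy_complexes <- function(n_complexes, planted_pair_preference = 0,
                               seed = 1, n_sites = 8, n_ligand_atoms = 12,
                               alpha = 1.61, r_cut = 14.5) {
  if (n_complexes < 1) abort("n_complexes must be at least 1")
  r_min <- 2
  sample_ref_r <- function(n) {
    # inverse-CDF sampling from density proportional to r^alpha on [r_min, r_cut]
    u <- runif(n)
    ((u * (r_cut^(alpha + 1) - r_min^(alpha + 1))) + r_min^(alpha + 1))^(1 / (alpha + 1))
  }
  site_res <- c("SER", "ALA") # OG ~ side-chain O sites vs CB ~ side-chain C
  with_seed(seed, {
    complexes <- map(seq_len(n_complexes), function(cx) {
      # sites on a coarse grid, spacing 40 A > 2 * r_cut: each ligand atom
      # interacts with exactly one site
      grid <- expand.grid(gx = 0:3, gy = 0:1, gz = 0)[seq_len(n_sites), ]
      site_xyz <- as.matrix(grid) * 40
      res_name <- rep(site_res, length.out = n_sites)
      atom_name <- ifelse(res_name == "SER", "OG", "CB")
      element <- ifelse(res_name == "SER", "O", "C")
      atoms <- tibble(
        serial = seq_len(n_sites), name = atom_name, altloc = "",
        res_name = res_name, chain = "A", resnum = seq_len(n_sites),
        icode = "", x = site_xyz[, 1], y = site_xyz[, 2], z = site_xyz[, 3],
        occupancy = 1, element = element, hetero = FALSE
      )
      st <- mol_structure(atoms, id = sprintf("cx%04d", cx))
      lig_elem <- rep(c("N", "C"), length.out = n_ligand_atoms)
      o_sites <- which(element == "O")
      lig_xyz <- matrix(0, n_ligand_atoms, 3)
      for (k in seq_len(n_ligand_atoms)) {
        planted <- lig_elem[k] == "N" && length(o_sites) &&
          runif(1) < planted_pair_preference
        site <- if (planted) {
          o_sites[sample.int(length(o_sites), 1)]
        } else {
          sample.int(n_sites, 1)
        }
        r <- if (planted) runif(1, 3, 4) else sample_ref_r(1)
        lig_xyz[k, ] <- site_xyz[site, ] + random_unit_vectors(1) * r
      }
      pose <- small_molecule(
        tibble(
          element = lig_elem, charge = 0L,
          x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
          aromatic = FALSE, h_count = 0L
        ),
        tibble(i = integer(), j = integer(), order = integer(),
          aromatic = logical()),
        id = sprintf("lig%04d", cx)
      )
      list(structure = st, pose = pose)
    })
    attr(complexes, "planted_pair") <- c(protein = "p.O.sc", ligand = "l.N")
    complexes
  })
}

#' Synthetic pocket-recognition benchmark
#'
#' The desk-scale analogue of a holo/apo pocket-recognition experiment: each
#' query is a parent pocket; actives are pockets derived from the same parent
#' (high residue overlap), inactives are derived with low overlap, and both
#' carry feature and coordinate noise so that pocket matching alone is an
#' informative but imperfect classifier.  Every candidate additionally gets a
#' virtual-screening rank-correlation measured on a generated library pair
#' whose latent signal is present for actives and absent for inactives, so
#' fusing the two scores improves early recognition.
#'
#' Candidates are scored three ways: pocket similarity alone (`ems`), the
#' fused score (`combined`), and each is returned as a list of
#' [recognition_case()]s ready for [evaluate_recognition()].
#'
#' @param n_queries Number of query pockets (default 20).
#' @param n_active,n_inactive Candidates per query (defaults 5 and 10).
#' @param seed Integer seed.
#' @param active_overlap,inactive_overlap Residue overlap of derived pockets
#'   (defaults 0.65 and 0.25; chosen so the two classes overlap in eMS).
#' @param feature_noise,coord_noise Noise applied to all derived pockets
#'   (defaults 0.6 and 1.2 so pocket matching alone stays below ceiling).
#' @param rho_active Spearman signal of active rank-list pairs (default 0.7;
#'   inactives use 0).
#' @return List with `cases_ems`, `cases_combined` (lists of recognition
#'   cases) and `scores` (tibble of per-candidate ems, rho, combined).
#' @export
make_recognition_benchmark <- function(n_queries = 20, n_active = 5,
                                       n_inactive = 10, seed = 1,
                                       active_overlap = 0.65,
                                       inactive_overlap = 0.25,
                                       feature_noise = 0.6, coord_noise = 1.2,
                                       rho_active = 0.7) {
  rows <- list()
  for (q in seq_len(n_queries)) {
    qseed <- seed * 10000 + q * 100
    parent <- make_toy_pocket(n_residues = 12, seed = qseed,
      target_id = sprintf("query%02d", q))
    n_cand <- n_active + n_inactive
    for (k in seq_len(n_cand)) {
      active <- k <= n_active
      cand <- derive_similar_pocket(
        parent$pocket,
        overlap = if (active) active_overlap else inactive_overlap,
        feature_noise = feature_noise, coord_noise = coord_noise,
        seed = qseed + k,
        target_id = sprintf("q%02d_c%02d", q, k)
      )
      ems <- match_pockets(parent$pocket, cand)$ems_score
      lib <- make_screen_library(
        n_total = 50, n_active = 5, enrichment = 1.5,
        seed = qseed + k,
        rho_target = if (active) rho_active else 0
      )
      rho <- spearman_rho(lib$ranks_a, lib$ranks_b)$rho
      rows[[length(rows) + 1]] <- tibble(
        query = parent$pocket$target_id, candidate = cand$target_id,
        is_active = active, ems = ems, rho = rho,
        combined = combine_scores(ems, rho)
      )
    }
  }
  scores <- bind_rows(rows)
  split_cases <- function(score_col) {
    lapply(split(scores, scores$query), function(df) {
      recognition_case(
        tibble(
          candidate_id = df$candidate, score = df[[score_col]],
          is_active = df$is_active
        ),
        query_id = df$query[1]
      )
    })
  }
  list(
    cases_ems = split_cases("ems"),
    cases_combined = split_cases("combined"),
    scores = scores
  )
}

#' Write a self-contained fixture directory
#'
#' Generates toy pockets (with backing structure PDBs), a screening library
#' (rank-list TSVs) and pocket-annotation TSVs, plus a JSON manifest of the
#' generating parameters.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param n_pockets Number of parent pockets.
#' @return The directory path, invisibly.
#' @export
write_fixture_set <- function(dir, seed = 1, n_pockets = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pockets <- map(seq_len(n_pockets), function(k) {
    make_toy_pocket(n_residues = 13, seed = seed + k,
      target_id = sprintf("toy%02d", k))
  })
  for (p in pockets) {
    write_pdb(p$structure, file.path(dir, paste0(p$pocket$target_id, ".pdb")))
  }
  write_pockets(map(pockets, "pocket"), file.path(dir, "pockets.tsv"))
  lib <- make_screen_library(n_total = 100, n_active = 5, enrichment = 2,
    seed = seed)
  write_rank_list(lib$ranks_a, file.path(dir, "ranks_a.tsv"))
  write_rank_list(lib$ranks_b, file.path(dir, "ranks_b.tsv"))
  jsonlite::write_json(
    list(seed = seed, n_pockets = n_pockets, n_residues = 13,
      library = list(n_total = 100, n_active = 5, enrichment = 2)),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE
  )
  invisible(dir)
}
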