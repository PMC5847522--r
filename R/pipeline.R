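#' Repositioning configuration
#'
#' Filter thresholds and algorithm parameters for a repositioning run.  The
#' defaults are the drug-size and model-quality regime the pipeline targets:
#' drugs of 150-550 Da, targets of 50-999 residues with an estimated
#' GDT-score of at least 0.4, pockets of at least moderate confidence,
#' redundancy removal at 0.9 ligand Tanimoto similarity and 80% protein
#' sequence identity.
#'
#' @param mw_range Drug molecular-weight range in Da (inclusive).
#' @param length_range Protein length range in residues (inclusive).
#' @param min_gdt Minimum estimated model GDT-score.
#' @param confidence_tier Required pocket confidence tier (`"high"` or
#'   `"moderate"`).
#' @param tier_thresholds Lower bounds of the confidence tiers (percent).
#' @param ems_threshold Significance threshold on the eMS score.
#' @param ligand_tc Ligand-redundancy Tanimoto threshold (merge at >= tc).
#' @param protein_identity Protein-redundancy identity threshold (fraction,
#'   computed over the shorter sequence; merge at >= identity).
#' @param clash_cutoff,max_translation,step Clash-relief parameters (see
#'   [relieve_clashes()]).
#' @return A list of class `reposition_config`.
#' @export
reposition_config <- function(mw_range = c(150, 550),
                              length_range = c(50, 999),
                              min_gdt = 0.4,
                              confidence_tier = "moderate",
                              tier_thresholds = c(high = 80, moderate = 50),
                              ems_threshold = 0.80,
                              ligand_tc = 0.9,
                              protein_identity = 0.80,
                              clash_cutoff = 2.5,
                              max_translation = 3,
                              step = 0.1) {
  stopifnot(
    mw_range[1] <= mw_range[2], length_range[1] <= length_range[2],
    min_gdt >= 0, min_gdt <= 1,
    confidence_tier %in% c("high", "moderate", "low"),
    ligand_tc >= 0, ligand_tc <= 1,
    protein_identity >= 0, protein_identity <= 1
  )
  structure(
    list(
      mw_range = mw_range, length_range = length_range, min_gdt = min_gdt,
      confidence_tier = confidence_tier, tier_thresholds = tier_thresholds,
      ems_threshold = ems_threshold, ligand_tc = ligand_tc,
      protein_identity = protein_identity, clash_cutoff = clash_cutoff,
      max_translation = max_translation, step = step
    ),
    class = "reposition_config"
  )
}

tier_rank <- function(tier) match(tier, c("low", "moderate", "high"))

#' Apply the filter cascade
#'
#' Retains drugs with molecular weight in range, proteins with length in
#' range and model GDT at or above threshold, and pockets at the required
#' confidence tier.  Every exclusion is logged with its reason.
#'
#' @param drugs Tibble with columns `drug_id`, `mw`.
#' @param targets Tibble with columns `target_id`, `length`, `gdt`.
#' @param pockets Tibble with columns `target_id`, `confidence`.
#' @param config A [reposition_config()].
#' @return List with filtered `drugs`, `targets`, `pockets` tibbles and an
#'   `exclusions` tibble (`kind`, `id`, `reason`).
#' @export
apply_filters <- function(drugs, targets, pockets, config = reposition_config()) {
  drugs <- as_tibble(drugs)
  targets <- as_tibble(targets)
  pockets <- as_tibble(pockets)
  excl <- list()
  log_excl <- function(kind, id, reason) {
    excl[[length(excl) + 1]] <<- tibble(kind = kind, id = id, reason = reason)
  }
  d_low <- drugs$mw < config$mw_range[1]
  d_high <- drugs$mw > config$mw_range[2]
  for (i in which(d_low)) log_excl("drug", drugs$drug_id[i], "mw_below_range")
  for (i in which(d_high)) log_excl("drug", drugs$drug_id[i], "mw_above_range")
  t_short <- targets$length < config$length_range[1]
  t_long <- targets$length > config$length_range[2]
  t_gdt <- targets$gdt < config$min_gdt
  for (i in which(t_short)) log_excl("target", targets$target_id[i], "length_below_range")
  for (i in which(t_long & !t_short)) log_excl("target", targets$target_id[i], "length_above_range")
  for (i in which(t_gdt & !t_short & !t_long)) log_excl("target", targets$target_id[i], "gdt_below_threshold")
  keep_targets <- !(t_short | t_long | t_gdt)
  p_tier <- confidence_tier(pockets$confidence, config$tier_thresholds)
  p_low <- tier_rank(p_tier) < tier_rank(config$confidence_tier)
  p_orphan <- !pockets$target_id %in% targets$target_id[keep_targets]
  for (i in which(p_low)) {
    log_excl("pocket", pockets$target_id[i], "confidence_below_tier")
  }
  for (i in which(p_orphan & !p_low)) {
    log_excl("pocket", pockets$target_id[i], "target_excluded")
  }
  list(
    drugs = drugs[!(d_low | d_high), , drop = FALSE],
    targets = targets[keep_targets, , drop = FALSE],
    pockets = pockets[!(p_low | p_orphan), , drop = FALSE],
    exclusions = if (length(excl)) bind_rows(excl) else
      tibble(kind = character(), id = character(), reason = character())
  )
}

#' Global sequence identity between two protein sequences
#'
#' Needleman-Wunsch global alignment identity, normalized by the shorter
#' sequence length.
#'
#' @param a,b Amino-acid sequences (1-letter strings).
#' @return Identity fraction in \[0, 1\].
#' @export
sequence_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global"
  )
  Biostrings::pid(aln, type = "PID3") / 100
}

greedy_cluster <- function(ids, sim_fun, threshold) {
  ord <- order(ids)
  reps <- character()
  members <- list()
  assign_to <- setNames(character(length(ids)), ids)
  for (i in ord) {
    id <- ids[i]
    placed <- FALSE
    for (r in reps) {
      if (sim_fun(id, r) >= threshold) {
        members[[r]] <- c(members[[r]], id)
        assign_to[id] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      members[[id]] <- id
      assign_to[id] <- id
    }
  }
  list(representatives = reps, members = members, assignment = assign_to)
}

#' Remove redundant drugs and targets
#'
#' Greedy clustering (in id order; the first member of each cluster is its
#' representative) of drugs at the ligand Tanimoto threshold and of targets
#' at the protein sequence-identity threshold.
#'
#' @param drugs Tibble with columns `drug_id` and `mol` (list of
#'   `small_mol`).
#' @param targets Tibble with columns `target_id` and `sequence` (1-letter
#'   amino-acid strings).
#' @param config A [reposition_config()].
#' @return List with non-redundant `drugs` and `targets` tibbles and the
#'   cluster memberships (`drug_clusters`, `target_clusters`).
#' @export
deduplicate <- function(drugs, targets, config = reposition_config()) {
  drugs <- as_tibble(drugs)
  targets <- as_tibble(targets)
  fps <- setNames(map(drugs$mol, fingerprint), drugs$drug_id)
  drug_sim <- function(a, b) tanimoto(fps[[a]], fps[[b]])
  dc <- greedy_cluster(drugs$drug_id, drug_sim, config$ligand_tc)
  seqs <- setNames(targets$sequence, targets$target_id)
  tgt_sim <- function(a, b) sequence_identity(seqs[[a]], seqs[[b]])
  tc <- greedy_cluster(targets$target_id, tgt_sim, config$protein_identity)
  list(
    drugs = drugs %>% filter(.data$drug_id %in% dc$representatives),
    targets = targets %>% filter(.data$target_id %in% tc$representatives),
    drug_clusters = dc$members,
    target_clusters = tc$members
  )
}

#' Run the repositioning engine over source and destination sets
#'
#' All-against-all pocket matching between source entries (pockets carrying
#' bound drug poses) and destination entries; for every significant match,
#' each drug bound to the source is transferred through the alignment,
#' clashes against the destination structure are relieved, and the complex
#' is scored with the statistical potential (when supplied).  When both
#' sides carry rank lists, the Spearman similarity and the combined score
#' are attached.  A drug reaching one destination through several sources
#' yields one catalog row with all routes plus a consensus over its poses.
#'
#' @param sources List of entries `list(pocket =, structure =, drugs = list
#'   of list(drug_id =, pose = drug_pose), ranks = optional rank_list)`.
#' @param destinations List of entries `list(pocket =, structure =, ranks =
#'   optional rank_list)`.
#' @param config A [reposition_config()].
#' @param potential Optional [train_potential()] table for complex scoring.
#' @return An object of class `repositioning_run`: `records` (one row per
#'   route), `catalog` (one row per drug-destination pair), `consensus`
#'   (named list of [consensus_pose()] results), `matches` (all pair scores).
#' @export
run_repositioning <- function(sources, destinations,
                              config = reposition_config(),
                              potential = NULL) {
  match_rows <- list()
  record_rows <- list()
  for (src in sources) {
    for (dst in destinations) {
      res <- match_pockets(src$pocket, dst$pocket,
        threshold = config$ems_threshold)
      aln_id <- paste0(src$pocket$target_id, "->", dst$pocket$target_id)
      match_rows[[length(match_rows) + 1]] <- tibble(
        source_id = src$pocket$target_id,
        destination_id = dst$pocket$target_id,
        ems = res$ems_score, significant = res$significant,
        n_aligned = res$alignment$n_aligned,
        aligned_rmsd = res$alignment$aligned_rmsd
      )
      if (!res$significant) next
      rho <- NA_real_
      if (!is.null(src$ranks) && !is.null(dst$ranks)) {
        rho <- spearman_rho(src$ranks, dst$ranks)$rho
      }
      combined <- if (is.na(rho)) NA_real_ else
        combine_scores(res$ems_score, rho)
      for (dr in src$drugs) {
        moved <- transfer_by_alignment(dr$pose, res$alignment,
          alignment_id = aln_id)
        relief <- relieve_clashes(moved, dst$structure,
          clash_cutoff = config$clash_cutoff,
          max_translation = config$max_translation, step = config$step)
        e_src <- if (is.null(potential)) NA_real_ else
          score_complex(src$structure, dr$pose$drug, potential)
        e_dst <- if (is.null(potential)) NA_real_ else
          score_complex(dst$structure, relief$pose$drug, potential)
        record_rows[[length(record_rows) + 1]] <- tibble(
          drug_id = dr$drug_id,
          source_id = src$pocket$target_id,
          destination_id = dst$pocket$target_id,
          ems = res$ems_score, rho = rho, combined = combined,
          dfire_source = e_src, dfire_destination = e_dst,
          n_residual_clashes = nrow(relief$clashes),
          displacement = relief$displacement,
          pose = list(relief$pose)
        )
      }
    }
  }
  records <- if (length(record_rows)) bind_rows(record_rows) else
    tibble(
      drug_id = character(), source_id = character(),
      destination_id = character(), ems = numeric(), rho = numeric(),
      combined = numeric(), dfire_source = numeric(),
      dfire_destination = numeric(), n_residual_clashes = integer(),
      displacement = numeric(), pose = list()
    )
  consensus <- list()
  catalog_rows <- list()
  if (nrow(records)) {
    grp <- records %>%
      group_by(.data$drug_id, .data$destination_id) %>%
      dplyr::group_split()
    for (g in grp) {
      key <- paste0(g$drug_id[1], "@", g$destination_id[1])
      cons_spread <- NA_real_
      if (nrow(g) >= 2) {
        cp <- consensus_pose(g$pose)
        consensus[[key]] <- cp
        best <- cp$typical_index
        cons_spread <- cp$spread[best]
      } else {
        best <- 1L
      }
      catalog_rows[[length(catalog_rows) + 1]] <- tibble(
        drug_id = g$drug_id[1], destination_id = g$destination_id[1],
        n_routes = nrow(g),
        sources = paste(g$source_id, collapse = ";"),
        best_ems = max(g$ems),
        ems = g$ems[best], rho = g$rho[best], combined = g$combined[best],
        dfire_source = g$dfire_source[best],
        dfire_destination = g$dfire_destination[best],
        consensus_spread = cons_spread
      )
    }
  }
  catalog <- if (length(catalog_rows)) {
    bind_rows(catalog_rows) %>% arrange(.data$drug_id, .data$destination_id)
  } else {
    tibble(
      drug_id = character(), destination_id = character(),
      n_routes = integer(), sources = character(), best_ems = numeric(),
      ems = numeric(), rho = numeric(), combined = numeric(),
      dfire_source = numeric(), dfire_destination = numeric(),
      consensus_spread = numeric()
    )
  }
  structure(
    list(
      records = records, catalog = catalog, consensus = consensus,
      matches = bind_rows(match_rows)
    ),
    class = "repositioning_run"
  )
}

#' @export
print.repositioning_run <- function(x, ...) {
  cat(sprintf(
    "<repositioning_run> %d pocket pairs (%d significant), %d records, %d catalog entries\n",
    nrow(x$matches), sum(x$matches$significant), nrow(x$records),
    nrow(x$catalog)
  ))
  invisible(x)
}

#' @export
tidy.repositioning_run <- function(x, ...) {
  select(x$records, -"pose")
}

#' @export
glance.repositioning_run <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$matches),
    n_significant = sum(x$matches$significant),
    n_records = nrow(x$records),
    n_catalog = nrow(x$catalog),
    median_ems_significant = if (any(x$matches$significant)) {
      median(x$matches$ems[x$matches$significant])
    } else {
      NA_real_
    }
  )
}

CATALOG_COLUMNS <- c(
  "drug_id", "destination_id", "n_routes", "sources", "best_ems", "ems",
  "rho", "combined", "dfire_source", "dfire_destination", "consensus_spread"
)

#' Export a repositioning catalog
#'
#' Writes the catalog as TSV (fixed column order) plus a JSON sidecar; the
#' TSV round-trips exactly through [read_catalog()].
#'
#' @param run A [run_repositioning()] result (or its catalog tibble).
#' @param path Output TSV path; the JSON sidecar replaces the extension.
#' @return The TSV path, invisibly.
#' @export
export_catalog <- function(run, path) {
  catalog <- if (inherits(run, "repositioning_run")) run$catalog else
    as_tibble(run)
  missing_cols <- setdiff(CATALOG_COLUMNS, names(catalog))
  if (length(missing_cols)) {
    abort(paste0("catalog lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- catalog[, CATALOG_COLUMNS]
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
    na = "NA")
  json_path <- sub("\\.tsv$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(path)
}

#' Read a catalog written by [export_catalog()]
#' @param path TSV path.
#' @return The catalog tibble.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
    na.strings = "NA")
  as_tibble(df) %>%
    mutate(
      drug_id = as.character(.data$drug_id),
      destination_id = as.character(.data$destination_id),
      sources = as.character(.data$sources)
    )
}
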