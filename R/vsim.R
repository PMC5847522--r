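#' Build a rank list from docking scores
#'
#' A per-target ranking of a screening library.  Lower (better) docking
#' scores receive smaller ranks; tied scores get average ranks.
#'
#' @param data Data frame with columns `compound_id` and `score` (docking
#'   score, lower is better).  An existing `rank` column is recomputed.
#' @param target_id Identifier of the screened target.
#' @return A tibble of class `rank_list` with columns `compound_id`, `score`,
#'   `rank`, and attribute `target_id`.
#' @export
rank_list <- function(data, target_id = "target") {
  df <- as_tibble(data)
  if (!all(c("compound_id", "score") %in% names(df))) {
    abort("rank list needs columns compound_id and score")
  }
  if (anyDuplicated(df$compound_id)) abort("duplicate compound ids in rank list")
  out <- df %>%
    mutate(rank = rank(.data$score, ties.method = "average")) %>%
    arrange(.data$rank)
  attr(out, "target_id") <- target_id
  class(out) <- c("rank_list", class(out))
  out
}

#' Read a rank-list TSV (compound_id, score, rank)
#' @param path Path to a tab-separated file.
#' @param target_id Target identifier (defaults to file name).
#' @return A [rank_list()].
#' @export
read_rank_list <- function(path, target_id = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  rank_list(df, target_id = target_id %||% sub("\\.tsv$", "", basename(path)))
}

#' Write a rank list to TSV
#' @param ranks A [rank_list()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rank_list <- function(ranks, path) {
  utils::write.table(
    ranks[, c("compound_id", "score", "rank")], path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Virtual-screening similarity of two pockets (Spearman's rho)
#'
#' Statistical dependence between the rankings two pockets impose on a shared
#' compound library: Spearman's rank correlation over the common compounds
#' (Pearson correlation of their average-rank vectors).
#'
#' @param a,b [rank_list()] objects sharing at least 3 compounds.
#' @return A one-row tibble of class `vs_similarity` with columns `rho` and
#'   `n_common`.
#' @export
spearman_rho <- function(a, b) {
  common <- intersect(a$compound_id, b$compound_id)
  if (length(common) < 3) {
    abort("rank lists share fewer than 3 compounds")
  }
  sa <- a$score[match(common, a$compound_id)]
  sb <- b$score[match(common, b$compound_id)]
  ra <- rank(sa, ties.method = "average")
  rb <- rank(sb, ties.method = "average")
  out <- tibble(rho = cor(ra, rb, method = "pearson"), n_common = length(common))
  class(out) <- c("vs_similarity", class(out))
  out
}

#' Fuse pocket similarity with virtual-screening similarity
#'
#' Arithmetic mean of the eMS score and the (negatively clamped) Spearman
#' rho: `(ems + max(rho, 0)) / 2`, a monotone bounded combination in
#' \[0, 1\].
#'
#' @param ems eMS score in \[0, 1\].
#' @param rho Spearman correlation in \[-1, 1\].
#' @return Combined score in \[0, 1\].
#' @export
combine_scores <- function(ems, rho) {
  if (any(ems < 0 | ems > 1)) abort("ems must lie in [0, 1]")
  if (any(rho < -1 | rho > 1)) abort("rho must lie in [-1, 1]")
  (ems + pmax(rho, 0)) / 2
}

#' Recognition case
#'
#' One evaluation unit for early-recognition statistics: a query and a scored
#' candidate list with binary activity labels.
#'
#' @param candidates Data frame with columns `candidate_id`, `score` (higher
#'   is better) and `is_active`.
#' @param query_id Identifier of the query.
#' @return A tibble of class `recognition_case`.
#' @export
recognition_case <- function(candidates, query_id = "query") {
  df <- as_tibble(candidates)
  if (!all(c("candidate_id", "score", "is_active") %in% names(df))) {
    abort("candidates need columns candidate_id, score, is_active")
  }
  if (!any(df$is_active) || all(df$is_active)) {
    abort("a recognition case needs at least one active and one inactive")
  }
  out <- df %>% arrange(dplyr::desc(.data$score), .data$candidate_id)
  attr(out, "query_id") <- query_id
  class(out) <- c("recognition_case", class(out))
  out
}

#' BEDROC early-recognition score
#'
#' Boltzmann-enhanced discrimination of ROC (Truchon-Bayly): candidates are
#' ranked by descending score (ties broken by candidate id), each active at
#' rank r contributes `exp(-alpha r / N)`, and the exponentially weighted sum
#' is normalized so the score lies in \[0, 1\], with ~80% of the weight in
#' the top `alpha/8`% of the list at the default `alpha = 20`.
#'
#' @param case A [recognition_case()] (or compatible data frame).
#' @param alpha Early-recognition exponent (default 20).
#' @return BEDROC in \[0, 1\].
#' @export
bedroc <- function(case, alpha = 20) {
  if (!inherits(case, "recognition_case")) case <- recognition_case(case)
  if (alpha <= 0) abort("alpha must be positive")
  n_total <- nrow(case)
  r_act <- which(case$is_active)
  n <- length(r_act)
  ra <- n / n_total
  s <- sum(exp(-alpha * r_act / n_total))
  rie <- s / ((n / n_total) * (1 - exp(-alpha)) / (exp(alpha / n_total) - 1))
  rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

#' Evaluate early recognition over a set of cases
#'
#' Per-case BEDROC plus the box-plot summary statistics (median, quartiles,
#' 1.5 IQR whisker bounds).
#'
#' @param cases List of [recognition_case()] objects.
#' @param alpha BEDROC exponent (default 20).
#' @return An object of class `recognition_eval`: `per_query` tibble and
#'   `summary` one-row tibble.
#' @export
evaluate_recognition <- function(cases, alpha = 20) {
  if (!length(cases)) abort("at least one recognition case is required")
  per <- tibble(
    query = map_chr(cases, ~ attr(.x, "query_id") %||% "query"),
    bedroc = map_dbl(cases, bedroc, alpha = alpha)
  )
  q <- quantile(per$bedroc, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  summary <- tibble(
    n = nrow(per), median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = max(min(per$bedroc), q[1] - 1.5 * iqr),
    whisker_high = min(max(per$bedroc), q[3] + 1.5 * iqr)
  )
  structure(
    list(per_query = per, summary = summary, alpha = alpha),
    class = "recognition_eval"
  )
}

#' @export
print.recognition_eval <- function(x, ...) {
  cat(sprintf(
    "<recognition_eval> %d queries, median BEDROC %.3f (Q1 %.3f, Q3 %.3f), alpha = %g\n",
    x$summary$n, x$summary$median, x$summary$q1, x$summary$q3, x$alpha
  ))
  invisible(x)
}

#' @export
tidy.recognition_eval <- function(x, ...) x$per_query

#' @export
glance.recognition_eval <- function(x, ...) x$summary

#' @export
autoplot.recognition_eval <- function(object, ...) {
  df <- mutate(object$per_query, group = "observed")
  ggplot(df, aes(x = .data$group, y = .data$bedroc)) +
    geom_boxplot(width = 0.3, outlier.shape = NA) +
    geom_jitter(width = 0.08, alpha = 0.6) +
    labs(
      x = NULL, y = "BEDROC",
      title = sprintf("Early recognition (alpha = %g)", object$alpha)
    ) +
    theme_minimal()
}

#' Random-classifier baseline for a recognition benchmark
#'
#' Re-scores every case with uniform random scores `n_rep` times and returns
#' the median BEDROC of each replicate; the null distribution against which
#' planted-signal benchmarks are compared.
#'
#' @param cases List of [recognition_case()] objects.
#' @param n_rep Number of replicates (>= 1).
#' @param seed Integer seed; the baseline is reproducible under a fixed seed.
#' @param alpha BEDROC exponent (default 20).
#' @return Tibble with columns `replicate`, `median_bedroc`.
#' @export
random_baseline <- function(cases, n_rep, seed = 1, alpha = 20) {
  if (n_rep < 1) abort("n_rep must be at least 1")
  with_seed(seed, {
    meds <- map_dbl(seq_len(n_rep), function(r) {
      shuffled <- map(cases, function(cs) {
        recognition_case(
          mutate(as_tibble(cs), score = runif(dplyr::n())),
          query_id = attr(cs, "query_id") %||% "query"
        )
      })
      median(map_dbl(shuffled, bedroc, alpha = alpha))
    })
    tibble(replicate = seq_len(n_rep), median_bedroc = meds)
  })
}
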