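#' Average transmembrane propensity of one sequence
#'
#' Computes the mean per-residue propensity H = (1/n) * sum(h_j) over the
#' scored region of a protein, where h_j is the scale value of the j-th
#' residue and n the number of scored residues. When `core_regions` are
#' supplied and `use_core = TRUE`, only residues inside those 1-based
#' inclusive intervals are scored (the intervals delineate the conserved
#' core helices); otherwise the full sequence is scored.
#'
#' Residues absent from the scale follow the scale's ambiguity policy:
#' `"skip"` excludes them from both the sum and n, `"error"` aborts.
#'
#' @param residues Character scalar, the amino-acid sequence.
#' @param scale A [tm_scale()] object.
#' @param use_core Score only `core_regions` instead of the full sequence.
#' @param core_regions Optional two-column matrix or data.frame of
#'   (aa_start, aa_end) 1-based inclusive intervals, non-overlapping, sorted.
#' @return The propensity score, a single number in scale units.
#' @export
#' @examples
#' sequence_tm_score("FFFF", tm_tendency_scale())  # 1.98
sequence_tm_score <- function(residues, scale, use_core = FALSE,
                              core_regions = NULL) {
  fc_assert(inherits(scale, "tm_scale"), "'scale' must be a tm_scale object",
            class = "famcontext_parameter_error")
  fc_assert(is.character(residues) && length(residues) == 1L &&
              nzchar(residues), "'residues' must be a non-empty string")
  aa <- strsplit(toupper(residues), "")[[1]]
  n_total <- length(aa)
  if (isTRUE(use_core)) {
    fc_assert(!is.null(core_regions),
              "use_core = TRUE requires core_regions",
              class = "famcontext_parameter_error")
    cr <- as.matrix(core_regions[, 1:2, drop = FALSE])
    storage.mode(cr) <- "integer"
    fc_assert(all(cr[, 1] >= 1L) && all(cr[, 2] >= cr[, 1]) &&
                all(cr[, 2] <= n_total),
              "core_regions must be 1-based intervals within the sequence")
    keep <- unlist(lapply(seq_len(nrow(cr)),
                          function(i) seq.int(cr[i, 1], cr[i, 2])))
    fc_assert(!anyDuplicated(keep), "core_regions must not overlap")
    aa <- aa[fc_sort(keep)]
  }
  h <- unclass(scale)[aa]
  unknown <- is.na(h)
  if (any(unknown)) {
    if (attr(scale, "ambiguity_policy") == "error") {
      fc_abort(sprintf("residue(s) absent from scale: %s",
                       paste(unique(aa[unknown]), collapse = ", ")),
               class = "famcontext_scoring_error")
    }
    message(sprintf("skipped %d ambiguous residue(s)", sum(unknown)))
    h <- h[!unknown]
  }
  fc_assert(length(h) > 0L, "no scorable residues after ambiguity policy",
            class = "famcontext_scoring_error")
  mean(h)
}

#' Per-family propensity score sets
#'
#' Scores every sequence with [sequence_tm_score()] and groups the scores by
#' family. The result is order-independent: permuting the input rows yields
#' identical score multisets.
#'
#' @param records Data frame with columns `sequence_id`, `family_id`,
#'   `residues` (see [read_family_fasta()]).
#' @param scale A [tm_scale()] object.
#' @param use_core Score only core regions.
#' @param core_regions Optional data frame (`sequence_id`, `aa_start`,
#'   `aa_end`) of core helix intervals, required when `use_core = TRUE`.
#' @return A `family_score_set` object: a named list (one element per
#'   family, sorted by family id) of numeric score vectors named by
#'   sequence id.
#' @export
family_scores <- function(records, scale, use_core = FALSE,
                          core_regions = NULL) {
  fc_assert(is.data.frame(records) &&
              all(c("sequence_id", "family_id", "residues") %in% names(records)),
            "records needs columns sequence_id, family_id, residues",
            class = "famcontext_format_error")
  fc_assert(nrow(records) > 0L, "no sequence records supplied")
  scores <- vapply(seq_len(nrow(records)), function(i) {
    cr <- NULL
    if (isTRUE(use_core)) {
      cr <- core_regions[core_regions$sequence_id == records$sequence_id[i],
                         c("aa_start", "aa_end"), drop = FALSE]
      fc_assert(nrow(cr) > 0L,
                sprintf("no core regions for sequence %s",
                        records$sequence_id[i]),
                class = "famcontext_scoring_error")
    }
    sequence_tm_score(records$residues[i], scale,
                      use_core = use_core, core_regions = cr)
  }, numeric(1))
  fam <- as.character(records$family_id)
  out <- lapply(fc_sort(unique(fam)), function(f) {
    idx <- which(fam == f)
    structure(scores[idx], names = records$sequence_id[idx])[
      fc_order(records$sequence_id[idx])]
  })
  names(out) <- fc_sort(unique(fam))
  empty <- names(out)[lengths(out) == 0L]
  fc_assert(length(empty) == 0L,
            sprintf("families with no scorable sequences: %s",
                    paste(empty, collapse = ", ")))
  structure(out, class = "family_score_set",
            full_length = !isTRUE(use_core))
}

#' Tidy per-sequence score table
#'
#' Flattens a [family_scores()] result into the per-sequence TSV layout
#' (`sequence_id`, `family_id`, `tm_score`) used for score-table exports.
#'
#' @param score_sets A `family_score_set`.
#' @return A data.frame with one row per scored sequence.
#' @export
score_table <- function(score_sets) {
  fc_assert(inherits(score_sets, "family_score_set"),
            "'score_sets' must come from family_scores()")
  do.call(rbind, lapply(names(score_sets), function(f) {
    data.frame(sequence_id = names(score_sets[[f]]),
               family_id = f,
               tm_score = as.numeric(score_sets[[f]]),
               stringsAsFactors = FALSE)
  }))
}

#' Classify families as transmembrane or soluble
#'
#' A family is labeled `TM` when the chosen summary statistic of its
#' per-sequence propensity scores exceeds `boundary`; otherwise (including
#' exact ties, which are logged) it is labeled `soluble`. With the shipped
#' transmembrane-tendency scale the default boundary of 0 sits at the
#' scale's soluble/TM divide.
#'
#' @param score_sets A `family_score_set` from [family_scores()].
#' @param boundary Finite score threshold (scale units).
#' @param statistic `"median"` (default, robust to within-family outliers)
#'   or `"mean"`.
#' @return Named character vector over families, values `"TM"` / `"soluble"`.
#' @export
classify_families <- function(score_sets, boundary = 0,
                              statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  fc_assert(is_number(boundary), "'boundary' must be finite",
            class = "famcontext_parameter_error")
  stat_fun <- if (statistic == "median") stats::median else mean
  stats <- vapply(score_sets, stat_fun, numeric(1))
  ties <- names(stats)[stats == boundary]
  if (length(ties) > 0L) {
    message(sprintf("families exactly at the boundary, labeled soluble: %s",
                    paste(ties, collapse = ", ")))
  }
  ifelse(stats > boundary, "TM", "soluble")
}

#' Kruskal-Wallis test across family score distributions
#'
#' Tests whether propensity scores differ across families, using the
#' rank-based Kruskal-Wallis statistic with tie correction and the
#' chi-squared approximation on k - 1 degrees of freedom.
#'
#' @param score_sets A `family_score_set` or named list of numeric vectors
#'   (>= 2 groups, total N >= 3).
#' @return List with `H_statistic`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(score_sets) {
  groups <- lapply(score_sets, as.numeric)
  fc_assert(length(groups) >= 2L, "need at least two groups",
            class = "famcontext_parameter_error")
  values <- unlist(groups, use.names = FALSE)
  fc_assert(length(values) >= 3L, "need a total of at least 3 observations",
            class = "famcontext_parameter_error")
  if (length(unique(values)) == 1L) {
    fc_abort("all values identical across all groups: tie correction is degenerate",
             class = "famcontext_degenerate_data_error")
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  list(H_statistic = unname(kt$statistic),
       p_value = unname(kt$p.value),
       df = unname(kt$parameter))
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise follow-up to [kruskal_wallis()]: for each family pair the z
#' statistic is the mean-rank difference divided by its tie-corrected
#' pooled standard error,
#' z = (rbar_a - rbar_b) / sqrt((N(N+1)/12 - T) (1/n_a + 1/n_b)),
#' with tie term T = sum(t^3 - t) / (12 (N - 1)). Two-sided normal p-values
#' are Bonferroni-adjusted over the k(k-1)/2 pairs. Families are then
#' grouped as in a critical-difference diagram: pairs that are NOT
#' significantly different (adjusted p >= alpha) are connected, and
#' `cd_groups` are the connected components of that graph.
#'
#' @param score_sets A `family_score_set` or named list of numeric vectors.
#' @param alpha Significance level for the critical-difference grouping.
#' @return A `group_comparison` list: `H_statistic`, `p_value` (omnibus),
#'   `pairwise` data.frame (`family_a`, `family_b`, `z`, `p_raw`,
#'   `p_adjusted`), `alpha`, and `cd_groups` (list of family character
#'   vectors partitioning the families).
#' @export
dunn_posthoc <- function(score_sets, alpha = 0.05) {
  groups <- lapply(score_sets, as.numeric)
  fc_assert(length(groups) >= 2L, "post-hoc comparison needs >= 2 groups",
            class = "famcontext_parameter_error")
  fc_assert(is_prob(alpha) && alpha > 0, "'alpha' must be in (0, 1]",
            class = "famcontext_parameter_error")
  omnibus <- kruskal_wallis(groups)
  fam <- names(groups)
  if (is.null(fam)) fam <- paste0("group", seq_along(groups))
  k <- length(groups)
  n <- lengths(groups)
  values <- unlist(groups, use.names = FALSE)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, rep(seq_len(k), n), mean)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
    z[m] <- (rbar[i] - rbar[j]) / se
    p_raw[m] <- 2 * stats::pnorm(-abs(z[m]))
  }
  p_adjusted <- pmin(1, p_raw * ncol(pairs))
  pairwise <- data.frame(family_a = fam[pairs[1, ]],
                         family_b = fam[pairs[2, ]],
                         z = z, p_raw = p_raw, p_adjusted = p_adjusted,
                         stringsAsFactors = FALSE)
  # critical-difference grouping: join pairs indistinguishable at alpha
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  igraph::V(g)$name <- fam
  keep <- which(p_adjusted >= alpha)
  if (length(keep) > 0L) {
    g <- igraph::add_edges(g, rbind(pairs[1, keep], pairs[2, keep]))
  }
  comp <- igraph::components(g)$membership
  cd_groups <- unname(lapply(split(fam, comp), fc_sort))
  structure(list(H_statistic = omnibus$H_statistic,
                 p_value = omnibus$p_value,
                 pairwise = pairwise,
                 alpha = alpha,
                 cd_groups = cd_groups),
            class = "group_comparison")
}
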