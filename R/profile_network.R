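# Family-relationship network from profile-profile comparison scores and
# Leiden sub-network detection.

#' Build a family similarity network from profile-profile comparisons
#'
#' Each comparison record (query family, target family, p-value, e-value)
#' becomes a candidate undirected edge. Reciprocal records for the same
#' unordered pair are combined (`max_weight`: keep the smaller p, i.e. the
#' stronger link; `mean_weight`: average the -log10 p of the records),
#' pairs whose combined p exceeds `p_threshold` are dropped, and the edge
#' weight is -log10(combined p). Families appearing only in dropped or
#' self comparisons are retained as isolated nodes.
#'
#' @param comparisons Data frame with columns `query_family`,
#'   `target_family`, `p_value` and optionally `e_value`.
#' @param p_threshold Maximum combined p for an edge, in (0, 1].
#' @param combine `"max_weight"` or `"mean_weight"`.
#' @param use_evalue Use the e-value column instead of p-values as the edge
#'   score (same combination and -log10 weighting).
#' @param floor_zero Replace non-positive scores with 1e-300 (with a
#'   warning) instead of rejecting them.
#' @return An igraph object with vertex attribute `name` and edge
#'   attributes `weight` (= -log10 p) and `p_value`.
#' @export
build_similarity_network <- function(comparisons, p_threshold = 0.05,
                                     combine = c("max_weight", "mean_weight"),
                                     use_evalue = FALSE, floor_zero = TRUE) {
  combine <- match.arg(combine)
  fc_assert(is.data.frame(comparisons) && nrow(comparisons) > 0L,
            "'comparisons' must be a non-empty data frame",
            class = "famcontext_parameter_error")
  score_col <- if (use_evalue) "e_value" else "p_value"
  fc_assert(all(c("query_family", "target_family", score_col) %in%
                  names(comparisons)),
            sprintf("comparisons needs columns query_family, target_family, %s",
                    score_col),
            class = "famcontext_format_error")
  fc_assert(is_number(p_threshold) && p_threshold > 0 && p_threshold <= 1,
            "'p_threshold' must be in (0, 1]",
            class = "famcontext_parameter_error")
  q <- as.character(comparisons$query_family)
  t <- as.character(comparisons$target_family)
  p <- as.numeric(comparisons[[score_col]])
  fc_assert(!anyNA(p), "comparison scores must not be NA")
  if (any(p <= 0)) {
    if (!floor_zero) {
      fc_abort("non-positive comparison score(s); enable floor_zero or fix input")
    }
    warning(sprintf("floored %d non-positive score(s) at 1e-300", sum(p <= 0)))
    p[p <= 0] <- 1e-300
  }
  nodes <- fc_sort(unique(c(q, t)))
  self <- q == t
  if (any(self)) {
    message(sprintf("dropping %d self-comparison(s)", sum(self)))
    q <- q[!self]; t <- t[!self]; p <- p[!self]
  }
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (length(q) > 0L) {
    a <- pmin(q, t); b <- pmax(q, t)
    key <- paste(a, b, sep = "\r")
    combined <- vapply(split(p, key), function(ps) {
      if (combine == "max_weight") min(ps) else 10^(-mean(-log10(ps)))
    }, numeric(1))
    keep <- combined <= p_threshold
    combined <- combined[keep]
    if (length(combined) > 0L) {
      ends <- do.call(rbind, strsplit(names(combined), "\r", fixed = TRUE))
      ord <- fc_order(ends[, 1], ends[, 2])
      ends <- ends[ord, , drop = FALSE]
      combined <- combined[ord]
      g <- igraph::add_edges(g, rbind(match(ends[, 1], nodes),
                                      match(ends[, 2], nodes)),
                             weight = unname(-log10(combined)),
                             p_value = unname(combined))
    }
  }
  g
}

#' Detect sub-networks with the Leiden algorithm
#'
#' Runs Leiden community detection (refinement-and-aggregation
#' optimization of modularity or the constant Potts model on edge weights)
#' `n_restarts` times with seeds derived from `seed`, and keeps the
#' partition with the best quality score. Deterministic given
#' `(seed, n_restarts)`.
#'
#' @param net Weighted igraph from [build_similarity_network()].
#' @param quality `"modularity"` or `"CPM"`.
#' @param resolution Resolution parameter, > 0.
#' @param seed Integer seed.
#' @param n_restarts Number of independent restarts (best kept).
#' @return A `community_partition` list: `membership` (named integer
#'   vector, labels renumbered in order of first appearance over sorted
#'   node names), `quality_function`, `resolution`, `seed`,
#'   `quality_score`, `n_communities`.
#' @export
detect_communities <- function(net, quality = c("modularity", "CPM"),
                               resolution = 1, seed = 1L, n_restarts = 20L) {
  quality <- match.arg(quality)
  fc_assert(igraph::is_igraph(net) && igraph::vcount(net) > 0L,
            "'net' must be a non-empty igraph object",
            class = "famcontext_parameter_error")
  fc_assert(is_number(resolution) && resolution > 0,
            "'resolution' must be > 0", class = "famcontext_parameter_error")
  fc_assert(is_count(n_restarts, min = 1L), "'n_restarts' must be >= 1",
            class = "famcontext_parameter_error")
  weights <- if ("weight" %in% igraph::edge_attr_names(net)) {
    igraph::E(net)$weight
  } else {
    NULL
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cl <- with_fc_seed(as.integer(seed) + r - 1L,
      igraph::cluster_leiden(net, objective_function = quality,
                             weights = weights, resolution = resolution,
                             n_iterations = 10L))
    if (!is.finite(cl$quality)) cl$quality <- -Inf  # e.g. edgeless graph
    if (is.null(best) || cl$quality > best$quality) best <- cl
  }
  mem <- igraph::membership(best)
  names(mem) <- igraph::V(net)$name
  # canonical label numbering so equal partitions compare equal
  ord <- fc_order(names(mem))
  mem <- as.integer(factor(mem, levels = unique(mem[ord])))
  names(mem) <- igraph::V(net)$name
  structure(list(membership = mem,
                 quality_function = quality,
                 resolution = resolution,
                 seed = as.integer(seed),
                 quality_score = best$quality,
                 n_communities = length(unique(mem))),
            class = "community_partition")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between a detected partition and a reference
#' labeling over the same node set: 1 for identical partitions (up to
#' relabeling), about 0 for independent ones.
#'
#' @param a A `community_partition` or named label vector.
#' @param b Named label vector over the same nodes.
#' @return ARI in [-1, 1].
#' @export
partition_agreement <- function(a, b) {
  if (inherits(a, "community_partition")) a <- a$membership
  fc_assert(!is.null(names(a)) && !is.null(names(b)),
            "both labelings must be named by node")
  fc_assert(setequal(names(a), names(b)),
            "labelings cover different node sets",
            class = "famcontext_parameter_error")
  b <- b[names(a)]
  tab <- table(as.character(a), as.character(b))
  n <- sum(tab)
  sum_comb <- sum(choose(tab, 2))
  comb_a <- sum(choose(rowSums(tab), 2))
  comb_b <- sum(choose(colSums(tab), 2))
  expected <- comb_a * comb_b / choose(n, 2)
  max_index <- (comb_a + comb_b) / 2
  if (max_index == expected) return(1)  # both trivial partitions
  (sum_comb - expected) / (max_index - expected)
}

#' Community assignment table
#'
#' @param partition A `community_partition`.
#' @return Data frame (`family_id`, `community`) sorted by family.
#' @export
community_table <- function(partition) {
  fc_assert(inherits(partition, "community_partition"),
            "'partition' must come from detect_communities()")
  mem <- partition$membership
  df <- data.frame(family_id = names(mem), community = as.integer(mem),
                   stringsAsFactors = FALSE)
  df <- df[fc_order(df$family_id), ]
  rownames(df) <- NULL
  df
}
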