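#' Phyletic profile of a clade
#'
#' A phyletic profile records, for one clade and each of M examined
#' lineages, the number of sampled species n_j that carry at least one clade
#' member out of N_j species sampled in that lineage. Paralog multiplicity
#' within a species does not inflate n_j: the counts are over species.
#'
#' @param clade_id Clade identifier.
#' @param lineage_id Character vector of M lineage identifiers.
#' @param n_present Integer vector, species with >= 1 representative (n_j).
#' @param n_sampled Integer vector, species sampled per lineage (N_j >= 1).
#' @return A `phyletic_profile` object (a validated data.frame plus
#'   attributes `clade_id` and `M`).
#' @export
phyletic_profile <- function(clade_id, lineage_id, n_present, n_sampled) {
  fc_assert(length(lineage_id) >= 1L, "need at least one lineage (M >= 1)",
            class = "famcontext_parameter_error")
  fc_assert(length(n_present) == length(lineage_id) &&
              length(n_sampled) == length(lineage_id),
            "lineage_id, n_present, n_sampled must have equal length")
  fc_assert(!anyDuplicated(lineage_id), "duplicate lineage_id")
  fc_assert(all(n_sampled >= 1), "every N_j must be >= 1")
  fc_assert(all(n_present >= 0) && all(n_present <= n_sampled),
            "n_j must satisfy 0 <= n_j <= N_j")
  structure(
    data.frame(lineage_id = as.character(lineage_id),
               n_present = as.integer(n_present),
               n_sampled = as.integer(n_sampled),
               stringsAsFactors = FALSE),
    class = c("phyletic_profile", "data.frame"),
    clade_id = as.character(clade_id),
    M = length(lineage_id))
}

#' Phyletic spread
#'
#' S = m / M, where m is the number of lineages with at least one clade
#' representative and M the total number of lineages examined. S measures
#' how widely a clade is distributed across major lineages.
#'
#' @param profile A [phyletic_profile()].
#' @return Spread in [0, 1].
#' @export
phyletic_spread <- function(profile) {
  fc_assert(inherits(profile, "phyletic_profile"),
            "'profile' must be a phyletic_profile")
  sum(profile$n_present > 0L) / attr(profile, "M")
}

#' Phyletic depth
#'
#' D = sum(n_j) / sum(N_j), the mediant of the per-lineage occupancy
#' fractions n_j / N_j, summed over all M examined lineages including those
#' where the clade is absent. As a mediant, D always lies between the
#' smallest and largest per-lineage fraction, weighting each lineage by its
#' sampling depth.
#'
#' @param profile A [phyletic_profile()].
#' @return Depth in [0, 1].
#' @export
phyletic_depth <- function(profile) {
  fc_assert(inherits(profile, "phyletic_profile"),
            "'profile' must be a phyletic_profile")
  total <- sum(profile$n_sampled)
  fc_assert(total >= 1L, "sum of N_j must be >= 1",
            class = "famcontext_parameter_error")
  sum(profile$n_present) / total
}

#' Spread/depth metric table with bar-graph encoding
#'
#' Computes S and D for each clade and attaches the bar encoding used to
#' plot phyletic patterns: bar width = spread, bar height = depth.
#'
#' @param profiles List of [phyletic_profile()] objects.
#' @return Data frame with columns `clade_id`, `S`, `D`, `bar_width`,
#'   `bar_height`, one row per clade (input order preserved).
#' @export
phyletic_table <- function(profiles) {
  if (length(profiles) == 0L) {
    return(data.frame(clade_id = character(), S = numeric(), D = numeric(),
                      bar_width = numeric(), bar_height = numeric(),
                      stringsAsFactors = FALSE))
  }
  ids <- vapply(profiles, function(p) attr(p, "clade_id"), character(1))
  fc_assert(!anyDuplicated(ids),
            sprintf("duplicate clade_id: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  S <- vapply(profiles, phyletic_spread, numeric(1))
  D <- vapply(profiles, phyletic_depth, numeric(1))
  data.frame(clade_id = ids, S = S, D = D,
             bar_width = S, bar_height = D,
             stringsAsFactors = FALSE)
}

#' Read phyletic profiles from a presence TSV
#'
#' Expects columns `clade_id`, `lineage_id`, `n_present`, `n_sampled`; one
#' row per (clade, lineage).
#'
#' @param path TSV file path.
#' @return Named list of [phyletic_profile()] objects, sorted by clade id.
#' @export
read_phyletic_profiles <- function(path) {
  df <- read_fc_tsv(path, required = c("clade_id", "lineage_id",
                                       "n_present", "n_sampled"))
  out <- lapply(fc_sort(unique(df$clade_id)), function(cid) {
    sub <- df[df$clade_id == cid, , drop = FALSE]
    phyletic_profile(cid, sub$lineage_id, sub$n_present, sub$n_sampled)
  })
  names(out) <- fc_sort(unique(df$clade_id))
  out
}

#' Write phyletic profiles to a presence TSV
#'
#' @param profiles Named list of [phyletic_profile()] objects.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_phyletic_profiles <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(clade_id = attr(p, "clade_id"),
               lineage_id = p$lineage_id,
               n_present = p$n_present,
               n_sampled = p$n_sampled,
               stringsAsFactors = FALSE)
  }))
  write_fc_tsv(df, path)
}
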