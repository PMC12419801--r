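# Seeded generators for every input the pipeline consumes, each planting a
# known ground truth so downstream stages can be validated at desk scale.

#' Generate family-tagged sequences with controlled mean TM propensity
#'
#' Sequences are built from a two-residue mixture of the most hydrophobic
#' and most hydrophilic residues of the active scale; the mixture weight is
#' solved in closed form so the expected per-residue propensity equals the
#' family's target mean. Per-sequence targets are drawn Normal(target,
#' tm_sd), truncated to the scale range, so per-sequence scores scatter
#' around the family mean; with `tm_sd = 0` and a target equal to a single
#' residue's value the output degenerates to homopolymers.
#'
#' @param families Data frame with columns `family_id`, `n_sequences`,
#'   `length`, `target_mean_tm`, `tm_sd`.
#' @param scale A [tm_scale()]; targets must lie within its value range.
#' @param seed Integer seed; fully determines the output.
#' @return Data frame of sequence records (`sequence_id`, `family_id`,
#'   `residues`).
#' @export
gen_family_sequences <- function(families, scale = tm_tendency_scale(),
                                 seed = 1L) {
  fc_assert(is.data.frame(families) &&
              all(c("family_id", "n_sequences", "length",
                    "target_mean_tm", "tm_sd") %in% names(families)),
            "families needs columns family_id, n_sequences, length, target_mean_tm, tm_sd",
            class = "famcontext_parameter_error")
  v <- unclass(scale)
  h_min <- min(v); h_max <- max(v)
  res_min <- names(v)[which.min(v)]; res_max <- names(v)[which.max(v)]
  bad <- families$target_mean_tm < h_min | families$target_mean_tm > h_max
  if (any(bad)) {
    fc_abort(sprintf("target_mean_tm outside scale range [%.2f, %.2f] for: %s",
                     h_min, h_max,
                     paste(families$family_id[bad], collapse = ", ")),
             class = "famcontext_parameter_error")
  }
  fc_assert(all(families$tm_sd >= 0) && all(families$length >= 1) &&
              all(families$n_sequences >= 1),
            "n_sequences, length must be >= 1 and tm_sd >= 0",
            class = "famcontext_parameter_error")
  with_fc_seed(seed, {
    rows <- lapply(seq_len(nrow(families)), function(i) {
      f <- families[i, ]
      targets <- pmin(h_max, pmax(h_min,
        stats::rnorm(f$n_sequences, f$target_mean_tm, f$tm_sd)))
      residues <- vapply(targets, function(t) {
        w <- (t - h_min) / (h_max - h_min)
        paste(sample(c(res_max, res_min), f$length, replace = TRUE,
                     prob = c(w, 1 - w)), collapse = "")
      }, character(1))
      data.frame(
        sequence_id = sprintf("%s_seq%04d", f$family_id,
                              seq_len(f$n_sequences)),
        family_id = f$family_id,
        residues = residues,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate phyletic profiles with planted spread and depth
#'
#' Deterministically constructs lineage presence counts whose recomputed
#' spread S = m/M and depth D = sum(n_j)/sum(N_j) match the planted values
#' to the nearest achievable rational: m = round(planted_S * M) lineages
#' are marked present and round(planted_D * sum(N_j)) present species are
#' distributed over them (each present lineage gets at least one).
#'
#' @param planted Data frame with columns `clade_id`, `planted_S`,
#'   `planted_D`, `M` (lineages examined) and `N_per_lineage` (species
#'   sampled per lineage; one integer applied to every lineage).
#' @return Named list of [phyletic_profile()] objects.
#' @export
gen_phyletic_profiles <- function(planted) {
  fc_assert(is.data.frame(planted) &&
              all(c("clade_id", "planted_S", "planted_D", "M",
                    "N_per_lineage") %in% names(planted)),
            "planted needs clade_id, planted_S, planted_D, M, N_per_lineage",
            class = "famcontext_parameter_error")
  fc_assert(all(planted$planted_S >= 0 & planted$planted_S <= 1) &&
              all(planted$planted_D >= 0 & planted$planted_D <= 1),
            "planted_S and planted_D must lie in [0, 1]",
            class = "famcontext_parameter_error")
  out <- lapply(seq_len(nrow(planted)), function(i) {
    p <- planted[i, ]
    M <- as.integer(p$M)
    N <- rep(as.integer(p$N_per_lineage), M)
    m <- as.integer(round(p$planted_S * M))
    total <- as.integer(round(p$planted_D * sum(N)))
    lo <- m
    hi <- if (m > 0L) sum(N[seq_len(m)]) else 0L
    if (total < lo || total > hi) {
      fc_abort(sprintf(
        "clade %s: planted_D %.3f infeasible with planted_S %.3f; feasible D range is [%.4f, %.4f]",
        p$clade_id, p$planted_D, p$planted_S, lo / sum(N), hi / sum(N)),
        class = "famcontext_parameter_error")
    }
    n <- integer(M)
    if (m > 0L) {
      n[seq_len(m)] <- 1L
      remaining <- total - m
      j <- 1L
      while (remaining > 0L) {  # round-robin fill over present lineages
        if (n[j] < N[j]) {
          n[j] <- n[j] + 1L
          remaining <- remaining - 1L
        }
        j <- if (j == m) 1L else j + 1L
      }
    }
    phyletic_profile(p$clade_id, sprintf("lineage_%02d", seq_len(M)), n, N)
  })
  names(out) <- planted$clade_id
  out
}

#' Generate a profile-comparison table with planted communities
#'
#' All-vs-all comparison records over the pooled family set: pairs within
#' one community get p = 10^(-u) with u uniform in `within_p_log10_range`;
#' pairs across communities get p uniform in `between_p_range`. Both
#' directed records of each pair are drawn independently, mimicking the
#' asymmetry of real profile-profile alignment scores.
#'
#' @param communities List of disjoint character vectors of family ids.
#' @param within_p_log10_range Range of -log10 p within communities.
#' @param between_p_range Range of p between communities.
#' @param seed Integer seed.
#' @return Data frame (`query_family`, `target_family`, `p_value`,
#'   `e_value`) with planted community labels as attribute `truth`.
#' @export
gen_profile_comparisons <- function(communities,
                                    within_p_log10_range = c(5, 20),
                                    between_p_range = c(0.05, 1),
                                    seed = 1L) {
  members <- unlist(communities)
  fc_assert(!anyDuplicated(members), "communities must be disjoint",
            class = "famcontext_parameter_error")
  fc_assert(length(members) >= 2L, "need at least two families overall",
            class = "famcontext_parameter_error")
  labels <- rep(seq_along(communities), lengths(communities))
  names(labels) <- members
  pairs <- utils::combn(members, 2)
  with_fc_seed(seed, {
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      same <- labels[a] == labels[b]
      p2 <- if (same) {
        10^(-stats::runif(2, within_p_log10_range[1], within_p_log10_range[2]))
      } else {
        stats::runif(2, between_p_range[1], between_p_range[2])
      }
      data.frame(query_family = c(a, b), target_family = c(b, a),
                 p_value = p2, e_value = p2 * length(members),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, truth = labels)
  })
}

#' Default domain pool for context simulations
#'
#' Four functional categories of 25 background domains each, in the
#' spirit of the categories that annotate real contextual networks (lipid
#' metabolism, peptidoglycan metabolism, nucleotide signaling, biological
#' conflict systems). The vocabulary is kept large relative to the number
#' of adjacency draws so the simulated domain-adjacency graph stays
#' sparse, as real contextual networks are; a much smaller pool saturates
#' into a complete graph and carries no contextual signal.
#'
#' @return Data frame with columns `domain_name`, `category`.
#' @export
default_domain_pool <- function() {
  cats <- c("lipid_metabolism", "peptidoglycan_metabolism",
            "nucleotide_signaling", "conflict_systems")
  do.call(rbind, lapply(cats, function(cat) {
    data.frame(domain_name = sprintf("%s_dom%02d",
                                     toupper(substr(cat, 1, 4)), 1:25),
               category = cat, stringsAsFactors = FALSE)
  }))
}

#' Generate annotated genomes with a planted neighborhood enrichment
#'
#' Each synthetic genome carries one neighborhood containing the focal
#' domain plus `n_background_neighborhoods` without it, laid out in tandem
#' on one strand with 50 bp intergenic gaps and large (10 kb) gaps between
#' neighborhoods. Every non-focal slot draws a domain of
#' `enriched_category` with probability `enrichment_rate` inside the focal
#' neighborhood and `background_rate` elsewhere; otherwise the domain is
#' drawn uniformly from the non-enriched background pool. Setting the two
#' rates equal yields a null dataset with no planted signal.
#'
#' @param n_genomes Number of genomes.
#' @param focal_domain Name of the focal domain.
#' @param enriched_category Category planted around the focal domain; must
#'   exist in `domain_pool`.
#' @param enrichment_rate,background_rate Per-slot probabilities in [0, 1].
#' @param neighborhood_size_range Integer range of genes per neighborhood
#'   (lower bound >= 2).
#' @param domain_pool Data frame (`domain_name`, `category`) of background
#'   domains spanning >= 2 categories.
#' @param n_background_neighborhoods Non-focal neighborhoods per genome.
#' @param seed Integer seed.
#' @return List with `genes`, `hits`, `labels` (focal domain labeled with
#'   its own `focal` category) and `truth` (per-slot draw record).
#' @export
gen_context_dataset <- function(n_genomes = 200L,
                                focal_domain = "ConeTM",
                                enriched_category = "lipid_metabolism",
                                enrichment_rate = 0.8,
                                background_rate = 0.2,
                                neighborhood_size_range = c(3L, 7L),
                                domain_pool = default_domain_pool(),
                                n_background_neighborhoods = 5L,
                                seed = 1L) {
  fc_assert(is_count(n_genomes, min = 1L), "'n_genomes' must be >= 1",
            class = "famcontext_parameter_error")
  fc_assert(is_prob(enrichment_rate) && is_prob(background_rate),
            "rates must lie in [0, 1]", class = "famcontext_parameter_error")
  fc_assert(neighborhood_size_range[1] >= 2L,
            "neighborhood_size_range lower bound must be >= 2",
            class = "famcontext_parameter_error")
  fc_assert(length(unique(domain_pool$category)) >= 2L,
            "domain_pool must span at least two categories",
            class = "famcontext_parameter_error")
  fc_assert(enriched_category %in% domain_pool$category,
            sprintf("enriched_category '%s' not in domain_pool",
                    enriched_category),
            class = "famcontext_parameter_error")
  fc_assert(!(focal_domain %in% domain_pool$domain_name),
            "focal_domain must not collide with a background pool domain",
            class = "famcontext_parameter_error")
  enriched_doms <- domain_pool$domain_name[
    domain_pool$category == enriched_category]
  other_doms <- domain_pool$domain_name[
    domain_pool$category != enriched_category]
  cat_of <- structure(domain_pool$category, names = domain_pool$domain_name)
  gene_length <- 900L
  intergenic <- 50L
  between_nb <- 10000L

  with_fc_seed(seed, {
    n_nb <- n_background_neighborhoods + 1L
    # one row per neighborhood, then expand to slots in vectorized form
    nb_genome <- rep(seq_len(n_genomes), each = n_nb)
    nb_index <- rep(seq_len(n_nb), times = n_genomes)
    focal_nb <- sample.int(n_nb, n_genomes, replace = TRUE)
    nb_size <- sample(seq.int(neighborhood_size_range[1],
                              neighborhood_size_range[2]),
                      length(nb_genome), replace = TRUE)
    is_focal_nb <- nb_index == focal_nb[nb_genome]

    slot <- sequence(nb_size)
    row_nb <- rep(seq_along(nb_size), nb_size)
    genome <- nb_genome[row_nb]
    genome_id <- sprintf("genome_%04d", genome)
    focal_slot <- ifelse(is_focal_nb, nb_size %/% 2L + 1L, 0L)
    is_focal_gene <- slot == focal_slot[row_nb]
    rate <- ifelse(is_focal_nb[row_nb], enrichment_rate, background_rate)
    enriched_draw <- stats::runif(length(slot)) < rate
    dom <- ifelse(enriched_draw,
                  sample(enriched_doms, length(slot), replace = TRUE),
                  sample(other_doms, length(slot), replace = TRUE))
    dom[is_focal_gene] <- focal_domain
    enriched_draw[is_focal_gene] <- NA

    gene_no <- stats::ave(genome, genome, FUN = seq_along)
    gene_id <- sprintf("%s_g%03d", genome_id, gene_no)
    # tandem layout: fixed gene length, small intra- and large
    # inter-neighborhood gaps
    step <- rep(gene_length + intergenic, length(slot))
    nb_change <- c(FALSE, diff(row_nb) != 0L)
    genome_change <- c(FALSE, diff(genome) != 0L)
    last_of_nb <- which(nb_change & !genome_change) - 1L  # gap goes after it
    step[last_of_nb] <- step[last_of_nb] + between_nb
    offset <- stats::ave(step, genome,
                         FUN = function(x) cumsum(c(0L, x[-length(x)])))
    start <- as.integer(1L + offset)

    genes <- data.frame(
      genome_id = genome_id, contig_id = "contig_1", gene_id = gene_id,
      start = start, end = start + gene_length - 1L, strand = "+",
      product_id = paste0(gene_id, "_p"), stringsAsFactors = FALSE)
    hits <- data.frame(
      product_id = genes$product_id, domain_name = dom,
      aa_start = 5L, aa_end = 250L, score = 50, source = "synthetic",
      stringsAsFactors = FALSE)
    truth <- data.frame(
      genome_id = genome_id, neighborhood = nb_index[row_nb],
      focal_neighborhood = is_focal_nb[row_nb], gene_id = gene_id,
      slot = slot, domain_name = dom,
      category = ifelse(dom == focal_domain, "focal",
                        unname(cat_of[dom])),
      enriched_draw = enriched_draw, stringsAsFactors = FALSE)
    labels <- functional_label_map(
      categories = c(unique(domain_pool$category), "focal"),
      domains = c(structure(as.list(domain_pool$category),
                            names = domain_pool$domain_name),
                  structure(list("focal"), names = focal_domain)))
    list(genes = genes, hits = hits, labels = labels, truth = truth)
  })
}

#' Default whole-study simulation specification
#'
#' Bundles the default conditions of all four generators: 30 sequence
#' families (18 with high membrane propensity, 12 soluble), 30 phyletic
#' clades on a grid of planted spread/depth values, 4 planted communities
#' of 10 families, and a 200-genome context dataset with a 0.8 vs 0.2
#' planted enrichment.
#'
#' @param seed Integer master seed; generator seeds are derived from it.
#' @return A `simulation_spec` list understood by [simulate_dataset()].
#' @export
simulation_spec <- function(seed = 1L) {
  fc_assert(is_count(seed), "'seed' must be a non-negative integer",
            class = "famcontext_parameter_error")
  fam_ids <- sprintf("F%02d", 1:30)
  families <- data.frame(
    family_id = fam_ids,
    n_sequences = 30L,
    length = 120L,
    target_mean_tm = c(rep(1.2, 18), rep(-1.0, 12)),
    tm_sd = 0.2,
    stringsAsFactors = FALSE)
  families$planted_class <- c(rep("TM", 18), rep("soluble", 12))
  S_grid <- rep(seq(0.1, 1, by = 0.1), 3)
  planted_phyletics <- data.frame(
    clade_id = sprintf("clade_%02d", 1:30),
    planted_S = S_grid,
    planted_D = round(0.6 * S_grid, 2),
    M = 10L,
    N_per_lineage = 10L,
    stringsAsFactors = FALSE)
  communities <- split(sprintf("N%02d", 1:40), rep(1:4, each = 10))
  structure(list(
    seed = as.integer(seed),
    families = families,
    phyletics = planted_phyletics,
    communities = communities,
    within_p_log10_range = c(5, 20),
    between_p_range = c(0.05, 1),
    context = list(n_genomes = 200L, focal_domain = "ConeTM",
                   enriched_category = "lipid_metabolism",
                   enrichment_rate = 0.8, background_rate = 0.2,
                   neighborhood_size_range = c(3L, 7L))),
    class = "simulation_spec")
}

#' Emit the complete synthetic fixture directory
#'
#' Runs all four generators under seeds derived from the spec's master
#' seed and writes every pipeline input format plus the planted ground
#' truth: FASTA + family TSV, phyletic presence TSV, comparison TSV, gene
#' TSV, domain TSV, label YAML and a ground-truth JSON.
#'
#' @param spec A [simulation_spec()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named list of generated objects.
#' @export
simulate_dataset <- function(spec, out_dir) {
  fc_assert(inherits(spec, "simulation_spec"),
            "'spec' must come from simulation_spec()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  records <- gen_family_sequences(spec$families, seed = spec$seed + 1L)
  write_family_fasta(records, p("sequences.fasta"), p("families.tsv"))

  profiles <- gen_phyletic_profiles(spec$phyletics)
  write_phyletic_profiles(profiles, p("phyletics.tsv"))

  comparisons <- gen_profile_comparisons(
    spec$communities, spec$within_p_log10_range, spec$between_p_range,
    seed = spec$seed + 2L)
  write_fc_tsv(comparisons, p("comparisons.tsv"))

  ctx <- do.call(gen_context_dataset,
                 c(spec$context, list(seed = spec$seed + 3L)))
  write_gene_table(ctx$genes, p("genes.tsv"), dialect = "tsv")
  write_domain_hits(ctx$hits, p("domains.tsv"), dialect = "tsv")
  write_label_yaml(ctx$labels, p("labels.yaml"))
  write_fc_tsv(ctx$truth, p("context_truth.tsv"))

  truth <- list(
    seed = spec$seed,
    planted_tm_class = structure(as.list(spec$families$planted_class),
                                 names = spec$families$family_id),
    planted_phyletics = spec$phyletics,
    planted_communities = structure(
      as.list(rep(seq_along(spec$communities),
                  lengths(spec$communities))),
      names = unlist(spec$communities)),
    context = spec$context[c("focal_domain", "enriched_category",
                             "enrichment_rate", "background_rate")])
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(records = records, profiles = profiles,
                 comparisons = comparisons, context = ctx))
}
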