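# Contextual (gene-neighborhood / domain-architecture) network analysis:
# decomposition into domain adjacency, clique merging around a focal
# domain, and functional-category enrichment.

#' Decompose genomes into architecture and neighborhood context instances
#'
#' Two kinds of context are extracted:
#' * architectures: for each protein product, its domains ordered by
#'   alignment start — the domain architecture string;
#' * neighborhoods: maximal runs of consecutive genes on one contig whose
#'   intergenic gap is at most `max_gap_bp` and (under `same_strand`) that
#'   share a strand — the candidate operons. Runs on the minus strand are
#'   reversed so domain order follows transcription. When `focal_domain`
#'   is given, runs are windowed to at most `max_genes` genes on each side
#'   of every gene carrying the focal domain.
#'
#' Each instance carries a `signature` (the ordered, strand-normalized
#' domain string). With `min_conserved_genomes` > 1, neighborhood
#' instances whose signature is seen in fewer distinct genomes are dropped
#' — a conservation filter for real genome collections.
#'
#' @param genes Gene table (see [read_gene_table()]).
#' @param hits Domain hit table (see [read_domain_hits()]); every
#'   `product_id` must appear in `genes`.
#' @param max_gap_bp Maximum intergenic gap within a neighborhood (bp).
#' @param max_genes Maximum genes on each side of a focal gene.
#' @param strand_rule `"same_strand"` or `"any_strand"`.
#' @param focal_domain Optional focal domain name for windowing.
#' @param min_conserved_genomes Keep neighborhood signatures seen in at
#'   least this many distinct genomes (1 = keep all).
#' @param kinds Which context kinds to emit.
#' @return A `context_instances` list; each element has `kind`,
#'   `genome_id`, `occurrences` (data.frame domain_name, gene_id,
#'   position) and `signature`.
#' @export
decompose_contexts <- function(genes, hits, max_gap_bp = 200L,
                               max_genes = 7L,
                               strand_rule = c("same_strand", "any_strand"),
                               focal_domain = NULL,
                               min_conserved_genomes = 1L,
                               kinds = c("architecture", "neighborhood")) {
  strand_rule <- match.arg(strand_rule)
  kinds <- match.arg(kinds, several.ok = TRUE)
  fc_assert(is_count(max_gap_bp), "'max_gap_bp' must be >= 0",
            class = "famcontext_parameter_error")
  fc_assert(is_count(max_genes, min = 2L), "'max_genes' must be >= 2",
            class = "famcontext_parameter_error")
  validate_gene_table(genes)
  unknown <- setdiff(hits$product_id, genes$product_id)
  fc_assert(length(unknown) == 0L,
            sprintf("domain hit(s) reference unknown product(s): %s",
                    paste(utils::head(unknown, 5), collapse = ", ")))
  gene_genome <- genes$genome_id[match(hits$product_id, genes$product_id)]
  instances <- list()

  ord <- fc_order(hits$product_id, hits$aa_start)
  domains_of <- split(hits$domain_name[ord], hits$product_id[ord])
  prod_idx <- match(names(domains_of), genes$product_id)
  gene_of <- genes$gene_id[prod_idx]
  genome_of <- genes$genome_id[prod_idx]

  if ("architecture" %in% kinds && nrow(hits) > 0L) {
    instances <- lapply(seq_along(domains_of), function(k) {
      doms <- domains_of[[k]]
      list(kind = "architecture",
           genome_id = genome_of[k],
           occurrences = fast_df(domain_name = doms,
                                 gene_id = rep(gene_of[k], length(doms)),
                                 position = seq_along(doms)),
           signature = paste(doms, collapse = ">"))
    })
  }

  if ("neighborhood" %in% kinds) {
    g <- genes[fc_order(genes$genome_id, genes$contig_id, genes$start), ,
               drop = FALSE]
    if (!is.null(focal_domain)) {
      focal_products <- names(domains_of)[
        vapply(domains_of, function(d) focal_domain %in% d, logical(1))]
      g$has_focal <- g$product_id %in% focal_products
    } else {
      g$has_focal <- FALSE
    }
    contig_rows <- split(seq_len(nrow(g)),
                         paste(g$genome_id, g$contig_id, sep = "\r"))
    nb_instances <- list()
    for (key in names(contig_rows)) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      sub <- g[contig_rows[[key]], , drop = FALSE]
      breaks <- logical(nrow(sub))
      if (nrow(sub) > 1L) {
        gap <- sub$start[-1L] - sub$end[-nrow(sub)] - 1L
        breaks[-1L] <- gap > max_gap_bp
        if (strand_rule == "same_strand") {
          breaks[-1L] <- breaks[-1L] |
            (sub$strand[-1L] != sub$strand[-nrow(sub)])
        }
      }
      run_id <- cumsum(breaks)
      for (run in split(seq_len(nrow(sub)), run_id)) {
        windows <- neighborhood_windows(sub[run, , drop = FALSE],
                                        domains_of, focal_domain, max_genes)
        for (w in windows) {
          occ <- neighborhood_occurrences(w, domains_of)
          if (nrow(occ) == 0L) next
          nb_instances[[length(nb_instances) + 1L]] <- list(
            kind = "neighborhood",
            genome_id = parts[1],
            occurrences = occ,
            signature = paste(occ$domain_name, collapse = ">"))
        }
      }
    }
    instances <- c(instances, nb_instances)
    if (min_conserved_genomes > 1L) {
      is_nb <- vapply(instances, function(x) x$kind == "neighborhood",
                      logical(1))
      sig <- vapply(instances, `[[`, character(1), "signature")
      gen <- vapply(instances, `[[`, character(1), "genome_id")
      support <- tapply(gen[is_nb], sig[is_nb],
                        function(x) length(unique(x)))
      drop <- is_nb & support[sig] < min_conserved_genomes
      instances <- instances[!drop]
    }
  }
  structure(instances, class = "context_instances")
}

# window a gene run: full run, or max_genes-per-side around each focal gene
neighborhood_windows <- function(run_genes, domains_of, focal_domain,
                                 max_genes) {
  if (is.null(focal_domain)) return(list(run_genes))
  has_focal <- run_genes$has_focal
  if (!any(has_focal)) return(list(run_genes))
  lapply(which(has_focal), function(i) {
    idx <- max(1L, i - max_genes):min(nrow(run_genes), i + max_genes)
    run_genes[idx, , drop = FALSE]
  })
}

# minimal-overhead data.frame constructor for hot loops
fast_df <- function(...) {
  cols <- list(...)
  structure(cols, class = "data.frame",
            row.names = .set_row_names(length(cols[[1]])))
}

# ordered domain occurrences of a gene window, strand-normalized
neighborhood_occurrences <- function(w, domains_of) {
  if (all(w$strand == "-")) {  # read minus-strand operons 3'->5' of contig
    w <- w[rev(seq_len(nrow(w))), , drop = FALSE]
  }
  doms_list <- domains_of[w$product_id]
  flip <- w$strand == "-" & lengths(doms_list) > 1L
  doms_list[flip] <- lapply(doms_list[flip], rev)
  doms <- unlist(doms_list, use.names = FALSE)
  if (is.null(doms)) {
    return(fast_df(domain_name = character(), gene_id = character(),
                   position = integer()))
  }
  fast_df(domain_name = doms,
          gene_id = rep(w$gene_id, lengths(doms_list)),
          position = seq_along(doms))
}

#' Build the domain adjacency graph
#'
#' Every pair of consecutive domain occurrences within a context instance
#' contributes an undirected edge between the two domain names. Edge
#' `support` counts the number of distinct genomes contributing the
#' adjacency; edges below `min_support` are dropped. Self-adjacencies
#' (domain repeats) are dropped with a message.
#'
#' @param instances A `context_instances` list.
#' @param min_support Minimum genome support per retained edge.
#' @return An igraph object with edge attributes `support` and `kinds`
#'   (comma-joined context kinds backing the edge).
#' @export
build_context_graph <- function(instances, min_support = 1L) {
  fc_assert(length(instances) > 0L, "no context instances",
            class = "famcontext_parameter_error")
  fc_assert(is_count(min_support, min = 1L), "'min_support' must be >= 1",
            class = "famcontext_parameter_error")
  dom_seqs <- lapply(instances, function(inst) inst$occurrences$domain_name)
  lens <- lengths(dom_seqs)
  all_domains <- unlist(dom_seqs, use.names = FALSE)
  inst_id <- rep.int(seq_along(instances), lens)
  # consecutive pairs within one instance, vectorized over everything
  n <- length(all_domains)
  if (n > 1L) {
    a <- all_domains[-n]; b <- all_domains[-1L]
    within <- inst_id[-n] == inst_id[-1L]
    self <- within & a == b
    keep <- within & !self
    n_self <- sum(self)
    from <- pmin(a[keep], b[keep])
    to <- pmax(a[keep], b[keep])
    src <- inst_id[-n][keep]
    genome <- vapply(instances, `[[`, character(1), "genome_id")[src]
    kind <- vapply(instances, `[[`, character(1), "kind")[src]
  } else {
    from <- to <- genome <- kind <- character()
    n_self <- 0L
  }
  if (n_self > 0L) {
    message(sprintf("dropped %d self-adjacency(ies) from domain repeats",
                    n_self))
  }
  nodes <- fc_sort(unique(all_domains))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (length(from) > 0L) {
    key <- paste(from, to, sep = "\r")
    support <- tapply(genome, key, function(x) length(unique(x)))
    kinds <- tapply(kind, key, function(x) paste(fc_sort(unique(x)),
                                                 collapse = ","))
    keep <- support >= min_support
    if (any(keep)) {
      ends <- do.call(rbind, strsplit(names(support)[keep], "\r",
                                      fixed = TRUE))
      ord <- fc_order(ends[, 1], ends[, 2])
      g <- igraph::add_edges(
        g, rbind(match(ends[ord, 1], nodes), match(ends[ord, 2], nodes)),
        support = as.integer(support[keep][ord]),
        kinds = as.character(kinds[keep][ord]))
    }
  }
  g
}

#' Maximal cliques containing a focal domain
#'
#' Enumerates all maximal cliques of the context graph that contain the
#' focal domain and have at least `min_size` nodes (Bron-Kerbosch with
#' pivoting, restricted to the closed neighborhood of the focal node).
#'
#' @param graph Context graph (igraph).
#' @param focal Focal domain name; must be a graph node.
#' @param min_size Minimum clique size, >= 2.
#' @return List of character vectors (sorted node names), in a stable
#'   order.
#' @export
enumerate_focal_cliques <- function(graph, focal, min_size = 3L) {
  fc_assert(igraph::is_igraph(graph), "'graph' must be an igraph object")
  fc_assert(focal %in% igraph::V(graph)$name,
            sprintf("focal domain '%s' not in graph", focal),
            class = "famcontext_parameter_error")
  fc_assert(is_count(min_size, min = 2L), "'min_size' must be >= 2",
            class = "famcontext_parameter_error")
  # a maximal clique of G containing focal lies inside N[focal] and is
  # maximal there too, so restricting first loses nothing
  ego <- igraph::induced_subgraph(
    graph, c(focal, igraph::neighbors(graph, focal)$name))
  ego_names <- igraph::V(ego)$name
  focal_idx <- which(ego_names == focal)
  name_rank <- match(ego_names, fc_sort(ego_names))
  cl <- igraph::max_cliques(ego, min = min_size)
  cl <- lapply(cl, as.integer)
  cl <- cl[vapply(cl, function(v) focal_idx %in% v, logical(1))]
  cl <- lapply(cl, function(v) ego_names[v[order(name_rank[v])]])
  cl[fc_order(vapply(cl, paste, character(1), collapse = "|"))]
}

#' Merge focal cliques into the dense subgraph
#'
#' The dense subgraph of a focal domain is the union of all maximal
#' cliques containing it: node set = union of clique members, edge set =
#' union of within-clique edges. With `min_size = 2` this equals the
#' induced subgraph on the closed neighborhood (ego graph) of the focal
#' node. An empty clique list yields the singleton subgraph with a
#' warning.
#'
#' @param cliques List of cliques from [enumerate_focal_cliques()]; every
#'   clique must contain `focal`.
#' @param graph The parent context graph.
#' @param focal Focal domain name.
#' @param method `"auto"` uses a shortcut when some contributing clique
#'   has <= 3 nodes (which implies the enumeration's size floor was <= 3):
#'   any edge between two merged nodes then closes a triangle with the
#'   focal node, whose enclosing maximal clique (size >= 3) is a
#'   contributor, so the edge union equals the induced edge set on the
#'   merged nodes. `"cliques"` always takes the explicit union over
#'   within-clique pairs. Both give identical results; the shortcut is
#'   just faster on dense neighborhoods.
#' @return A `dense_subgraph` list: `focal_domain`, `nodes`, `edges`
#'   (two-column character matrix), `cliques`, and `subgraph` (igraph).
#' @export
merge_focal_cliques <- function(cliques, graph, focal,
                                method = c("auto", "cliques")) {
  method <- match.arg(method)
  fc_assert(focal %in% igraph::V(graph)$name,
            sprintf("focal domain '%s' not in graph", focal),
            class = "famcontext_parameter_error")
  fc_assert(all(vapply(cliques, function(cl) focal %in% cl, logical(1))),
            "every clique must contain the focal domain")
  if (length(cliques) == 0L) {
    warning(sprintf("no cliques for focal domain '%s': singleton subgraph",
                    focal))
    nodes <- focal
    edges <- matrix(character(), ncol = 2,
                    dimnames = list(NULL, c("from", "to")))
  } else {
    nodes <- fc_sort(unique(unlist(cliques, use.names = FALSE)))
    n_nodes <- length(nodes)
    use_shortcut <- method == "auto" && any(lengths(cliques) <= 3L)
    if (use_shortcut) {
      el <- igraph::as_edgelist(igraph::induced_subgraph(graph, nodes))
      pair_codes <- match(pmin(el[, 1], el[, 2]), nodes) * (n_nodes + 1) +
        match(pmax(el[, 1], el[, 2]), nodes)
    } else {
      # within-clique pairs on integer codes, de-duplicated at the end
      idx <- lapply(cliques, function(cl) sort.int(match(cl, nodes)))
      pair_codes <- unique(unlist(lapply(idx, function(v) {
        m <- length(v)
        if (m < 2L) return(numeric())
        pr <- utils::combn(v, 2L)
        pr[1L, ] * (n_nodes + 1) + pr[2L, ]
      }), use.names = FALSE))
    }
    pair_codes <- sort(pair_codes)
    edges <- cbind(from = nodes[pair_codes %/% (n_nodes + 1)],
                   to = nodes[pair_codes %% (n_nodes + 1)])
  }
  sg <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(sg)$name <- nodes
  if (nrow(edges) > 0L) {
    sg <- igraph::add_edges(sg, rbind(match(edges[, 1], nodes),
                                      match(edges[, 2], nodes)))
  }
  structure(list(focal_domain = focal, nodes = nodes, edges = edges,
                 cliques = cliques, subgraph = sg),
            class = "dense_subgraph")
}

#' One-sided Fisher's exact test (enrichment direction)
#'
#' Exact hypergeometric upper tail P(X >= a) for the 2x2 table
#' (a, b; c, d): the probability, with all margins fixed, of seeing at
#' least `a` labeled nodes in the subgraph. Computed by exact summation of
#' log-space hypergeometric densities.
#'
#' @param a,b,c,d Non-negative integer cell counts: labeled/other in
#'   subgraph, labeled/other in background.
#' @return p-value in (0, 1].
#' @export
fisher_exact_one_sided <- function(a, b, c, d) {
  for (x in list(a, b, c, d)) {
    fc_assert(is_count(x), "all contingency counts must be non-negative integers",
              class = "famcontext_parameter_error")
  }
  N <- a + b + c + d
  K <- a + c   # labeled in total
  n <- a + b   # subgraph size
  if (n == 0L || K == 0L) return(1)
  x <- seq.int(a, min(K, n))
  # full-support sums can exceed 1 by one ulp; clamp
  min(1, sum(exp(stats::dhyper(x, K, N - K, n, log = TRUE))))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity;
#' output order matches input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return q-values in [0, 1].
#' @export
bh_adjust <- function(p_values) {
  fc_assert(is.numeric(p_values) && !anyNA(p_values) &&
              all(p_values >= 0) && all(p_values <= 1),
            "p-values must all lie in [0, 1]",
            class = "famcontext_parameter_error")
  stats::p.adjust(p_values, method = "BH")
}

#' Functional-category enrichment of a dense subgraph
#'
#' For each category of the label vocabulary, counts labeled versus other
#' domains among the non-focal subgraph nodes (a, b) and among the
#' background — all other graph nodes, the focal domain excluded from both
#' sides (c, d) — then applies [fisher_exact_one_sided()] and
#' Benjamini-Hochberg correction across categories. Unlabeled domains
#' count as "other".
#'
#' @param subgraph A `dense_subgraph`.
#' @param graph The parent context graph.
#' @param labels A [functional_label_map()].
#' @param alpha Significance level applied to q-values.
#' @return Data frame with one row per category: `focal_domain`,
#'   `category`, `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`, `q_value`,
#'   `significant`; sorted by p then category.
#' @export
test_enrichment <- function(subgraph, graph, labels, alpha = 0.05) {
  fc_assert(inherits(subgraph, "dense_subgraph"),
            "'subgraph' must come from merge_focal_cliques()")
  fc_assert(inherits(labels, "functional_label_map"),
            "'labels' must be a functional_label_map")
  fc_assert(is_prob(alpha) && alpha > 0, "'alpha' must be in (0, 1]",
            class = "famcontext_parameter_error")
  all_nodes <- igraph::V(graph)$name
  fc_assert(all(subgraph$nodes %in% all_nodes),
            "subgraph contains nodes absent from the graph",
            class = "famcontext_parameter_error")
  focal <- subgraph$focal_domain
  in_sub <- setdiff(subgraph$nodes, focal)
  in_bg <- setdiff(all_nodes, c(subgraph$nodes, focal))
  cat_of <- label_of(labels, all_nodes)
  fc_assert(any(!is.na(cat_of)),
            "labels cover no category present in the graph",
            class = "famcontext_parameter_error")
  rows <- lapply(labels$categories, function(category) {
    a <- sum(cat_of[in_sub] == category, na.rm = TRUE)
    b <- length(in_sub) - a
    c_ <- sum(cat_of[in_bg] == category, na.rm = TRUE)
    d <- length(in_bg) - c_
    odds <- if (b == 0L || c_ == 0L) Inf else (a * d) / (b * c_)
    if (a == 0L) odds <- if (c_ == 0L) NaN else 0
    data.frame(focal_domain = focal, category = category,
               a = a, b = b, c = c_, d = d,
               odds_ratio = odds,
               p_value = fisher_exact_one_sided(a, b, c_, d),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value <= alpha
  res <- res[fc_order(res$p_value, res$category), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Full contextual-analysis convenience wrapper
#'
#' Decomposition, graph construction, clique merging around the focal
#' domain and enrichment testing in one call.
#'
#' @param genes,hits,labels Inputs as for the stage functions.
#' @param focal_domain Focal domain name.
#' @param max_gap_bp,max_genes,strand_rule,min_conserved_genomes Passed to
#'   [decompose_contexts()].
#' @param min_support Passed to [build_context_graph()].
#' @param min_clique_size Passed to [enumerate_focal_cliques()].
#' @param alpha Passed to [test_enrichment()].
#' @return List with `instances`, `graph`, `cliques`, `subgraph`,
#'   `enrichment`.
#' @export
context_analysis <- function(genes, hits, labels, focal_domain,
                             max_gap_bp = 200L, max_genes = 7L,
                             strand_rule = "same_strand",
                             min_conserved_genomes = 1L,
                             min_support = 1L, min_clique_size = 3L,
                             alpha = 0.05) {
  instances <- decompose_contexts(genes, hits, max_gap_bp = max_gap_bp,
                                  max_genes = max_genes,
                                  strand_rule = strand_rule,
                                  focal_domain = focal_domain,
                                  min_conserved_genomes = min_conserved_genomes)
  graph <- build_context_graph(instances, min_support = min_support)
  cliques <- enumerate_focal_cliques(graph, focal_domain,
                                     min_size = min_clique_size)
  subgraph <- merge_focal_cliques(cliques, graph, focal_domain)
  enrichment <- test_enrichment(subgraph, graph, labels, alpha = alpha)
  list(instances = instances, graph = graph, cliques = cliques,
       subgraph = subgraph, enrichment = enrichment)
}
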