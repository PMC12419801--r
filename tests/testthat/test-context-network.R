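make_genes <- function(starts, ends, strands = "+", genome = "g1",
                       ids = NULL) {
  n <- length(starts)
  ids <- ids %||% sprintf("gene%d", seq_len(n))
  data.frame(genome_id = genome, contig_id = "c1", gene_id = ids,
             start = as.integer(starts), end = as.integer(ends),
             strand = rep(strands, length.out = n),
             product_id = paste0(ids, "_p"), stringsAsFactors = FALSE)
}

make_hits <- function(product_id, domain_name, aa_start = NULL) {
  n <- length(product_id)
  data.frame(product_id = product_id, domain_name = domain_name,
             aa_start = as.integer(aa_start %||% seq(5, by = 100,
                                                     length.out = n)),
             aa_end = as.integer((aa_start %||% seq(5, by = 100,
                                                    length.out = n)) + 50),
             score = 40, source = "test", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("architectures order domains by alignment start", {
  genes <- make_genes(1, 900)
  hits <- make_hits(c("gene1_p", "gene1_p"), c("B", "A"),
                    aa_start = c(70, 5))
  inst <- decompose_contexts(genes, hits, kinds = "architecture")
  expect_length(inst, 1L)
  expect_identical(inst[[1]]$occurrences$domain_name, c("A", "B"))
  expect_identical(inst[[1]]$signature, "A>B")
})

test_that("gap and strand rules split neighborhoods as specified", {
  # gap 50 <= 200: one neighborhood (A, B)
  genes <- make_genes(c(1, 951), c(900, 1850))
  hits <- make_hits(c("gene1_p", "gene2_p"), c("A", "B"))
  inst <- decompose_contexts(genes, hits, max_gap_bp = 200,
                             kinds = "neighborhood")
  sigs <- vapply(inst, `[[`, character(1), "signature")
  expect_identical(sigs, "A>B")
  # gap 5000 > 200: two singleton neighborhoods
  far <- make_genes(c(1, 5901), c(900, 6800))
  inst2 <- decompose_contexts(far, hits, max_gap_bp = 200,
                              kinds = "neighborhood")
  expect_identical(sort(vapply(inst2, `[[`, character(1), "signature")),
                   c("A", "B"))
  # opposite strands under same_strand: also split
  opp <- make_genes(c(1, 951), c(900, 1850), strands = c("+", "-"))
  inst3 <- decompose_contexts(opp, hits, kinds = "neighborhood")
  expect_length(inst3, 2L)
  inst4 <- decompose_contexts(opp, hits, strand_rule = "any_strand",
                              kinds = "neighborhood")
  expect_length(inst4, 1L)
})

test_that("minus-strand neighborhoods are read in transcription order", {
  genes <- make_genes(c(1, 951), c(900, 1850), strands = "-")
  hits <- make_hits(c("gene1_p", "gene2_p"), c("A", "B"))
  inst <- decompose_contexts(genes, hits, kinds = "neighborhood")
  expect_identical(inst[[1]]$signature, "B>A")
})

test_that("hits naming unknown products are rejected", {
  genes <- make_genes(1, 900)
  hits <- make_hits("nosuch_p", "A")
  expect_error(decompose_contexts(genes, hits), "unknown")
})

test_that("focal windowing caps neighborhoods at max_genes per side", {
  n <- 9
  starts <- seq(1, by = 950, length.out = n)
  genes <- make_genes(starts, starts + 899)
  hits <- make_hits(paste0(sprintf("gene%d", 1:n), "_p"),
                    c(rep("X", 4), "FOC", rep("Y", 4)))
  inst <- decompose_contexts(genes, hits, max_genes = 2,
                             focal_domain = "FOC",
                             kinds = "neighborhood")
  expect_length(inst, 1L)
  expect_identical(inst[[1]]$signature, "X>X>FOC>Y>Y")
})

test_that("adjacency edges count distinct genome support", {
  inst3 <- list(
    list(kind = "neighborhood", genome_id = "g1",
         occurrences = data.frame(domain_name = c("A", "B", "C"),
                                  gene_id = "x", position = 1:3),
         signature = "A>B>C"))
  g <- build_context_graph(inst3)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  ends <- igraph::as_edgelist(g)
  expect_setequal(paste(ends[, 1], ends[, 2]), c("A B", "B C"))
  expect_true(all(igraph::E(g)$support == 1L))
  # same adjacency in 3 genomes, min_support 2 keeps it with support 3
  rep3 <- lapply(1:3, function(i) {
    list(kind = "neighborhood", genome_id = paste0("g", i),
         occurrences = data.frame(domain_name = c("A", "B"),
                                  gene_id = "x", position = 1:2),
         signature = "A>B")
  })
  g2 <- build_context_graph(rep3, min_support = 2)
  expect_identical(igraph::E(g2)$support, 3L)
  # repeat domains drop the self-adjacency but keep the rest
  rep_self <- list(list(kind = "architecture", genome_id = "g1",
                        occurrences = data.frame(
                          domain_name = c("A", "A", "B"),
                          gene_id = "x", position = 1:3),
                        signature = "A>A>B"))
  expect_message(g3 <- build_context_graph(rep_self), "self-adjacency")
  ends3 <- igraph::as_edgelist(g3)
  expect_identical(paste(ends3[, 1], ends3[, 2]), "A B")
})

test_that("conservation filter keeps only recurrent signatures", {
  mk <- function(genome, doms, start0) {
    make_genes(c(start0, start0 + 950), c(start0 + 899, start0 + 1849),
               genome = genome,
               ids = paste0(genome, "_", seq_along(doms)))
  }
  genes <- rbind(mk("g1", c("A", "B"), 1), mk("g2", c("A", "B"), 1),
                 mk("g3", c("A", "B"), 1), mk("g4", c("C", "D"), 1))
  hits <- make_hits(genes$product_id, c("A", "B", "A", "B", "A", "B",
                                        "C", "D"))
  inst <- decompose_contexts(genes, hits, min_conserved_genomes = 3,
                             kinds = "neighborhood")
  sigs <- vapply(inst, `[[`, character(1), "signature")
  expect_identical(sort(sigs), rep("A>B", 3))
})

test_that("focal cliques match the toy anchors", {
  tri <- igraph::make_graph(~ F - A, F - B, A - B)
  cl <- enumerate_focal_cliques(tri, "F", min_size = 3)
  expect_identical(cl, list(c("A", "B", "F")))
  star <- igraph::make_graph(~ F - A, F - B)
  expect_identical(enumerate_focal_cliques(star, "F", 3), list())
  expect_error(enumerate_focal_cliques(star, "Z", 3),
               class = "famcontext_parameter_error")
})

test_that("focal cliques equal exhaustive enumeration on random graphs", {
  withr::with_seed(77, {
    for (i in 1:200) {
      n <- sample(4:12, 1)
      g <- random_named_graph(n, runif(1, 0.2, 0.7))
      min_size <- sample(2:4, 1)
      got <- enumerate_focal_cliques(g, "F", min_size)
      want <- oracle_focal_cliques(g, "F", min_size)
      expect_setequal_cliques(got, want)
    }
  })
})

test_that("clique merge matches the worked example", {
  g <- igraph::make_graph(~ F - A, F - B, F - C, A - B, B - C)
  cliques <- list(c("A", "B", "F"), c("B", "C", "F"))
  sub <- merge_focal_cliques(cliques, g, "F")
  expect_setequal(sub$nodes, c("A", "B", "C", "F"))
  expect_identical(nrow(sub$edges), 5L)
  got <- paste(sub$edges[, 1], sub$edges[, 2])
  expect_setequal(got, c("A B", "A F", "B C", "B F", "C F"))
})

test_that("empty clique list warns and returns the singleton subgraph", {
  star <- igraph::make_graph(~ F - A, F - B)
  expect_warning(sub <- merge_focal_cliques(list(), star, "F"),
                 "singleton")
  expect_identical(sub$nodes, "F")
  expect_identical(nrow(sub$edges), 0L)
})

test_that("merging with min_size 2 reproduces the induced ego graph", {
  withr::with_seed(78, {
    for (i in 1:200) {
      n <- sample(4:12, 1)
      g <- random_named_graph(n, runif(1, 0.15, 0.7))
      cl <- enumerate_focal_cliques(g, "F", min_size = 2)
      sub <- if (length(cl) == 0L) {
        suppressWarnings(merge_focal_cliques(cl, g, "F"))
      } else {
        merge_focal_cliques(cl, g, "F")
      }
      ego <- igraph::induced_subgraph(
        g, c("F", igraph::neighbors(g, "F")$name))
      expect_setequal(sub$nodes, igraph::V(ego)$name)
      expect_equal(nrow(sub$edges), as.integer(igraph::ecount(ego)))
      # and always: nodes confined to the closed neighborhood of F
      expect_true(all(sub$nodes %in% c("F", igraph::neighbors(g, "F")$name)))
    }
  })
})

test_that("merge shortcut and explicit clique union are identical", {
  withr::with_seed(79, {
    for (i in 1:50) {
      g <- random_named_graph(10, 0.5)
      cl <- enumerate_focal_cliques(g, "F", min_size = 3)
      if (length(cl) == 0L) next
      s1 <- merge_focal_cliques(cl, g, "F", method = "auto")
      s2 <- merge_focal_cliques(cl, g, "F", method = "cliques")
      expect_identical(s1$nodes, s2$nodes)
      expect_identical(s1$edges, s2$edges)
    }
  })
})

test_that("one-sided Fisher matches enumeration anchors and monotonicity", {
  expect_identical(fisher_exact_one_sided(0, 5, 3, 2), 1)
  expect_equal(fisher_exact_one_sided(3, 1, 1, 3), 17 / 70,
               tolerance = 1e-12)
  # increasing a with all margins fixed never increases p
  ps <- vapply(0:4, function(a) fisher_exact_one_sided(a, 4 - a, 4 - a, a),
               numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(fisher_exact_one_sided(-1, 2, 3, 4),
               class = "famcontext_parameter_error")
})

test_that("Fisher p agrees with stats::fisher.test", {
  withr::with_seed(14, {
    for (i in 1:25) {
      tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
      expect_equal(
        fisher_exact_one_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
        stats::fisher.test(tab, alternative = "greater")$p.value,
        tolerance = 1e-10)
    }
  })
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_identical(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9),
               tolerance = 1e-12)
  expect_identical(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_error(bh_adjust(c(0.5, 1.2)),
               class = "famcontext_parameter_error")
})

test_that("enrichment counts partition the non-focal node set", {
  ctx <- gen_context_dataset(n_genomes = 40, seed = 55)
  res <- suppressMessages(suppressWarnings(
    context_analysis(ctx$genes, ctx$hits, ctx$labels, "ConeTM")))
  n_nonfocal <- igraph::vcount(res$graph) - 1L
  expect_true(all(res$enrichment$a + res$enrichment$b +
                    res$enrichment$c + res$enrichment$d == n_nonfocal))
  expect_true(all(res$enrichment$p_value > 0 & res$enrichment$p_value <= 1))
  expect_true(all(res$enrichment$q_value >= 0 & res$enrichment$q_value <= 1))
})

test_that("a fully enriched subgraph ranks its category first", {
  g <- igraph::make_full_graph(4)
  igraph::V(g)$name <- c("F", "L1", "L2", "L3")
  g <- igraph::add_vertices(g, 3, name = c("O1", "O2", "O3"))
  g <- igraph::add_edges(g, c(match("O1", igraph::V(g)$name),
                              match("O2", igraph::V(g)$name)))
  labels <- functional_label_map(
    categories = c("lipid", "other"),
    domains = c(L1 = "lipid", L2 = "lipid", L3 = "lipid",
                O1 = "other", O2 = "other", O3 = "other"))
  cl <- enumerate_focal_cliques(g, "F", 3)
  sub <- merge_focal_cliques(cl, g, "F")
  res <- test_enrichment(sub, g, labels, alpha = 0.05)
  expect_identical(res$category[1], "lipid")
  expect_identical(res$a[1], 3L)
  expect_identical(res$c[1], 0L)
  expect_equal(res$p_value[1], oracle_fisher_greater(3, 0, 0, 3),
               tolerance = 1e-12)
})

test_that("the pipeline is deterministic end to end", {
  ctx <- gen_context_dataset(n_genomes = 30, seed = 66)
  r1 <- suppressMessages(suppressWarnings(
    context_analysis(ctx$genes, ctx$hits, ctx$labels, "ConeTM")))
  r2 <- suppressMessages(suppressWarnings(
    context_analysis(ctx$genes, ctx$hits, ctx$labels, "ConeTM")))
  expect_identical(r1$enrichment, r2$enrichment)
  expect_identical(r1$subgraph$nodes, r2$subgraph$nodes)
})
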