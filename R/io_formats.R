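# Readers and writers for the external representations the pipeline
# touches. Internal convention everywhere: 1-based, inclusive coordinates
# (both bp and aa), matching GFF3 and HMMER.

#' Read a gene coordinate table
#'
#' @param path Input file.
#' @param dialect `"tsv"` (columns genome_id, contig_id, gene_id, start,
#'   end, strand, product_id) or `"gff3"` (CDS features; `ID` attribute is
#'   the gene id, `product_id` attribute if present else `ID` is the
#'   product id).
#' @param genome_id Genome identifier for GFF3 input, which carries none;
#'   defaults to the file name without extension.
#' @return Data frame of gene records sorted by (genome_id, contig_id,
#'   start), coordinates 1-based inclusive.
#' @export
read_gene_table <- function(path, dialect = c("tsv", "gff3"),
                            genome_id = NULL) {
  dialect <- match.arg(dialect)
  cols <- c("genome_id", "contig_id", "gene_id", "start", "end",
            "strand", "product_id")
  if (dialect == "tsv") {
    df <- read_fc_tsv(path, required = cols)
    df <- df[, cols]
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "CDS"]
    if (is.null(genome_id)) {
      genome_id <- sub("\\.[^.]*$", "", basename(path))
    }
    product <- if ("product_id" %in% names(S4Vectors::mcols(gr))) {
      as.character(gr$product_id)
    } else {
      as.character(gr$ID)
    }
    df <- data.frame(
      genome_id = genome_id,
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      gene_id = as.character(gr$ID),
      start = BiocGenerics::start(gr),
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      product_id = product,
      stringsAsFactors = FALSE)
  }
  validate_gene_table(df)
  df <- df[fc_order(df$genome_id, df$contig_id, df$start), ]
  rownames(df) <- NULL
  df
}

validate_gene_table <- function(df) {
  bad <- which(df$end < df$start | df$start < 1)
  if (length(bad) > 0L) {
    fc_abort(sprintf("invalid gene coordinates (end < start or start < 1) at row(s): %s",
                     paste(bad, collapse = ", ")))
  }
  fc_assert(all(df$strand %in% c("+", "-")),
            "strand must be '+' or '-'")
  key <- paste(df$genome_id, df$gene_id)
  fc_assert(!anyDuplicated(key),
            "duplicate (genome_id, gene_id) pairs in gene table")
  invisible(df)
}

#' Write a gene coordinate table
#'
#' @param genes Gene record data frame (see [read_gene_table()]).
#' @param path Output file.
#' @param dialect `"tsv"` or `"gff3"` (one file; `genome_id` is not
#'   representable in GFF3 and is restored at read time).
#' @return The path, invisibly.
#' @export
write_gene_table <- function(genes, path, dialect = c("tsv", "gff3")) {
  dialect <- match.arg(dialect)
  validate_gene_table(genes)
  if (dialect == "tsv") {
    return(write_fc_tsv(genes, path))
  }
  fc_assert(length(unique(genes$genome_id)) <= 1L,
            "GFF3 output holds one genome per file")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  gr$type <- "CDS"
  gr$source <- "famcontext"
  gr$phase <- 0L  # complete CDS records; silences the exporter's warning
  gr$ID <- genes$gene_id
  gr$product_id <- genes$product_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read per-protein domain hits
#'
#' @param path Input file.
#' @param dialect `"domtblout"` (HMMER3 per-domain table; envelope
#'   coordinates are used as the hit interval) or `"tsv"` (columns
#'   product_id, domain_name, aa_start, aa_end, score, source).
#' @param source Profile collection name to record; for domtblout defaults
#'   to the target accession field when present, else `"hmmer"`.
#' @return Data frame of domain hits, aa coordinates 1-based inclusive,
#'   sorted by (product_id, aa_start).
#' @export
read_domain_hits <- function(path, dialect = c("domtblout", "tsv"),
                             source = NULL) {
  dialect <- match.arg(dialect)
  cols <- c("product_id", "domain_name", "aa_start", "aa_end",
            "score", "source")
  if (dialect == "tsv") {
    df <- read_fc_tsv(path, required = cols)[, cols]
  } else {
    lines <- readLines(path)
    keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
    if (length(keep) == 0L) {
      df <- data.frame(product_id = character(), domain_name = character(),
                       aa_start = integer(), aa_end = integer(),
                       score = numeric(), source = character(),
                       stringsAsFactors = FALSE)
    } else {
      rows <- lapply(keep, function(i) {
        f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
        if (length(f) < 22L) {
          fc_abort(sprintf("%s line %d: expected >= 22 domtblout fields, got %d",
                           path, i, length(f)),
                   class = "famcontext_format_error")
        }
        # fields: 1 target (profile), 2 target acc, 4 query (product),
        # 14 this-domain bit score, 20..21 envelope from/to
        src <- if (!is.null(source)) source
               else if (f[2] != "-") f[2] else "hmmer"
        data.frame(product_id = f[4], domain_name = f[1],
                   aa_start = as.integer(f[20]), aa_end = as.integer(f[21]),
                   score = as.numeric(f[14]), source = src,
                   stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
      if (anyNA(df$aa_start) || anyNA(df$aa_end) || anyNA(df$score)) {
        bad <- keep[which(is.na(df$aa_start) | is.na(df$aa_end) |
                            is.na(df$score))]
        fc_abort(sprintf("%s: unparsable numeric field(s) at line(s): %s",
                         path, paste(bad, collapse = ", ")),
                 class = "famcontext_format_error")
      }
    }
  }
  fc_assert(all(df$aa_start >= 1) && all(df$aa_end >= df$aa_start),
            "domain hit coordinates must satisfy 1 <= aa_start <= aa_end")
  df <- df[fc_order(df$product_id, df$aa_start), ]
  rownames(df) <- NULL
  df
}

#' Write domain hits
#'
#' @param hits Domain hit data frame (see [read_domain_hits()]).
#' @param path Output file.
#' @param dialect `"tsv"` or `"domtblout"` (a minimal but valid HMMER3
#'   per-domain table; unknown fields are written as `-` or 0).
#' @return The path, invisibly.
#' @export
write_domain_hits <- function(hits, path, dialect = c("tsv", "domtblout")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    return(write_fc_tsv(hits, path))
  }
  header <- paste0("# famcontext domtblout export\n",
                   "#target_name accession tlen query_name accession qlen ",
                   "E-value score bias n of c-Evalue i-Evalue score bias ",
                   "hmm_from hmm_to ali_from ali_to env_from env_to acc ",
                   "description")
  rows <- vapply(seq_len(nrow(hits)), function(i) {
    paste(hits$domain_name[i], hits$source[i], 0, hits$product_id[i], "-", 0,
          0, hits$score[i], 0, 1, 1, 0, 0, hits$score[i], 0,
          hits$aa_start[i], hits$aa_end[i], hits$aa_start[i], hits$aa_end[i],
          hits$aa_start[i], hits$aa_end[i], 0, "-")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Functional label map
#'
#' Maps domain names to categories from a user-declared controlled
#' vocabulary. Domains without a mapping are permitted and treated as
#' unlabeled downstream.
#'
#' @param categories Character vector, the controlled vocabulary.
#' @param domains Named character vector or single-depth list mapping
#'   domain name to category; every category must be in `categories`.
#' @return A `functional_label_map` object.
#' @export
functional_label_map <- function(categories, domains = character()) {
  categories <- as.character(categories)
  fc_assert(length(categories) >= 1L && !anyDuplicated(categories),
            "categories must be a non-empty vector without duplicates")
  domains <- unlist(domains)
  if (length(domains) > 0L) {
    fc_assert(!is.null(names(domains)) && all(nzchar(names(domains))),
              "domains must be a named mapping")
    bad <- which(!(domains %in% categories))
    if (length(bad) > 0L) {
      fc_abort(sprintf("domain '%s' mapped to undeclared category '%s'",
                       names(domains)[bad[1]], domains[bad[1]]))
    }
  }
  structure(list(categories = categories,
                 domains = as.list(domains)),
            class = "functional_label_map")
}

#' Look up the category of each domain
#'
#' @param labels A [functional_label_map()].
#' @param domain_names Character vector of domain names.
#' @return Character vector of categories, `NA` for unlabeled domains.
#' @export
label_of <- function(labels, domain_names) {
  fc_assert(inherits(labels, "functional_label_map"),
            "'labels' must be a functional_label_map")
  out <- unlist(labels$domains)[domain_names]
  out <- as.character(out)
  names(out) <- domain_names
  out
}

#' Read a functional label map from YAML
#'
#' Expects top-level keys `categories` (list of names) and `domains`
#' (mapping domain name to category).
#'
#' @param path YAML file.
#' @return A [functional_label_map()].
#' @export
read_label_yaml <- function(path) {
  fc_assert(file.exists(path), sprintf("file not found: %s", path),
            class = "famcontext_io_error")
  y <- yaml::read_yaml(path)
  fc_assert(all(c("categories", "domains") %in% names(y)),
            sprintf("%s: YAML must have top-level 'categories' and 'domains'",
                    path),
            class = "famcontext_format_error")
  functional_label_map(unlist(y$categories), y$domains)
}

#' Write a functional label map to YAML
#'
#' @param labels A [functional_label_map()].
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_label_yaml <- function(labels, path) {
  fc_assert(inherits(labels, "functional_label_map"),
            "'labels' must be a functional_label_map")
  doms <- labels$domains[fc_order(names(labels$domains))]
  yaml::write_yaml(list(categories = as.list(labels$categories),
                        domains = doms), path)
  invisible(path)
}

#' Write a weighted undirected graph
#'
#' @param graph An igraph object with unique character vertex names and
#'   finite non-negative numeric edge weights (attribute `weight`; graphs
#'   without a weight attribute are written with weight 1).
#' @param path Output file.
#' @param dialect `"graphml"` or `"edgelist_tsv"` (columns from, to,
#'   weight; isolated vertices recorded as a commented node list header).
#' @return The path, invisibly.
#' @export
write_network <- function(graph, path, dialect = c("graphml", "edgelist_tsv")) {
  dialect <- match.arg(dialect)
  fc_assert(igraph::is_igraph(graph), "'graph' must be an igraph object")
  nm <- igraph::V(graph)$name
  fc_assert(!is.null(nm) && !anyDuplicated(nm) && all(nzchar(nm)),
            "vertex names must be unique non-empty text")
  if (!("weight" %in% igraph::edge_attr_names(graph))) {
    igraph::E(graph)$weight <- rep(1, igraph::ecount(graph))
  }
  w <- igraph::E(graph)$weight
  fc_assert(all(is.finite(w)) && all(w >= 0),
            "edge weights must be finite and non-negative")
  if (dialect == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    df <- data.frame(from = el[, 1], to = el[, 2], weight = w,
                     stringsAsFactors = FALSE)
    df <- df[fc_order(df$from, df$to), , drop = FALSE]
    con <- file(path, "w")
    writeLines(sprintf("# nodes: %s", paste(fc_sort(nm), collapse = ",")),
               con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    close(con)
  }
  invisible(path)
}

#' Read a weighted undirected graph written by [write_network()]
#'
#' @param path Input file.
#' @param dialect `"graphml"` or `"edgelist_tsv"`.
#' @return An igraph object with vertex names and edge weights.
#' @export
read_network <- function(path, dialect = c("graphml", "edgelist_tsv")) {
  dialect <- match.arg(dialect)
  fc_assert(file.exists(path), sprintf("file not found: %s", path),
            class = "famcontext_io_error")
  if (dialect == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (!("name" %in% igraph::vertex_attr_names(g)) &&
        "id" %in% igraph::vertex_attr_names(g)) {
      igraph::V(g)$name <- igraph::V(g)$id
    }
    return(g)
  }
  first <- readLines(path, n = 1L)
  nodes <- character()
  if (grepl("^# nodes:", first)) {
    spec <- trimws(sub("^# nodes:", "", first))
    if (nzchar(spec)) nodes <- strsplit(spec, ",")[[1]]
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  all_nodes <- fc_sort(unique(c(nodes, df$from, df$to)))
  g <- igraph::add_vertices(g, length(all_nodes), name = all_nodes)
  if (nrow(df) > 0L) {
    g <- igraph::add_edges(g, rbind(match(df$from, all_nodes),
                                    match(df$to, all_nodes)),
                           weight = df$weight)
  }
  g
}
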