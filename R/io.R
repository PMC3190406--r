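read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("cannot read ", what, " table: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", na.strings = NULL)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read node and edge tables
#'
#' Tab-delimited UTF-8 tables with a header line. The node table has columns
#' `id`, `type`, `label`; the edge table has `source`, `target`, `type`,
#' `weight`, `directed`, `pubmed`. A `"."` in `weight` means "use the
#' default" (1.0); `pubmed` holds semicolon-delimited PubMed ids, `""` or
#' `"."` for none. Error messages carry the offending file line number
#' (header is line 1).
#'
#' `read_edge_table` enforces the container invariants at parse time:
#' unknown edge types, edges referencing nodes absent from `nodes`, duplicate
#' `(source, target, type)` triples (after canonicalizing undirected edges)
#' and a `directed` flag inconsistent with the edge class are all rejected.
#' Duplicate association reports are not merged here; merging with Fisher's
#' method happens during assembly only.
#'
#' @param path file path.
#' @param nodes node table (data frame) against which edge endpoints are
#'   checked.
#' @return `read_node_table`: a node data frame; `read_edge_table`: an edge
#'   data frame (see [empty_nodes()] for layouts).
#' @export
read_node_table <- function(path) {
  df <- read_tsv_checked(path, c("id", "type", "label"), "node")
  if (nrow(df) == 0) return(empty_nodes())
  line <- seq_len(nrow(df)) + 1L
  bad <- !df$type %in% .NODE_TYPES
  if (any(bad)) {
    i <- which(bad)[1]
    stop("line ", line[i], " of ", path, ": unknown node type '", df$type[i], "'")
  }
  if (anyDuplicated(df$id)) {
    i <- which(duplicated(df$id))[1]
    stop("line ", line[i], " of ", path, ": duplicate node id '", df$id[i], "'")
  }
  as_node_df(df)
}

#' @rdname read_node_table
#' @export
read_edge_table <- function(path, nodes) {
  nodes <- as_node_df(nodes)
  df <- read_tsv_checked(
    path, c("source", "target", "type", "weight", "directed", "pubmed"), "edge")
  if (nrow(df) == 0) return(empty_edges())
  line <- seq_len(nrow(df)) + 1L

  bad <- !df$type %in% .EDGE_TYPES$type
  if (any(bad)) {
    i <- which(bad)[1]
    stop("line ", line[i], " of ", path, ": unknown edge type '", df$type[i], "'")
  }
  info <- edge_type_info(df$type)

  weight <- suppressWarnings(as.numeric(df$weight))
  use_default <- df$weight %in% c(".", "")
  weight[use_default] <- 1
  if (anyNA(weight)) {
    i <- which(is.na(weight))[1]
    stop("line ", line[i], " of ", path, ": unparseable weight '", df$weight[i], "'")
  }

  directed <- tolower(df$directed) %in% c("true", "t", "1", "yes")
  bad_dir <- !tolower(df$directed) %in%
    c("true", "t", "1", "yes", "false", "f", "0", "no")
  if (any(bad_dir)) {
    i <- which(bad_dir)[1]
    stop("line ", line[i], " of ", path, ": unparseable directed flag '",
         df$directed[i], "'")
  }
  if (any(directed != info$directed)) {
    i <- which(directed != info$directed)[1]
    stop("line ", line[i], " of ", path, ": edge class ", df$type[i],
         " must be ", if (info$directed[i]) "directed" else "undirected")
  }

  missing_ep <- !(df$source %in% nodes$id) | !(df$target %in% nodes$id)
  if (any(missing_ep)) {
    i <- which(missing_ep)[1]
    absent <- setdiff(c(df$source[i], df$target[i]), nodes$id)
    stop("line ", line[i], " of ", path, ": referential integrity: node '",
         absent[1], "' not in node table")
  }

  pubmed <- df$pubmed
  pubmed[pubmed == "."] <- ""
  edges <- canonicalize_edges(data.frame(
    source = df$source, target = df$target, type = df$type,
    weight = weight, directed = directed, pubmed = pubmed,
    stringsAsFactors = FALSE))
  if (anyDuplicated(edge_key(edges))) {
    i <- which(duplicated(edge_key(edges)))[1]
    stop("line ", line[i], " of ", path, ": duplicate edge ",
         df$source[i], " -> ", df$target[i], " (", df$type[i], ")")
  }
  edges
}

#' Read a network from a tsv_pair directory
#'
#' Reads `nodes.tsv` and `edges.tsv` (the `tsv_pair` layout written by
#' [write_network()]) and returns the validated network.
#'
#' @param dir directory containing `nodes.tsv` and `edges.tsv`.
#' @return A [hetero_network].
#' @export
read_network <- function(dir) {
  nodes <- read_node_table(file.path(dir, "nodes.tsv"))
  edges <- read_edge_table(file.path(dir, "edges.tsv"), nodes)
  hetero_network(nodes, edges)
}

fmt_num <- function(x) {
  ## round-trips doubles through text to >= 15 significant digits
  sprintf("%.17g", x)
}

#' Write a network to disk
#'
#' Three formats are supported:
#' \describe{
#'   \item{`tsv_pair`}{`nodes.tsv` + `edges.tsv` in `path` (a directory);
#'     lossless, round-trips exactly through [read_network()].}
#'   \item{`sif`}{Cytoscape SIF at `path`: one `source<TAB>token<TAB>target`
#'     line per edge using the fixed edge-class tokens `dg` (disease_gene),
#'     `pp` (protein_protein), `pd` (protein_dna), `dt` (disease_tissue),
#'     `tg` (tissue_gene), `drg` (drug_gene); isolated nodes are emitted as
#'     bare node lines. Edge weights and PubMed ids go to sidecar attribute
#'     tables `<path>.weight.eda` and `<path>.pubmed.eda`.}
#'   \item{`graphml`}{GraphML at `path` with typed attributes (`node_type`,
#'     `label`, `edge_type`, `weight`, `pubmed`, `edge_directed`).}
#' }
#'
#' @param net a [hetero_network].
#' @param path output directory (`tsv_pair`) or file (`sif`, `graphml`).
#' @param format one of `"tsv_pair"`, `"sif"`, `"graphml"`.
#' @return The paths written, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv_pair", "sif", "graphml")) {
  stopifnot(inherits(net, "hetero_network"))
  format <- match.arg(format)
  switch(format,
    tsv_pair = write_tsv_pair(net, path),
    sif = write_sif(net, path),
    graphml = write_graphml(net, path))
}

write_tsv_pair <- function(net, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  np <- file.path(dir, "nodes.tsv")
  ep <- file.path(dir, "edges.tsv")
  nodes <- net$nodes
  edges <- net$edges
  con <- file(np, "w", encoding = "UTF-8")
  writeLines(c("id\ttype\tlabel",
               if (nrow(nodes)) paste(nodes$id, nodes$type, nodes$label,
                                      sep = "\t")), con)
  close(con)
  con <- file(ep, "w", encoding = "UTF-8")
  writeLines(c("source\ttarget\ttype\tweight\tdirected\tpubmed",
               if (nrow(edges)) paste(edges$source, edges$target, edges$type,
                                      fmt_num(edges$weight),
                                      ifelse(edges$directed, "true", "false"),
                                      ifelse(nzchar(edges$pubmed),
                                             edges$pubmed, "."),
                                      sep = "\t")), con)
  close(con)
  invisible(c(np, ep))
}

write_sif <- function(net, path) {
  edges <- net$edges
  tokens <- edge_type_info(edges$type)$sif
  lines <- if (nrow(edges)) paste(edges$source, tokens, edges$target,
                                  sep = "\t") else character()
  isolated <- setdiff(net$nodes$id, c(edges$source, edges$target))
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(c(lines, isolated), con)
  close(con)
  out <- path
  if (nrow(edges)) {
    ekey <- paste0(edges$source, " (", tokens, ") ", edges$target)
    wp <- paste0(path, ".weight.eda")
    con <- file(wp, "w", encoding = "UTF-8")
    writeLines(c("weight", paste(ekey, "=", fmt_num(edges$weight))), con)
    close(con)
    pp <- paste0(path, ".pubmed.eda")
    con <- file(pp, "w", encoding = "UTF-8")
    writeLines(c("pubmed", paste(ekey, "=",
                                 ifelse(nzchar(edges$pubmed), edges$pubmed, "."))),
               con)
    close(con)
    out <- c(path, wp, pp)
  }
  invisible(out)
}

#' Convert to and from igraph
#'
#' `as_igraph` returns a directed `igraph` graph carrying all node and edge
#' attributes; undirected network edges are marked with the edge attribute
#' `edge_directed = FALSE` (they appear once, in canonical orientation).
#'
#' @param net a [hetero_network].
#' @return An `igraph` object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "hetero_network"))
  vdf <- data.frame(name = net$nodes$id, node_type = net$nodes$type,
                    label = net$nodes$label, stringsAsFactors = FALSE)
  edf <- data.frame(from = net$edges$source, to = net$edges$target,
                    edge_type = net$edges$type, weight = net$edges$weight,
                    pubmed = net$edges$pubmed,
                    edge_directed = net$edges$directed,
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

write_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read gene annotation from BED6
#'
#' Reads a BED6 file (`chrom`, `chromStart`, `chromEnd`, `name`, `score`,
#' `strand`; 0-based half-open coordinates) and returns the package's
#' internal 1-based inclusive annotation table with the transcriptional
#' start site resolved per strand (`start` for `+`, `end` for `-`). The
#' BED `name` field is the gene symbol; `score` is ignored.
#'
#' @param path BED6 file path.
#' @return data frame with columns `symbol`, `chrom`, `start`, `end`,
#'   `strand`, `tss`.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("gene annotation requires an explicit strand for every record")
  ann <- data.frame(
    symbol = as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand,
    stringsAsFactors = FALSE)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  stopifnot(all(c("symbol", "chrom", "start", "end", "strand") %in% names(ann)))
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  if (any(ann$start > ann$end)) stop("gene annotation with start > end")
  if (any(!ann$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(ann$symbol))
    stop("duplicate gene symbol(s) in annotation: ",
         paste(unique(ann$symbol[duplicated(ann$symbol)]), collapse = ", "))
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  rownames(ann) <- NULL
  ann[, c("symbol", "chrom", "start", "end", "strand", "tss")]
}

#' Read phenotype-SNP association records
#'
#' TSV with header and columns `snp_id`, `chrom`, `pos`, `phenotype`,
#' `pvalue`, `pubmed` — one row per reported study result, so the same
#' phenotype-SNP pair may occur on several rows (one per study). P-values
#' reported as 0 are clamped to 1e-300 with a warning so that the
#' `-log10(p)` edge weight stays finite.
#'
#' @param path TSV file path.
#' @return data frame of association records.
#' @export
read_association_table <- function(path) {
  df <- read_tsv_checked(
    path, c("snp_id", "chrom", "pos", "phenotype", "pvalue", "pubmed"),
    "association")
  df$pos <- as.integer(df$pos)
  df$pvalue <- as.numeric(df$pvalue)
  if (anyNA(df$pos) || any(df$pos < 1)) stop("positions must be integers >= 1")
  if (anyNA(df$pvalue) || any(df$pvalue > 1))
    stop("p-values must be numeric in (0, 1]")
  zero <- df$pvalue <= 0
  if (any(zero)) {
    warning(sum(zero), " p-value(s) <= 0 clamped to 1e-300", call. = FALSE)
    df$pvalue[zero] <- 1e-300
  }
  df[, c("snp_id", "chrom", "pos", "phenotype", "pvalue", "pubmed")]
}

#' Read transcription-factor binding-site records
#'
#' TSV with header and columns `tf_symbol`, `chrom`, `pos` (1-based site
#' midpoint) and `zscore` (binding-site confidence score).
#'
#' @param path TSV file path.
#' @return data frame of TFBS records.
#' @export
read_tfbs_table <- function(path) {
  df <- read_tsv_checked(path, c("tf_symbol", "chrom", "pos", "zscore"), "TFBS")
  df$pos <- as.integer(df$pos)
  df$zscore <- as.numeric(df$zscore)
  if (anyNA(df$pos) || anyNA(df$zscore)) stop("unparseable TFBS record")
  df[, c("tf_symbol", "chrom", "pos", "zscore")]
}
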