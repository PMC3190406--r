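#' Assembly configuration
#'
#' Parameters controlling how the five-layer network is built from raw
#' records.
#'
#' @param threshold_tau significance threshold on the `-log10(p)` scale;
#'   disease-gene edges with weight >= `threshold_tau` (equivalently
#'   p <= 10^-tau, boundary inclusive) are retained. `0` keeps everything.
#' @param ds degrees of separation (0, 1 or 2): radius of the gene-gene
#'   neighbourhood added around directly associated genes. `ds = 0` keeps
#'   only direct associations plus existing interactions among them.
#' @param layers subset of `c("ppi", "tfbs", "tissue", "drug")` to attach.
#' @param z_min TFBS confidence cutoff; only sites with score strictly
#'   greater than `z_min` induce edges (default 4.0).
#' @param promoter_window maximum distance in bp (inclusive) between a
#'   binding site and the nearest transcriptional start site (default 5000).
#' @param keep_isolated_diseases retain diseases whose every association
#'   fails the threshold as isolated nodes (default `FALSE`: dropped).
#' @return A list of class `assembly_config`.
#' @export
assembly_config <- function(threshold_tau = 0, ds = 0, layers = character(),
                            z_min = 4, promoter_window = 5000,
                            keep_isolated_diseases = FALSE) {
  if (!is.numeric(threshold_tau) || length(threshold_tau) != 1 ||
      is.na(threshold_tau) || threshold_tau < 0)
    stop("threshold_tau must be a single number >= 0")
  if (!ds %in% c(0L, 1L, 2L)) stop("ds must be 0, 1 or 2")
  layers <- as.character(layers)
  unknown <- setdiff(layers, c("ppi", "tfbs", "tissue", "drug"))
  if (length(unknown)) stop("unknown layer(s): ", paste(unknown, collapse = ", "))
  structure(list(threshold_tau = threshold_tau, ds = as.integer(ds),
                 layers = layers, z_min = z_min,
                 promoter_window = promoter_window,
                 keep_isolated_diseases = keep_isolated_diseases),
            class = "assembly_config")
}

## Nearest-feature lookup via GenomicRanges, with exact-distance refinement
## and a lexicographic tie-break on the gene symbol. `feat` needs columns
## chrom, .start, .end, symbol. Returns NA where the chromosome has no
## feature.
nearest_feature <- function(chrom, pos, feat) {
  res <- rep(NA_character_, length(pos))
  if (nrow(feat) == 0 || length(pos) == 0) return(res)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(feat$chrom, IRanges::IRanges(feat$.start, feat$.end))
  ## suppressed: seqlevel-mismatch chatter when a query chromosome has no
  ## feature at all (those queries legitimately return NA)
  hits <- suppressWarnings(
    GenomicRanges::nearest(q, s, select = "all", ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (!length(qh)) return(res)
  ## nearest() measures gap distance (0 for adjacency), so refine ties with
  ## the exact point-to-interval distance before breaking them by symbol
  p <- pos[qh]
  d <- ifelse(p >= feat$.start[sh] & p <= feat$.end[sh], 0,
              pmin(abs(p - feat$.start[sh]), abs(p - feat$.end[sh])))
  sym <- feat$symbol[sh]
  ord <- order(qh, d, sym)
  qh <- qh[ord]; d <- d[ord]; sym <- sym[ord]
  first <- !duplicated(qh)
  ## drop refined candidates that are not at the true minimum distance
  res[qh[first]] <- sym[first]
  res
}

#' Map SNPs to their nearest gene
#'
#' Each SNP position is assigned the gene minimizing its distance to the
#' gene body: 0 if the position falls inside `[start, end]`, otherwise the
#' distance to the nearer boundary. Exact ties are broken toward the
#' lexicographically smaller gene symbol, so the mapping is deterministic.
#'
#' @param chrom,pos character / integer vectors (parallel) of SNP
#'   coordinates, 1-based.
#' @param annotation gene annotation table (see [read_gene_annotation()]).
#' @param on_unmapped `"error"` (default) stops if any SNP lies on a
#'   chromosome with no annotated gene; `"na"` returns `NA` for those.
#' @return Character vector of gene symbols, parallel to `pos`.
#' @export
map_snp_to_gene <- function(chrom, pos, annotation,
                            on_unmapped = c("error", "na")) {
  on_unmapped <- match.arg(on_unmapped)
  annotation <- validate_annotation(annotation)
  feat <- data.frame(chrom = annotation$chrom, .start = annotation$start,
                     .end = annotation$end, symbol = annotation$symbol,
                     stringsAsFactors = FALSE)
  res <- nearest_feature(as.character(chrom), as.integer(pos), feat)
  if (anyNA(res) && on_unmapped == "error") {
    i <- which(is.na(res))[1]
    stop("no annotated gene on chromosome ", chrom[i],
         " (position ", pos[i], ")")
  }
  res
}

#' Fisher's combined p-value
#'
#' Combines independent p-values for the same phenotype-SNP association
#' reported by different studies. For k >= 2 values the statistic
#' X^2 = -2 * sum(ln p_i) is referred to the upper tail of a chi-square
#' distribution with 2k degrees of freedom; a single p-value is returned
#' unchanged.
#'
#' @param pvalues numeric vector of p-values, each in (0, 1].
#' @return Combined p-value in (0, 1].
#' @examples
#' fisher_meta_p(c(0.05, 0.05))
#' @export
fisher_meta_p <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (length(p) == 0) stop("at least one p-value is required")
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  if (length(p) == 1) return(p)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Build weighted disease-gene edges from association records
#'
#' Association records are mapped to their nearest gene, replicated reports
#' of the same phenotype-SNP pair are combined with [fisher_meta_p()], and
#' the edge weight for each (disease, gene) pair is `-log10` of the smallest
#' combined p-value across that gene's SNPs — the most significantly
#' associated SNP defines the gene-trait edge. Edge provenance is the union
#' of the PubMed ids of all contributing records. Records on chromosomes
#' without annotation are skipped with a warning; p-values of 0 are clamped
#' to 1e-300 so weights stay finite.
#'
#' @param records association data frame (see [read_association_table()]).
#' @param annotation gene annotation table.
#' @return Edge data frame with `source` = disease, `target` = gene,
#'   `type = "disease_gene"`; orientation is canonicalized when the edges
#'   enter a [hetero_network].
#' @export
build_disease_gene_edges <- function(records, annotation) {
  if (nrow(records) == 0) return(empty_edges())
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  bad <- !is.finite(records$pvalue) | records$pvalue > 1
  if (any(bad)) stop("p-values must be numeric <= 1")
  zero <- records$pvalue <= 0
  if (any(zero)) {
    warning(sum(zero), " p-value(s) <= 0 clamped to 1e-300", call. = FALSE)
    records$pvalue[zero] <- 1e-300
  }
  gene <- map_snp_to_gene(records$chrom, records$pos, annotation,
                          on_unmapped = "na")
  if (anyNA(gene)) {
    warning(sum(is.na(gene)),
            " association record(s) skipped: no gene on their chromosome",
            call. = FALSE)
    records <- records[!is.na(gene), , drop = FALSE]
    gene <- gene[!is.na(gene)]
  }
  if (nrow(records) == 0) return(empty_edges())

  ## stage 1: Fisher combination across studies of the same phenotype-SNP pair
  snp_key <- paste(records$phenotype, records$snp_id, gene, sep = "\r")
  meta <- vapply(split(records$pvalue, snp_key), fisher_meta_p, numeric(1))
  meta <- pmax(meta, 1e-300)

  ## stage 2: best SNP per (disease, gene) defines the edge weight
  uniq <- !duplicated(snp_key)
  pair_key <- paste(records$phenotype, gene, sep = "\r")[uniq]
  best <- vapply(split(meta[match(snp_key[uniq], names(meta))], pair_key),
                 min, numeric(1))

  pm_by_pair <- vapply(
    split(records$pubmed, paste(records$phenotype, gene, sep = "\r")),
    function(v) join_pubmed(unlist(split_pubmed(v))), character(1))

  parts <- strsplit(names(best), "\r", fixed = TRUE)
  data.frame(
    source = vapply(parts, `[`, character(1), 1),
    target = vapply(parts, `[`, character(1), 2),
    type = "disease_gene",
    weight = -log10(best),
    directed = FALSE,
    pubmed = unname(pm_by_pair[names(best)]),
    stringsAsFactors = FALSE)
}

#' Threshold-filter disease-gene edges
#'
#' Retains exactly the disease-gene edges whose weight (`-log10 p`) is at
#' least `tau`, i.e. p <= 10^-tau with an inclusive boundary. Edges of every
#' other class pass through untouched. Filtering is monotone: raising `tau`
#' can only shrink the retained set.
#'
#' @param edges edge data frame or [hetero_network].
#' @param tau threshold on the `-log10(p)` scale, >= 0.
#' @return Object of the same kind as `edges` with failing disease-gene
#'   edges removed (network nodes are kept; node pruning is an assembly
#'   policy, see [assemble()]).
#' @export
filter_by_threshold <- function(edges, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau < 0)
    stop("tau must be a single number >= 0")
  if (inherits(edges, "hetero_network")) {
    keep <- edges$edges$type != "disease_gene" | edges$edges$weight >= tau
    return(suppressWarnings(
      hetero_network(edges$nodes, edges$edges[keep, , drop = FALSE])))
  }
  keep <- edges$type != "disease_gene" | edges$weight >= tau
  edges[keep, , drop = FALSE]
}

#' Derive directed TF-to-gene edges from binding sites
#'
#' A binding site induces a directed `protein_dna` edge from its
#' transcription factor to a target gene when (i) its confidence score is
#' strictly greater than `z_min` and (ii) it lies within `window` bp
#' (inclusive) of the nearest transcriptional start site on the same
#' chromosome. Nearest-TSS ties are broken toward the lexicographically
#' smaller gene symbol. A TF whose nearest TSS is its own gene yields a
#' self-edge, which is kept (autoregulation) and flagged in the log.
#'
#' @param sites TFBS data frame (see [read_tfbs_table()]).
#' @param annotation gene annotation table.
#' @param z_min confidence cutoff, strict (default 4.0).
#' @param window promoter window in bp, inclusive (default 5000).
#' @return Edge data frame of deduplicated directed `protein_dna` edges with
#'   weight 1.
#' @export
derive_tfbs_edges <- function(sites, annotation, z_min = 4, window = 5000) {
  annotation <- validate_annotation(annotation)
  if (nrow(sites) == 0) return(empty_edges())
  keep <- sites$zscore > z_min
  sites <- sites[keep, , drop = FALSE]
  n_z_dropped <- sum(!keep)
  if (nrow(sites) == 0) {
    message("derive_tfbs_edges: ", n_z_dropped, " site(s) below score cutoff")
    return(empty_edges())
  }
  tss_feat <- data.frame(chrom = annotation$chrom, .start = annotation$tss,
                         .end = annotation$tss, symbol = annotation$symbol,
                         stringsAsFactors = FALSE)
  target <- nearest_feature(as.character(sites$chrom), as.integer(sites$pos),
                            tss_feat)
  tss <- annotation$tss[match(target, annotation$symbol)]
  in_window <- !is.na(target) & abs(sites$pos - tss) <= window
  message("derive_tfbs_edges: ", n_z_dropped, " site(s) below score cutoff, ",
          sum(!in_window), " outside the promoter window")
  sites <- sites[in_window, , drop = FALSE]
  target <- target[in_window]
  if (nrow(sites) == 0) return(empty_edges())
  edges <- data.frame(source = sites$tf_symbol, target = target,
                      type = "protein_dna", weight = 1, directed = TRUE,
                      pubmed = "", stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edge_key(edges)), , drop = FALSE]
  self <- edges$source == edges$target
  if (any(self))
    message("derive_tfbs_edges: ", sum(self),
            " autoregulatory self-edge(s) kept: ",
            paste(edges$source[self], collapse = ", "))
  rownames(edges) <- NULL
  edges
}

## Coerce a PPI/TFBS universe (edge df or network) to its gene-gene edges.
gene_layer_edges <- function(universe) {
  edges <- if (inherits(universe, "hetero_network")) universe$edges else
    as_edge_df(universe)
  edges[edges$type %in% c("protein_protein", "protein_dna"), , drop = FALSE]
}

#' Expand a network by degrees of separation in the gene-gene layer
#'
#' Adds interaction context around the directly associated genes. With
#' `ds = 0` only universe edges whose both endpoints are already present are
#' added (no new nodes). With `ds = k` (1 or 2), every gene within graph
#' distance k of a directly associated gene — measured over the combined
#' protein-protein and protein-DNA layer with directions ignored — joins the
#' network, together with all universe edges among the enlarged gene set.
#'
#' @param net a [hetero_network] containing the directly associated genes.
#' @param universe the full gene-gene interaction layer: an edge data frame
#'   or network holding `protein_protein` / `protein_dna` edges.
#' @param ds 0, 1 or 2.
#' @return The expanded [hetero_network].
#' @export
expand_neighborhood <- function(net, universe, ds) {
  stopifnot(inherits(net, "hetero_network"))
  if (!ds %in% c(0L, 1L, 2L)) stop("ds must be 0, 1 or 2")
  uedges <- gene_layer_edges(universe)
  if (nrow(uedges) == 0) return(net)
  assoc <- net$nodes$id[net$nodes$type == "gene"]
  if (length(assoc) == 0) return(net)

  if (ds == 0) {
    keep <- uedges$source %in% assoc & uedges$target %in% assoc
    return(add_to_network(net, edges = uedges[keep, , drop = FALSE]))
  }

  g <- igraph::graph_from_data_frame(
    unique(uedges[, c("source", "target")]), directed = FALSE)
  present <- intersect(assoc, igraph::V(g)$name)
  reached <- if (length(present)) {
    unique(unlist(lapply(
      igraph::ego(g, order = ds, nodes = present, mode = "all"),
      names)))
  } else character()
  gene_set <- union(assoc, reached)
  keep <- uedges$source %in% gene_set & uedges$target %in% gene_set
  new_nodes <- node_df(setdiff(gene_set, net$nodes$id), "gene")
  add_to_network(net, nodes = new_nodes,
                 edges = uedges[keep, , drop = FALSE])
}

#' Assemble the five-layer complex-trait network
#'
#' Runs the full construction pipeline: map SNPs to nearest genes, combine
#' replicated phenotype-SNP reports (Fisher), weight edges by `-log10` of
#' the best combined p-value per gene, filter at the significance threshold,
#' attach the requested interaction layers, and expand the gene-gene
#' neighbourhood by `ds`. Tissue and drug edges are attached only around the
#' retained disease-gene core: disease-tissue edges for retained diseases
#' (introducing their tissues), tissue-gene and drug-gene edges only for
#' genes already present in the network.
#'
#' @param records association records (see [read_association_table()]).
#' @param annotation gene annotation table.
#' @param sites TFBS records, required when `"tfbs"` is in `config$layers`.
#' @param ppi_edges protein-protein edge data frame (`source`, `target`,
#'   optional `pubmed`), required when `"ppi"` is in `config$layers`.
#' @param tissue_edges edge data frame with rows of type `disease_tissue`
#'   and/or `tissue_gene`.
#' @param drug_edges edge data frame with rows of type `drug_gene`.
#' @param config an [assembly_config()].
#' @return A [hetero_network].
#' @export
assemble <- function(records, annotation, sites = NULL, ppi_edges = NULL,
                     tissue_edges = NULL, drug_edges = NULL,
                     config = assembly_config()) {
  stopifnot(inherits(config, "assembly_config"))
  annotation <- validate_annotation(annotation)

  dg <- build_disease_gene_edges(records, annotation)
  dgf <- filter_by_threshold(dg, config$threshold_tau)
  message("assemble: ", nrow(dgf), "/", nrow(dg),
          " disease-gene edges pass tau = ", config$threshold_tau)

  diseases <- if (config$keep_isolated_diseases) unique(dg$source)
              else unique(dgf$source)
  genes <- unique(dgf$target)
  nodes <- rbind(node_df(diseases, "disease"), node_df(genes, "gene"))
  net <- suppressWarnings(hetero_network(nodes, dgf))

  universe <- empty_edges()
  if ("ppi" %in% config$layers) {
    if (is.null(ppi_edges)) stop("layer 'ppi' requested but ppi_edges is NULL")
    ppi <- as.data.frame(ppi_edges, stringsAsFactors = FALSE)
    ppi$type <- "protein_protein"
    universe <- rbind(universe, canonicalize_edges(ppi))
  }
  if ("tfbs" %in% config$layers) {
    if (is.null(sites)) stop("layer 'tfbs' requested but sites is NULL")
    universe <- rbind(universe,
                      derive_tfbs_edges(sites, annotation,
                                        z_min = config$z_min,
                                        window = config$promoter_window))
  }
  universe <- universe[!duplicated(edge_key(universe)), , drop = FALSE]
  if (nrow(universe)) {
    net <- expand_neighborhood(net, universe, config$ds)
    message("assemble: gene-gene layer attached at ds = ", config$ds, " (",
            sum(net$edges$type %in% c("protein_protein", "protein_dna")),
            " edges)")
  }

  if ("tissue" %in% config$layers && !is.null(tissue_edges)) {
    te <- as_edge_df(tissue_edges)
    dt <- te[te$type == "disease_tissue", , drop = FALSE]
    dt <- dt[dt$source %in% net$nodes$id | dt$target %in% net$nodes$id, ,
             drop = FALSE]
    tissues <- unique(c(dt$source, dt$target))
    tissues <- setdiff(tissues, net$nodes$id)
    net <- add_to_network(
      net, nodes = node_df(tissues, "tissue"), edges = dt)
    tg <- te[te$type == "tissue_gene", , drop = FALSE]
    tg <- tg[tg$source %in% net$nodes$id & tg$target %in% net$nodes$id, ,
             drop = FALSE]
    net <- add_to_network(net, edges = tg)
    message("assemble: tissue layer attached (", nrow(dt), " disease-tissue, ",
            nrow(tg), " tissue-gene edges)")
  }

  if ("drug" %in% config$layers && !is.null(drug_edges)) {
    de <- as_edge_df(drug_edges)
    de <- de[de$type == "drug_gene", , drop = FALSE]
    gene_ids <- net$nodes$id[net$nodes$type == "gene"]
    de <- de[de$source %in% gene_ids | de$target %in% gene_ids, , drop = FALSE]
    drugs <- setdiff(unique(c(de$source, de$target)), net$nodes$id)
    net <- add_to_network(
      net, nodes = node_df(drugs, "drug"), edges = de)
    message("assemble: drug layer attached (", nrow(de), " drug-gene edges)")
  }

  net
}
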