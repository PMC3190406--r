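#' Project a heterogeneous network onto one node type
#'
#' Replaces indirect connections through an intermediate node class by
#' direct similarity edges: two nodes of `project_type` are linked iff they
#' share at least one `via_type` neighbour over `via_edge_type` edges, and
#' the edge weight is the number of shared neighbours (e.g. diseases
#' connected by the number of genes they share). Edge weights on the
#' bipartite layer are ignored — only presence/absence counts. A
#' `normalized_weight` in [0, 1] (weight divided by the maximum weight) is
#' provided for colour mapping. Optionally the Jaccard index of the two
#' neighbour sets can be reported instead of the raw count.
#'
#' @param net a [hetero_network].
#' @param project_type node type to keep (e.g. `"disease"`).
#' @param via_type intermediate node type (e.g. `"gene"`); must differ from
#'   `project_type`.
#' @param via_edge_type edge class connecting the two types (e.g.
#'   `"disease_gene"`).
#' @param jaccard if `TRUE`, weight is |intersection| / |union| instead of
#'   the shared-neighbour count (default `FALSE`).
#' @return An object of class `similarity_network`: list with `node_type`,
#'   `nodes` (all `project_type` ids) and `edges`
#'   (`u`, `v`, `weight`, `normalized_weight`; `u < v` lexicographically).
#'   Pairs sharing no neighbour get no edge; with no edges at all the result
#'   is empty and a warning is raised.
#' @examples
#' net <- hetero_network(
#'   nodes = data.frame(id = c("D1", "D2", "A", "B", "C"),
#'                      type = c("disease", "disease", "gene", "gene", "gene")),
#'   edges = data.frame(source = c("D1", "D1", "D2", "D2"),
#'                      target = c("A", "B", "B", "C"),
#'                      type = "disease_gene", weight = 8)
#' )
#' project_similarity(net, "disease", "gene", "disease_gene")$edges
#' @export
project_similarity <- function(net, project_type, via_type,
                               via_edge_type = NULL, jaccard = FALSE) {
  stopifnot(inherits(net, "hetero_network"))
  if (!project_type %in% .NODE_TYPES) stop("unknown node type: ", project_type)
  if (!via_type %in% .NODE_TYPES) stop("unknown node type: ", via_type)
  if (project_type == via_type)
    stop("project_type and via_type must differ")
  if (is.null(via_edge_type)) {
    info <- .EDGE_TYPES
    hit <- (info$end1 == project_type & info$end2 == via_type) |
           (info$end2 == project_type & info$end1 == via_type)
    if (sum(hit) != 1)
      stop("cannot infer via_edge_type between ", project_type, " and ",
           via_type)
    via_edge_type <- info$type[hit]
  }
  proj_nodes <- sort(net$nodes$id[net$nodes$type == project_type])
  via_nodes <- net$nodes$id[net$nodes$type == via_type]

  e <- net$edges[net$edges$type == via_edge_type, , drop = FALSE]
  res <- structure(list(node_type = project_type, via_type = via_type,
                        nodes = proj_nodes,
                        edges = data.frame(u = character(), v = character(),
                                           weight = numeric(),
                                           normalized_weight = numeric(),
                                           stringsAsFactors = FALSE)),
                   class = "similarity_network")
  if (nrow(e) == 0) {
    warning("no edges of type ", via_edge_type, "; empty similarity network",
            call. = FALSE)
    return(res)
  }
  ## orient each bipartite edge as (projected, via)
  src_is_proj <- e$source %in% proj_nodes
  p <- ifelse(src_is_proj, e$source, e$target)
  v <- ifelse(src_is_proj, e$target, e$source)
  keep <- p %in% proj_nodes & v %in% via_nodes
  p <- p[keep]; v <- v[keep]
  if (!length(p)) {
    warning("no usable bipartite edges; empty similarity network", call. = FALSE)
    return(res)
  }
  ## sparse incidence B (projected x via); shared counts = B B^T
  pi <- factor(p, levels = proj_nodes)
  vi <- factor(v, levels = sort(unique(v)))
  B <- Matrix::sparseMatrix(i = as.integer(pi), j = as.integer(vi), x = 1,
                            dims = c(length(proj_nodes), nlevels(vi)),
                            dimnames = list(proj_nodes, levels(vi)))
  B@x[] <- 1  # count each via-node at most once per pair
  S <- Matrix::tcrossprod(B)
  S <- methods::as(Matrix::triu(S, k = 1), "TsparseMatrix")
  if (length(S@x) == 0) return(res)
  w <- S@x
  u_id <- proj_nodes[S@i + 1L]
  v_id <- proj_nodes[S@j + 1L]
  if (jaccard) {
    deg <- Matrix::rowSums(B)
    w <- w / (deg[S@i + 1L] + deg[S@j + 1L] - w)
  }
  ord <- order(u_id, v_id)
  edges <- data.frame(u = u_id[ord], v = v_id[ord], weight = w[ord],
                      normalized_weight = w[ord] / max(w),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  res$edges <- edges
  res
}

#' @export
print.similarity_network <- function(x, ...) {
  cat("similarity_network over", x$node_type, "nodes (via ", x$via_type,
      "): ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Write a similarity network
#'
#' TSV output has columns `u`, `v`, `shared_count`, `normalized_weight`;
#' SIF output uses the relation token `sim`.
#'
#' @param sim a `similarity_network` from [project_similarity()].
#' @param path output file.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path, format = c("tsv", "sif")) {
  stopifnot(inherits(sim, "similarity_network"))
  format <- match.arg(format)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(c("u\tv\tshared_count\tnormalized_weight",
                 if (nrow(sim$edges))
                   paste(sim$edges$u, sim$edges$v, fmt_num(sim$edges$weight),
                         fmt_num(sim$edges$normalized_weight), sep = "\t")),
               con)
  } else {
    isolated <- setdiff(sim$nodes, c(sim$edges$u, sim$edges$v))
    writeLines(c(if (nrow(sim$edges))
                   paste(sim$edges$u, "sim", sim$edges$v, sep = "\t"),
                 isolated), con)
  }
  invisible(path)
}
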