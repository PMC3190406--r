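#' @keywords internal
"_PACKAGE"

## Edge-type registry: endpoint node types, directedness and the SIF token
## used on export. protein_dna is the only directed class (TF -> target).
.EDGE_TYPES <- data.frame(
  type     = c("disease_gene", "protein_protein", "protein_dna",
               "disease_tissue", "tissue_gene", "drug_gene"),
  end1     = c("disease", "gene", "gene", "disease", "tissue", "drug"),
  end2     = c("gene", "gene", "gene", "tissue", "gene", "gene"),
  directed = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
  sif      = c("dg", "pp", "pd", "dt", "tg", "drg"),
  stringsAsFactors = FALSE
)

.NODE_TYPES <- c("gene", "disease", "tissue", "drug")

edge_type_info <- function(type) {
  i <- match(type, .EDGE_TYPES$type)
  if (anyNA(i)) stop("unknown edge type: ", paste(type[is.na(i)], collapse = ", "))
  .EDGE_TYPES[i, , drop = FALSE]
}

#' Empty node / edge tables
#'
#' Zero-row data frames with the canonical column layout used throughout the
#' package. Nodes carry `(id, type, label)`, edges carry
#' `(source, target, type, weight, directed, pubmed)` where `pubmed` is a
#' semicolon-delimited string of PubMed identifiers (empty string for none).
#'
#' @return A zero-row `data.frame`.
#' @export
empty_nodes <- function() {
  data.frame(id = character(), type = character(), label = character(),
             stringsAsFactors = FALSE)
}

#' @rdname empty_nodes
#' @export
empty_edges <- function() {
  data.frame(source = character(), target = character(), type = character(),
             weight = numeric(), directed = logical(), pubmed = character(),
             stringsAsFactors = FALSE)
}

## length-0-safe node table builder
node_df <- function(ids, type) {
  data.frame(id = as.character(ids), type = rep(type, length(ids)),
             stringsAsFactors = FALSE)
}

as_node_df <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (nrow(nodes) == 0) return(empty_nodes())
  if (is.null(nodes$label)) nodes$label <- nodes$id
  nodes <- nodes[, c("id", "type", "label")]
  nodes$id <- as.character(nodes$id)
  nodes$type <- as.character(nodes$type)
  nodes$label <- as.character(nodes$label)
  rownames(nodes) <- NULL
  nodes
}

as_edge_df <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0) return(empty_edges())
  info <- edge_type_info(as.character(edges$type))
  if (is.null(edges$weight)) edges$weight <- 1
  if (is.null(edges$directed)) edges$directed <- info$directed
  if (is.null(edges$pubmed)) edges$pubmed <- ""
  edges <- edges[, c("source", "target", "type", "weight", "directed", "pubmed")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$type <- as.character(edges$type)
  edges$weight <- as.numeric(edges$weight)
  edges$directed <- as.logical(edges$directed)
  edges$pubmed <- as.character(edges$pubmed)
  edges$pubmed[is.na(edges$pubmed)] <- ""
  rownames(edges) <- NULL
  edges
}

## Undirected edges are stored with endpoints in lexicographic order so that
## duplicate detection is independent of input orientation.
canonicalize_edges <- function(edges) {
  edges <- as_edge_df(edges)
  if (nrow(edges) == 0) return(edges)
  swap <- !edges$directed & edges$source > edges$target
  if (any(swap)) {
    tmp <- edges$source[swap]
    edges$source[swap] <- edges$target[swap]
    edges$target[swap] <- tmp
  }
  edges
}

edge_key <- function(edges) {
  paste(edges$source, edges$target, edges$type, sep = "\r")
}

#' Construct a heterogeneous complex-trait network
#'
#' A `hetero_network` is a typed multi-partite graph with four node classes
#' (gene, disease, tissue, drug) and six edge classes (`disease_gene`,
#' `protein_protein`, `protein_dna`, `disease_tissue`, `tissue_gene`,
#' `drug_gene`). Genes, SNPs and proteins share the single `gene` node class:
#' SNPs are resolved to their nearest gene during assembly, and gene products
#' carry the interaction layers. Disease-gene edges are weighted by
#' `-log10` of the association p-value; all other classes default to
#' weight 1. Only `protein_dna` edges (TF to target gene) are directed.
#'
#' Undirected edges are canonicalized with endpoints in lexicographic order.
#' The constructor validates referential integrity (every edge endpoint must
#' exist in `nodes`), endpoint-type consistency per edge class, non-negative
#' weights, and rejects duplicate `(source, target, type)` triples.
#'
#' @param nodes data frame with columns `id`, `type`, `label` (label optional,
#'   defaults to `id`).
#' @param edges data frame with columns `source`, `target`, `type` and
#'   optionally `weight`, `directed`, `pubmed`.
#' @return An object of class `hetero_network` with elements `nodes`, `edges`
#'   and `n` (node count).
#' @examples
#' net <- hetero_network(
#'   nodes = data.frame(id = c("MS", "HLA-DRB1"), type = c("disease", "gene")),
#'   edges = data.frame(source = "MS", target = "HLA-DRB1",
#'                      type = "disease_gene", weight = 8)
#' )
#' net
#' @export
hetero_network <- function(nodes = empty_nodes(), edges = empty_edges()) {
  nodes <- as_node_df(nodes)
  edges <- canonicalize_edges(edges)
  net <- structure(list(nodes = nodes, edges = edges, n = nrow(nodes)),
                   class = "hetero_network")
  validate_network(net)
  net
}

#' Validate a heterogeneous network
#'
#' Checks every structural invariant of the [hetero_network] container:
#' unique node ids, known node and edge types, edge endpoints present in the
#' node table, endpoint node types consistent with the edge class,
#' directedness fixed by edge class (only `protein_dna` is directed),
#' non-negative weights, and no duplicate `(source, target, type)` triples.
#' Self-interactions are tolerated for `protein_protein` (some PPI snapshots
#' contain them) and for `protein_dna` (a TF can bind its own promoter); both
#' are reported with a warning.
#'
#' @param net a `hetero_network`.
#' @return `net`, invisibly; stops on the first violated invariant.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "hetero_network"))
  nodes <- net$nodes
  edges <- net$edges
  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  bad <- !nodes$type %in% .NODE_TYPES
  if (any(bad))
    stop("unknown node type(s): ", paste(unique(nodes$type[bad]), collapse = ", "))
  if (net$n != nrow(nodes)) stop("node count field out of sync")
  if (nrow(edges) == 0) return(invisible(net))

  info <- edge_type_info(edges$type)
  missing_ep <- !(edges$source %in% nodes$id) | !(edges$target %in% nodes$id)
  if (any(missing_ep)) {
    i <- which(missing_ep)[1]
    stop("referential integrity: edge ", edges$source[i], " -> ",
         edges$target[i], " (", edges$type[i], ") references an absent node")
  }
  ntype <- nodes$type[match(edges$source, nodes$id)]
  ttype <- nodes$type[match(edges$target, nodes$id)]
  ok <- (ntype == info$end1 & ttype == info$end2) |
        (ntype == info$end2 & ttype == info$end1)
  if (any(!ok)) {
    i <- which(!ok)[1]
    stop("edge type ", edges$type[i], " cannot link a ", ntype[i],
         " node to a ", ttype[i], " node (", edges$source[i], " -> ",
         edges$target[i], ")")
  }
  if (any(edges$directed != info$directed)) {
    i <- which(edges$directed != info$directed)[1]
    stop("edge class ", edges$type[i], " must be ",
         if (info$directed[i]) "directed" else "undirected")
  }
  if (any(!is.finite(edges$weight) | edges$weight < 0))
    stop("edge weights must be finite and >= 0")
  if (anyDuplicated(edge_key(edges))) {
    k <- edge_key(edges)
    i <- which(duplicated(k))[1]
    stop("duplicate edge: ", edges$source[i], " -> ", edges$target[i],
         " (", edges$type[i], ")")
  }
  self <- edges$source == edges$target
  if (any(self)) {
    bad_self <- self & !edges$type %in% c("protein_protein", "protein_dna")
    if (any(bad_self)) {
      i <- which(bad_self)[1]
      stop("self-edge not permitted for edge class ", edges$type[i])
    }
    warning(sum(self), " self-interaction(s) present (",
            paste(unique(edges$type[self]), collapse = ", "), ")",
            call. = FALSE)
  }
  invisible(net)
}

#' @export
print.hetero_network <- function(x, ...) {
  cat("hetero_network:", x$n, "nodes,", nrow(x$edges), "edges\n")
  if (x$n > 0) {
    nt <- table(x$nodes$type)
    cat("  nodes:", paste(names(nt), nt, sep = "=", collapse = ", "), "\n")
  }
  if (nrow(x$edges) > 0) {
    et <- table(x$edges$type)
    cat("  edges:", paste(names(et), et, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.hetero_network <- function(object, ...) {
  dg <- object$edges[object$edges$type == "disease_gene", , drop = FALSE]
  structure(list(
    n_nodes = object$n,
    n_edges = nrow(object$edges),
    node_types = table(object$nodes$type),
    edge_types = table(object$edges$type),
    disease_gene_weight = if (nrow(dg)) summary(dg$weight) else NULL
  ), class = "summary.hetero_network")
}

#' @export
print.summary.hetero_network <- function(x, ...) {
  cat("Heterogeneous complex-trait network\n")
  cat("  nodes:", x$n_nodes, " edges:", x$n_edges, "\n")
  if (length(x$node_types)) { cat("  node types:\n"); print(x$node_types) }
  if (length(x$edge_types)) { cat("  edge types:\n"); print(x$edge_types) }
  if (!is.null(x$disease_gene_weight)) {
    cat("  disease-gene edge weight (-log10 p):\n")
    print(x$disease_gene_weight)
  }
  invisible(x)
}

#' Induced subnetwork on a node set
#'
#' Returns the network containing exactly the requested nodes and every edge
#' (of any class) with both endpoints in the set. This is the primitive
#' behind the `ds = 0` view: direct associations plus any existing
#' interaction among the retained nodes, nothing else.
#'
#' @param net a `hetero_network`.
#' @param ids character vector of node ids; must all be present in `net`.
#' @return A `hetero_network`.
#' @export
induced_subnetwork <- function(net, ids) {
  stopifnot(inherits(net, "hetero_network"))
  ids <- unique(as.character(ids))
  unknown <- setdiff(ids, net$nodes$id)
  if (length(unknown))
    stop("unknown node id(s): ", paste(unknown, collapse = ", "))
  nodes <- net$nodes[net$nodes$id %in% ids, , drop = FALSE]
  keep <- net$edges$source %in% ids & net$edges$target %in% ids
  suppressWarnings(hetero_network(nodes, net$edges[keep, , drop = FALSE]))
}

## Merge additional nodes/edges into a network, ignoring exact duplicates.
add_to_network <- function(net, nodes = NULL, edges = NULL) {
  all_nodes <- net$nodes
  if (!is.null(nodes) && nrow(nodes) > 0) {
    nodes <- as_node_df(nodes)
    nodes <- nodes[!nodes$id %in% all_nodes$id, , drop = FALSE]
    all_nodes <- rbind(all_nodes, nodes)
  }
  all_edges <- net$edges
  if (!is.null(edges) && nrow(edges) > 0) {
    edges <- canonicalize_edges(edges)
    edges <- edges[!edge_key(edges) %in% edge_key(all_edges), , drop = FALSE]
    edges <- edges[!duplicated(edge_key(edges)), , drop = FALSE]
    all_edges <- rbind(all_edges, edges)
  }
  suppressWarnings(hetero_network(all_nodes, all_edges))
}

## pubmed helpers: a semicolon-joined id string <-> character vector
split_pubmed <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE),
         function(v) v[nzchar(v) & v != "."])
}

join_pubmed <- function(ids) {
  paste(sort(unique(ids[nzchar(ids)])), collapse = ";")
}
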