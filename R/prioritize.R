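#' Propagation parameters
#'
#' Controls the iterative update `p[t+1] = (1 - r) W p[t] + r p0`, where `W`
#' is the normalized adjacency operator of the network, `p0` the restart
#' (prior) vector and `r` the restart ratio. With `r = 1` the walker is
#' trapped at the starting nodes and the scores equal `p0`; small `r` lets
#' the walk reach farther nodes.
#'
#' @param r restart ratio in [0, 1] (default 0.5).
#' @param tol convergence tolerance on the L1 change per iteration
#'   (default 1e-6).
#' @param max_iter iteration cap (default 1000).
#' @param normalization `"column_stochastic"` (`A D^-1`; the random-walk
#'   convention) or `"symmetric"` (`D^-1/2 A D^-1/2`; the network-propagation
#'   convention).
#' @return A list of class `propagation_params`.
#' @export
propagation_params <- function(r = 0.5, tol = 1e-6, max_iter = 1000,
                               normalization = c("column_stochastic",
                                                 "symmetric")) {
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0 || r > 1)
    stop("r must be a single number in [0, 1]")
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(r = r, tol = tol, max_iter = as.integer(max_iter),
                 normalization = match.arg(normalization)),
            class = "propagation_params")
}

## Unweighted undirected adjacency over a chosen edge subset; keeps every
## node of `ids` (isolated nodes get zero rows/columns).
build_adjacency <- function(ids, edges) {
  n <- length(ids)
  if (n == 0) stop("cannot build an adjacency over an empty node set")
  i <- match(edges$source, ids)
  j <- match(edges$target, ids)
  keep <- !is.na(i) & !is.na(j) & i != j  # self-loops carry no walk information
  A <- Matrix::sparseMatrix(i = c(i[keep], j[keep]), j = c(j[keep], i[keep]),
                            x = 1, dims = c(n, n), dimnames = list(ids, ids))
  A@x[] <- 1  # parallel edges (e.g. a pp and a pd edge) collapse to 1
  A
}

gene_layer_adjacency <- function(net) {
  ids <- sort(net$nodes$id[net$nodes$type == "gene"])
  build_adjacency(ids, gene_layer_edges(net))
}

hetero_adjacency <- function(net) {
  ids <- sort(net$nodes$id)
  build_adjacency(ids, net$edges)
}

#' Normalize an adjacency matrix for propagation
#'
#' `column_stochastic` returns `A D^-1` (each nonzero column sums to 1);
#' `symmetric` returns `D^-1/2 A D^-1/2`. Zero-degree nodes keep zero
#' rows/columns; by the update equation their fixed-point score is exactly
#' `r * p0`.
#'
#' @param x a [hetero_network] (its gene-gene layer is used), or a square
#'   (sparse) adjacency matrix with dimnames.
#' @param mode `"column_stochastic"` or `"symmetric"`.
#' @return A sparse normalized operator `W`.
#' @export
normalize_adjacency <- function(x, mode = c("column_stochastic", "symmetric")) {
  mode <- match.arg(mode)
  A <- if (inherits(x, "hetero_network")) gene_layer_adjacency(x) else
    methods::as(x, "CsparseMatrix")
  if (nrow(A) == 0) stop("empty graph")
  deg <- Matrix::colSums(A)
  W <- if (mode == "column_stochastic") {
    inv <- ifelse(deg > 0, 1 / deg, 0)
    A %*% Matrix::Diagonal(x = inv)
  } else {
    inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
    D <- Matrix::Diagonal(x = inv_sqrt)
    D %*% A %*% D
  }
  dimnames(W) <- dimnames(A)
  W
}

## Core iteration shared by both prioritizers.
propagate <- function(W, p0, params) {
  p <- p0
  iters <- 0L
  converged <- FALSE
  while (iters < params$max_iter) {
    p_new <- as.numeric((1 - params$r) * (W %*% p) + params$r * p0)
    iters <- iters + 1L
    if (sum(abs(p_new - p)) < params$tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
  }
  if (!converged)
    warning("propagation did not converge in ", params$max_iter,
            " iterations", call. = FALSE)
  names(p) <- names(p0)
  list(p = p, iterations = iters, converged = converged)
}

#' Rank candidate genes by propagation score
#'
#' Orders non-seed genes by descending score; exact ties are broken by
#' ascending node id so rankings are deterministic. Ranks are dense
#' (1..m).
#'
#' @param scores named numeric vector of node scores.
#' @param seed_set character vector of seed ("associated") genes, excluded
#'   from the ranking.
#' @return data frame with columns `rank`, `gene`, `score`.
#' @export
rank_candidates <- function(scores, seed_set = character()) {
  cand <- scores[!names(scores) %in% seed_set]
  ord <- order(-cand, names(cand))
  data.frame(rank = seq_along(cand), gene = names(cand)[ord],
             score = unname(cand)[ord], stringsAsFactors = FALSE)
}

#' Genes associated with a disease above a threshold
#'
#' The seed ("associated") set for prioritization: genes whose disease-gene
#' edge weight (`-log10 p`) reaches `tau`. With `disease = NULL` genes
#' associated with any disease qualify.
#'
#' @param net a [hetero_network].
#' @param tau threshold on the `-log10(p)` scale.
#' @param disease optional disease id restricting the edges considered.
#' @return Character vector of gene ids.
#' @export
associated_genes <- function(net, tau, disease = NULL) {
  e <- net$edges[net$edges$type == "disease_gene" & net$edges$weight >= tau, ,
                 drop = FALSE]
  if (!is.null(disease)) {
    if (!disease %in% net$nodes$id) stop("unknown disease: ", disease)
    e <- e[e$source == disease | e$target == disease, , drop = FALSE]
  }
  is_gene <- net$nodes$type[match(c(e$source, e$target), net$nodes$id)] == "gene"
  sort(unique(c(e$source, e$target)[is_gene]))
}

new_propagation_result <- function(method, scores, seed_set, iterations,
                                   converged, params, extra = list()) {
  structure(c(list(method = method, scores = scores, seed_set = seed_set,
                   candidate_ranking = rank_candidates(scores, seed_set),
                   iterations_used = iterations, converged = converged,
                   params = params), extra),
            class = "propagation_result")
}

#' Random walk with restarts on the gene-gene layer
#'
#' Prioritizes candidate genes by their closeness to the confirmed
#' ("associated") genes in the protein interaction network. The walker
#' starts from the seeds with equal probability (`p0` uniform over seeds)
#' and iterates `p[t+1] = (1 - r) W p[t] + r p0` on the combined
#' protein-protein / protein-DNA layer (directions ignored, edges
#' unweighted) until the L1 change drops below `tol`. Genes are classified
#' as "associated" (the seeds) or "candidate"; candidates are ranked by
#' their converged score.
#'
#' @param net a [hetero_network] whose gene-gene layer carries the walk.
#' @param seeds character vector of seed genes; if `NULL`, derived as
#'   [associated_genes()] of `disease` at threshold `tau`.
#' @param params a [propagation_params()]; the default normalization for
#'   RWR is `column_stochastic`.
#' @param disease,tau used only when `seeds` is `NULL`.
#' @return A `propagation_result`: named `scores` over all gene nodes,
#'   `seed_set`, `candidate_ranking` (seeds excluded), `iterations_used`,
#'   `converged`.
#' @seealso [prince_extended()] for propagation over the full heterogeneous
#'   network with a disease-similarity prior.
#' @export
rwr <- function(net, seeds = NULL, params = propagation_params(),
                disease = NULL, tau = NULL) {
  stopifnot(inherits(net, "hetero_network"))
  if (is.null(seeds)) {
    if (is.null(disease) || is.null(tau))
      stop("provide either seeds or (disease, tau)")
    seeds <- associated_genes(net, tau, disease)
  }
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) stop("seed set is empty")
  A <- gene_layer_adjacency(net)
  absent <- setdiff(seeds, rownames(A))
  if (length(absent))
    stop("seed gene(s) not in the network: ", paste(absent, collapse = ", "))
  W <- normalize_adjacency(A, params$normalization)
  p0 <- stats::setNames(numeric(nrow(A)), rownames(A))
  p0[seeds] <- 1 / length(seeds)
  fit <- propagate(W, p0, params)
  new_propagation_result("rwr", fit$p, seeds, fit$iterations, fit$converged,
                         params)
}

#' GWAS-derived disease similarity
#'
#' Similarity between diseases computed from their thresholded gene
#' associations: `sim(d1, d2) = |shared genes| / min(|genes(d1)|,
#' |genes(d2)|)`, which lies in [0, 1] and equals 1 for identical gene
#' sets; `sim(d, d) = 1` by convention. Shared counts come from the
#' bipartite projection ([project_similarity()]). Diseases with no retained
#' gene have similarity 0 to every other disease.
#'
#' @param net a [hetero_network] with disease-gene edges.
#' @param tau association threshold on the `-log10(p)` scale.
#' @return A symmetric similarity matrix over the diseases in `net`.
#' @export
build_disease_similarity <- function(net, tau) {
  stopifnot(inherits(net, "hetero_network"))
  netf <- filter_by_threshold(net, tau)
  diseases <- sort(net$nodes$id[net$nodes$type == "disease"])
  sim <- matrix(0, length(diseases), length(diseases),
                dimnames = list(diseases, diseases))
  if (length(diseases) == 0) return(sim)
  diag(sim) <- 1
  dg <- netf$edges[netf$edges$type == "disease_gene", , drop = FALSE]
  if (nrow(dg) == 0) return(sim)
  is_disease_src <- dg$source %in% diseases &
    net$nodes$type[match(dg$source, net$nodes$id)] == "disease"
  d_id <- ifelse(is_disease_src, dg$source, dg$target)
  sizes <- table(factor(d_id, levels = diseases))
  proj <- suppressWarnings(
    project_similarity(netf, "disease", "gene", "disease_gene"))
  if (nrow(proj$edges)) {
    shared <- proj$edges
    mins <- pmin(as.numeric(sizes[shared$u]), as.numeric(sizes[shared$v]))
    val <- shared$weight / mins
    sim[cbind(shared$u, shared$v)] <- val
    sim[cbind(shared$v, shared$u)] <- val
  }
  sim
}

#' Logistic prior transfer function
#'
#' Maps a disease similarity in [0, 1] to a prior gene weight:
#' `L(x) = 1 / (1 + exp(c * x + d))`. The defaults `c = -15`,
#' `d = log(9999)` pin the extremes at `L(0) = 1e-4` and `L(1) ~ 0.997`, so
#' genes of unrelated diseases contribute almost nothing while genes of the
#' query disease itself carry nearly full prior weight.
#'
#' @param x similarity value(s) in [0, 1].
#' @param c,d logistic parameters.
#' @return Prior weight(s) in (0, 1).
#' @export
logistic_prior <- function(x, c = -15, d = log(9999)) {
  1 / (1 + exp(c * x + d))
}

#' PRINCE-style propagation over the full heterogeneous network
#'
#' Network propagation extended to all five edge classes. Instead of an
#' arbitrary disease-similarity matrix, the prior is derived from the GWAS
#' data itself: true associations at the chosen threshold define each
#' disease's gene set, diseases are compared with
#' [build_disease_similarity()], and each gene linked (at threshold) to some
#' disease receives prior `y(g) = max_d L(sim(query, d))` over its diseases,
#' with [logistic_prior()] as the transfer function. The query disease node
#' has prior 1; all other nodes start at 0. The same update
#' `p[t+1] = (1 - r) W p[t] + r p0` is then iterated over the unweighted,
#' undirected heterogeneous adjacency (symmetric normalization by default),
#' and genes are ranked by their converged scores.
#'
#' @param net a [hetero_network]; may contain all five edge classes.
#' @param query_disease disease id to prioritize for.
#' @param tau association threshold defining "true" associations.
#' @param params a [propagation_params()]; `normalization` defaults to
#'   `"symmetric"` for this method.
#' @param c,d parameters of [logistic_prior()].
#' @param prior optional explicit named prior vector over the network's
#'   nodes (missing names are 0), bypassing the disease-similarity
#'   construction; useful for custom priors.
#' @return A `propagation_result` with gene scores only; the seed set is
#'   the query disease's associated genes at `tau`.
#' @export
prince_extended <- function(net, query_disease = NULL, tau = NULL,
                            params = propagation_params(normalization = "symmetric"),
                            c = -15, d = log(9999), prior = NULL) {
  stopifnot(inherits(net, "hetero_network"))
  ids <- sort(net$nodes$id)
  p0 <- stats::setNames(numeric(length(ids)), ids)
  seeds <- character()
  sim_row <- NULL
  walk_net <- net
  if (is.null(prior)) {
    if (is.null(query_disease) || is.null(tau))
      stop("provide either (query_disease, tau) or an explicit prior")
    if (!query_disease %in% net$nodes$id)
      stop("unknown disease: ", query_disease)
    sim <- build_disease_similarity(net, tau)
    sim_row <- sim[query_disease, ]
    netf <- filter_by_threshold(net, tau)
    dg <- netf$edges[netf$edges$type == "disease_gene", , drop = FALSE]
    if (nrow(dg)) {
      src_is_disease <-
        net$nodes$type[match(dg$source, net$nodes$id)] == "disease"
      d_id <- ifelse(src_is_disease, dg$source, dg$target)
      g_id <- ifelse(src_is_disease, dg$target, dg$source)
      lw <- logistic_prior(sim_row[d_id], c = c, d = d)
      y <- vapply(split(lw, g_id), max, numeric(1))
      p0[names(y)] <- y
    }
    p0[query_disease] <- 1
    seeds <- associated_genes(netf, tau, query_disease)
    ## the walk runs over the thresholded network: only "true" associations
    ## (p <= 10^-tau) carry propagation, like every other unweighted layer
    walk_net <- netf
    gene_prior <- p0[net$nodes$id[net$nodes$type == "gene"]]
    if (length(seeds) == 0 &&
        all(gene_prior <= logistic_prior(0, c = c, d = d) + 1e-12))
      warning("query disease has no thresholded associations and no ",
              "similar disease; gene prior is at baseline, scores will be ",
              "near zero", call. = FALSE)
  } else {
    prior <- prior[names(prior) %in% ids]
    p0[names(prior)] <- prior
    seeds <- attr(prior, "seed_set") %||% character()
  }
  A <- hetero_adjacency(walk_net)
  W <- normalize_adjacency(A, params$normalization)
  if (sum(p0) == 0)
    warning("prior is identically zero; scores will be zero", call. = FALSE)
  fit <- propagate(W, p0, params)
  gene_ids <- sort(net$nodes$id[net$nodes$type == "gene"])
  scores <- fit$p[gene_ids]
  new_propagation_result("prince", scores, seeds, fit$iterations,
                         fit$converged, params,
                         extra = list(query_disease = query_disease,
                                      disease_similarity = sim_row,
                                      prior = p0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.propagation_result <- function(x, ...) {
  cat("propagation_result (", x$method, "): ", length(x$scores),
      " genes scored, ", length(x$seed_set), " seeds, ",
      nrow(x$candidate_ranking), " candidates\n", sep = "")
  cat("  r = ", x$params$r, ", normalization = ", x$params$normalization,
      ", ", x$iterations_used, " iterations, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  top <- utils::head(x$candidate_ranking, 5)
  if (nrow(top)) {
    cat("  top candidates:\n")
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.propagation_result <- function(object, ...) {
  structure(list(
    method = object$method,
    params = object$params,
    n_scored = length(object$scores),
    n_seeds = length(object$seed_set),
    n_candidates = nrow(object$candidate_ranking),
    iterations = object$iterations_used,
    converged = object$converged,
    score_summary = summary(object$scores),
    top = utils::head(object$candidate_ranking, 10)
  ), class = "summary.propagation_result")
}

#' @export
print.summary.propagation_result <- function(x, ...) {
  cat("Candidate-gene prioritization (", x$method, ")\n", sep = "")
  cat("  restart ratio r =", x$params$r, " normalization =",
      x$params$normalization, "\n")
  cat("  ", x$n_scored, " genes (", x$n_seeds, " seeds, ", x$n_candidates,
      " candidates); ", x$iterations, " iterations; ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  cat("  score distribution:\n")
  print(x$score_summary)
  cat("  top 10 candidates:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.propagation_result <- function(x, ...) {
  df <- data.frame(gene = names(x$scores), score = unname(x$scores),
                   is_seed = names(x$scores) %in% x$seed_set,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$gene), ]
  rownames(df) <- NULL
  df
}

#' @export
plot.propagation_result <- function(x, n_top = 20, ...) {
  r <- utils::head(x$candidate_ranking, n_top)
  op <- graphics::par(mar = c(5, 7, 3, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(r$score), names.arg = rev(r$gene), horiz = TRUE,
                    las = 1, cex.names = 0.7,
                    xlab = "propagation score",
                    main = paste0("Top candidate genes (", x$method, ")"),
                    ...)
  invisible(x)
}

#' Write a candidate ranking as TSV
#'
#' Columns: `rank`, `gene`, `score`, `is_seed`. Seeds are appended after the
#' ranked candidates with rank `NA` so the full score vector is preserved.
#'
#' @param result a `propagation_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(result, path) {
  stopifnot(inherits(result, "propagation_result"))
  r <- result$candidate_ranking
  seeds <- result$seed_set
  seed_scores <- result$scores[names(result$scores) %in% seeds]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "rank\tgene\tscore\tis_seed",
    if (nrow(r)) paste(r$rank, r$gene, fmt_num(r$score), "false", sep = "\t"),
    if (length(seed_scores))
      paste("NA", names(seed_scores), fmt_num(unname(seed_scores)), "true",
            sep = "\t")), con)
  invisible(path)
}
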