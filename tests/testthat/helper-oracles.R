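# Independent brute-force oracles and small graph builders shared by the
# suite. Each oracle is a direct transcription of the defining rule, kept
# deliberately naive so it cannot share code paths with the implementation.

# Upper tail of the chi-square distribution by numerical integration of the
# closed-form density (independent of pchisq).
chisq_tail_oracle <- function(x, df) {
  if (x <= 0) return(1)
  dens <- function(t) t^(df / 2 - 1) * exp(-t / 2) / (2^(df / 2) * gamma(df / 2))
  stats::integrate(dens, x, Inf, rel.tol = 1e-13, abs.tol = 1e-14,
                   subdivisions = 2000L)$value
}

# Direct linear-system fixed point of p = (1-r) W p + r p0.
fixed_point_oracle <- function(W, p0, r) {
  n <- length(p0)
  sol <- solve(diag(n) - (1 - r) * as.matrix(W), r * p0)
  stats::setNames(as.numeric(sol), names(p0))
}

# Nearest gene by exhaustive minimization of the stated distance
# (0 inside the gene body, else distance to the nearer boundary),
# lexicographic tie-break.
bf_nearest_gene <- function(chrom, pos, ann) {
  cand <- ann[ann$chrom == chrom, , drop = FALSE]
  if (nrow(cand) == 0) return(NA_character_)
  d <- ifelse(pos >= cand$start & pos <= cand$end, 0,
              pmin(abs(pos - cand$start), abs(pos - cand$end)))
  best <- cand$symbol[d == min(d)]
  sort(best)[1]
}

# TFBS edge derivation as a naive (site x gene) double loop.
bf_tfbs_edges <- function(sites, ann, z_min = 4, window = 5000) {
  out <- list()
  for (i in seq_len(nrow(sites))) {
    if (!(sites$zscore[i] > z_min)) next
    cand <- ann[ann$chrom == sites$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    d <- abs(sites$pos[i] - cand$tss)
    best <- cand$symbol[d == min(d)]
    g <- sort(best)[1]
    if (min(d) <= window)
      out[[length(out) + 1L]] <- c(sites$tf_symbol[i], g)
  }
  if (!length(out)) return(character())
  sort(unique(vapply(out, paste, character(1), collapse = "->")))
}

# Breadth-first search truncated at depth k over an undirected edge list.
bf_bfs <- function(edges, start, k) {
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges$source[i]; b <- edges$target[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  frontier <- intersect(start, names(adj))
  seen <- frontier
  depth <- 0
  while (depth < k && length(frontier)) {
    frontier <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- union(seen, frontier)
    depth <- depth + 1
  }
  sort(union(start, seen))
}

# Shared-neighbour projection as a triple loop.
bf_project <- function(proj_nodes, edge_p, edge_v) {
  res <- list()
  pn <- sort(proj_nodes)
  for (i in seq_along(pn)) for (j in seq_along(pn)) {
    if (j <= i) next
    shared <- length(intersect(edge_v[edge_p == pn[i]],
                               edge_v[edge_p == pn[j]]))
    if (shared > 0)
      res[[length(res) + 1L]] <- data.frame(u = pn[i], v = pn[j],
                                            weight = shared,
                                            stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(u = character(), v = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, res)
}

# --- small builders -------------------------------------------------------

gene_nodes <- function(ids) {
  data.frame(id = ids, type = "gene", stringsAsFactors = FALSE)
}

ppi_net <- function(edge_pairs, extra_nodes = character()) {
  ids <- sort(unique(c(unlist(edge_pairs), extra_nodes)))
  edges <- if (length(edge_pairs))
    data.frame(source = vapply(edge_pairs, `[`, character(1), 1),
               target = vapply(edge_pairs, `[`, character(1), 2),
               type = "protein_protein", stringsAsFactors = FALSE)
  else empty_edges()
  hetero_network(gene_nodes(ids), edges)
}

random_ppi_net <- function(n, p = 0.15) {
  ids <- sprintf("g%03d", seq_len(n))
  pairs <- utils::combn(ids, 2)
  hit <- stats::runif(ncol(pairs)) < p
  edges <- data.frame(source = pairs[1, hit], target = pairs[2, hit],
                      stringsAsFactors = FALSE)
  edges$type <- rep("protein_protein", nrow(edges))
  hetero_network(gene_nodes(ids), edges)
}

random_bipartite_net <- function(n_d, n_g, p = 0.2) {
  d_ids <- sprintf("d%03d", seq_len(n_d))
  g_ids <- sprintf("g%03d", seq_len(n_g))
  grid <- expand.grid(source = d_ids, target = g_ids,
                      stringsAsFactors = FALSE)
  hit <- stats::runif(nrow(grid)) < p
  nodes <- rbind(data.frame(id = d_ids, type = "disease",
                            stringsAsFactors = FALSE),
                 gene_nodes(g_ids))
  edges <- grid[hit, , drop = FALSE]
  edges$type <- "disease_gene"
  edges$weight <- 8
  hetero_network(nodes, edges)
}

# A small annotation table on two synthetic chromosomes (10 kb spacing,
# 2 kb gene bodies), matching the generator's layout rules.
toy_annotation <- function(n_per_chrom = 5) {
  idx <- seq_len(n_per_chrom)
  ann <- do.call(rbind, lapply(c("chr1", "chr2"), function(ch) {
    data.frame(symbol = sprintf("%s_G%02d", toupper(ch), idx), chrom = ch,
               start = (idx - 1L) * 10000L + 1L,
               end = (idx - 1L) * 10000L + 2000L,
               strand = rep(c("+", "-"), length.out = n_per_chrom),
               stringsAsFactors = FALSE)
  }))
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  ann
}

# Tiny fixture configuration used where full default scale is not needed.
small_fixture_config <- function(...) {
  fixture_config(n_genes = 80, n_diseases = 4, n_tissues = 4, n_drugs = 5,
                 module_size = 10, n_noise_assoc = 40, n_tf = 4, n_tfbs = 40,
                 ...)
}
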