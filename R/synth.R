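#' Synthetic fixture configuration
#'
#' Parameters of the planted-module generator. The generator emulates the
#' edge-level statistical structure the downstream methods consume: each
#' disease has a planted module of associated genes whose GWAS p-values are
#' drawn from a strong-signal distribution, a held-out subset of each module
#' is emitted with noise-level p-values only (so it can be recovered by
#' propagation but not by thresholding), modules are denser than background
#' in the PPI layer, designated disease pairs share a fraction of their
#' modules, and sub-threshold noise associations are sprinkled over random
#' disease-gene pairs.
#'
#' The default signal support (log-uniform over `[1e-30, 1e-8]`) and noise
#' support (uniform over `[1e-6, 0.05]`) leave a gap around `p = 1e-7`, so a
#' threshold of `tau = 7` separates them exactly.
#'
#' @param n_genes,n_diseases,n_tissues,n_drugs node counts.
#' @param module_size planted associated genes per disease.
#' @param heldout_fraction fraction of each module emitted with noise-level
#'   p-values (rounded up).
#' @param ppi_model `"erdos_renyi"` or `"scale_free"` (Barabasi-Albert plus
#'   the module boost).
#' @param ppi_p background edge probability (Erdos-Renyi).
#' @param ba_m edges per new vertex for the scale-free model.
#' @param within_module_edge_boost multiplier on `ppi_p` for gene pairs
#'   inside the same disease module (>= 1).
#' @param p_signal,p_noise length-2 supports of the signal (log-uniform) and
#'   noise (uniform) p-value distributions.
#' @param n_noise_assoc number of spurious disease-gene association records.
#' @param replication_rate fraction of signal associations reported by two
#'   independent studies (exercises Fisher combination).
#' @param overlap_fraction fraction of the module shared between designated
#'   disease pairs (diseases 1-2, 3-4, ...).
#' @param n_tf,n_tfbs transcription factors and binding-site records.
#' @param rng_seed integer seed; the entire fixture is a deterministic
#'   function of the configuration and this seed.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_genes = 400, n_diseases = 6, n_tissues = 10,
                           n_drugs = 15, module_size = 20,
                           heldout_fraction = 0.25,
                           ppi_model = c("erdos_renyi", "scale_free"),
                           ppi_p = 0.01, ba_m = 2,
                           within_module_edge_boost = 20,
                           p_signal = c(1e-30, 1e-8),
                           p_noise = c(1e-6, 0.05),
                           n_noise_assoc = 200, replication_rate = 0.3,
                           overlap_fraction = 0.2, n_tf = 10, n_tfbs = 200,
                           rng_seed = 42) {
  ppi_model <- match.arg(ppi_model)
  if (module_size > n_genes) stop("module_size cannot exceed n_genes")
  if (within_module_edge_boost < 1)
    stop("within_module_edge_boost must be >= 1")
  counts <- c(n_genes, n_diseases, n_tissues, n_drugs, n_noise_assoc,
              n_tf, n_tfbs)
  if (any(counts < 0)) stop("counts must be >= 0")
  overlap <- round(overlap_fraction * module_size)
  n_pairs <- n_diseases %/% 2
  if (n_pairs * (2 * module_size - overlap) +
      (n_diseases %% 2) * module_size > n_genes)
    stop("modules do not fit in n_genes")
  structure(list(n_genes = n_genes, n_diseases = n_diseases,
                 n_tissues = n_tissues, n_drugs = n_drugs,
                 module_size = module_size,
                 heldout_fraction = heldout_fraction, ppi_model = ppi_model,
                 ppi_p = ppi_p, ba_m = ba_m,
                 within_module_edge_boost = within_module_edge_boost,
                 p_signal = p_signal, p_noise = p_noise,
                 n_noise_assoc = n_noise_assoc,
                 replication_rate = replication_rate,
                 overlap_fraction = overlap_fraction, n_tf = n_tf,
                 n_tfbs = n_tfbs, rng_seed = rng_seed),
            class = "fixture_config")
}

with_fixture_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a complete synthetic five-layer fixture
#'
#' Produces all raw inputs of the assembly pipeline — association records,
#' BED gene annotation, TFBS records, PPI edges, tissue and drug layers —
#' together with the planted ground truth, deterministically from
#' `config$rng_seed`. Gene coordinates are laid out on four synthetic
#' chromosomes at a fixed 10 kb spacing (gene body 2 kb), so nearest-gene
#' distances are unambiguous and hand-checkable; association SNPs are placed
#' inside their gene body.
#'
#' @param config a [fixture_config()].
#' @param dir optional output directory; when given, the fixture is also
#'   written as plain-text files (`associations.tsv`, `genes.bed`,
#'   `tfbs.tsv`, `ppi_edges.tsv`, `tissue_edges.tsv`, `drug_edges.tsv`,
#'   `truth.json`) that parse through the package readers.
#' @return A list with elements `associations`, `annotation`, `sites`,
#'   `ppi_edges`, `tissue_edges`, `drug_edges`, `truth` (planted modules,
#'   held-out subsets and pair overlaps) and `config`.
#' @export
generate_fixture <- function(config = fixture_config(), dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  fx <- with_fixture_seed(config$rng_seed, build_fixture(config))
  if (!is.null(dir)) write_fixture(fx, dir)
  fx
}

build_fixture <- function(config) {
  n <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(n))
  n_chrom <- 4L
  chrom_of <- rep(paste0("chr", seq_len(n_chrom)), length.out = n)
  idx_in_chrom <- stats::ave(seq_len(n), chrom_of, FUN = seq_along)
  start <- (idx_in_chrom - 1L) * 10000L + 1L
  annotation <- data.frame(
    symbol = gene_ids, chrom = chrom_of, start = start, end = start + 1999L,
    strand = rep(c("+", "-"), length.out = n), stringsAsFactors = FALSE)
  annotation <- validate_annotation(annotation)

  disease_ids <- sprintf("D%02d", seq_len(config$n_diseases))
  m <- config$module_size
  o <- round(config$overlap_fraction * m)
  perm <- sample(gene_ids)
  ptr <- 0L
  take <- function(k) {
    out <- perm[ptr + seq_len(k)]
    ptr <<- ptr + k
    out
  }
  modules <- stats::setNames(vector("list", config$n_diseases), disease_ids)
  overlaps <- data.frame(d1 = character(), d2 = character(),
                         shared = integer(), stringsAsFactors = FALSE)
  i <- 1L
  while (i <= config$n_diseases) {
    if (i + 1L <= config$n_diseases) {
      shared <- take(o)
      modules[[i]] <- c(shared, take(m - o))
      modules[[i + 1L]] <- c(shared, take(m - o))
      overlaps <- rbind(overlaps, data.frame(
        d1 = disease_ids[i], d2 = disease_ids[i + 1L], shared = o,
        stringsAsFactors = FALSE))
      i <- i + 2L
    } else {
      modules[[i]] <- take(m)
      i <- i + 1L
    }
  }
  n_held <- ceiling(config$heldout_fraction * m)
  heldout <- lapply(modules, function(g) sort(sample(g, n_held)))
  modules <- lapply(modules, sort)

  ## association records
  rows <- list()
  snp_counter <- 0L
  new_snp <- function() {
    snp_counter <<- snp_counter + 1L
    sprintf("rs%06d", snp_counter)
  }
  draw_signal <- function(k)
    10^stats::runif(k, log10(config$p_signal[1]), log10(config$p_signal[2]))
  draw_noise <- function(k)
    stats::runif(k, config$p_noise[1], config$p_noise[2])
  pubmed_pool <- sprintf("%08d", sample.int(89999999L, 500) + 9999999L)
  for (d in disease_ids) {
    for (g in modules[[d]]) {
      a <- annotation[annotation$symbol == g, ]
      snp <- new_snp()
      pos <- sample(a$start:a$end, 1)
      held <- g %in% heldout[[d]]
      p1 <- if (held) draw_noise(1) else draw_signal(1)
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snp, chrom = a$chrom, pos = pos, phenotype = d, pvalue = p1,
        pubmed = sample(pubmed_pool, 1), stringsAsFactors = FALSE)
      if (!held && stats::runif(1) < config$replication_rate) {
        ## replicated report of the same phenotype-SNP pair (second study)
        rows[[length(rows) + 1L]] <- data.frame(
          snp_id = snp, chrom = a$chrom, pos = pos, phenotype = d,
          pvalue = draw_signal(1), pubmed = sample(pubmed_pool, 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  ## spurious sub-threshold associations on non-planted pairs
  planted_pairs <- unlist(lapply(disease_ids, function(d)
    paste(d, modules[[d]], sep = "\r")))
  n_noise <- config$n_noise_assoc
  if (n_noise > 0) {
    nd <- sample(disease_ids, n_noise, replace = TRUE)
    ng <- sample(gene_ids, n_noise, replace = TRUE)
    ok <- !paste(nd, ng, sep = "\r") %in% planted_pairs
    nd <- nd[ok]; ng <- ng[ok]
    ai <- match(ng, annotation$symbol)
    if (length(nd)) {
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = vapply(seq_along(nd), function(i) new_snp(), character(1)),
        chrom = annotation$chrom[ai],
        pos = annotation$start[ai] +
          sample(0:1999, length(nd), replace = TRUE),
        phenotype = nd, pvalue = draw_noise(length(nd)),
        pubmed = sample(pubmed_pool, length(nd), replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  associations <- do.call(rbind, rows)
  rownames(associations) <- NULL

  ## PPI layer: background model + within-module densification
  ppi_edges <- sample_ppi(config, gene_ids, modules)

  ## TFBS records around gene TSSs
  tf_ids <- sort(sample(gene_ids, config$n_tf))
  if (config$n_tfbs > 0) {
    tg <- sample(seq_len(n), config$n_tfbs, replace = TRUE)
    offset <- sample(-8000:8000, config$n_tfbs, replace = TRUE)
    sites <- data.frame(
      tf_symbol = sample(tf_ids, config$n_tfbs, replace = TRUE),
      chrom = annotation$chrom[tg],
      pos = pmax(1L, annotation$tss[tg] + offset),
      zscore = round(stats::runif(config$n_tfbs, 2.5, 8), 3),
      stringsAsFactors = FALSE)
  } else {
    sites <- data.frame(tf_symbol = character(), chrom = character(),
                        pos = integer(), zscore = numeric(),
                        stringsAsFactors = FALSE)
  }

  ## tissue and drug layers
  tissue_ids <- sprintf("T%02d", seq_len(config$n_tissues))
  dt <- do.call(rbind, lapply(disease_ids, function(d) {
    k <- sample(1:3, 1)
    data.frame(source = d, target = sample(tissue_ids, min(k, length(tissue_ids))),
               type = "disease_tissue", stringsAsFactors = FALSE)
  }))
  tg_edges <- do.call(rbind, lapply(tissue_ids, function(t) {
    data.frame(source = t, target = sample(gene_ids, 15),
               type = "tissue_gene", stringsAsFactors = FALSE)
  }))
  tissue_edges <- as_edge_df(rbind(dt, tg_edges))

  drug_ids <- sprintf("DR%02d", seq_len(config$n_drugs))
  drug_edges <- as_edge_df(do.call(rbind, lapply(drug_ids, function(dr) {
    data.frame(source = dr, target = sample(gene_ids, sample(1:4, 1)),
               type = "drug_gene", stringsAsFactors = FALSE)
  })))

  truth <- list(modules = modules, heldout = heldout, overlaps = overlaps)
  list(associations = associations, annotation = annotation, sites = sites,
       ppi_edges = ppi_edges, tissue_edges = tissue_edges,
       drug_edges = drug_edges, truth = truth, config = config)
}

sample_ppi <- function(config, gene_ids, modules) {
  n <- length(gene_ids)
  pairs <- utils::combn(n, 2)
  prob <- rep(config$ppi_p, ncol(pairs))
  key <- paste(pairs[1, ], pairs[2, ], sep = "\r")
  boosted <- min(1, config$ppi_p * config$within_module_edge_boost)
  for (mod in modules) {
    idx <- sort(match(mod, gene_ids))
    mp <- utils::combn(idx, 2)
    prob[match(paste(mp[1, ], mp[2, ], sep = "\r"), key)] <- boosted
  }
  if (config$ppi_model == "erdos_renyi") {
    hit <- stats::runif(ncol(pairs)) < prob
    src <- pairs[1, hit]; dst <- pairs[2, hit]
  } else {
    g <- igraph::sample_pa(n, m = config$ba_m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    extra <- stats::runif(ncol(pairs)) < (prob - config$ppi_p) /
      (1 - config$ppi_p) * (prob > config$ppi_p)
    src <- c(el[, 1], pairs[1, extra])
    dst <- c(el[, 2], pairs[2, extra])
  }
  edges <- data.frame(source = gene_ids[src], target = gene_ids[dst],
                      type = "protein_protein", stringsAsFactors = FALSE)
  edges <- canonicalize_edges(edges)
  edges[!duplicated(edge_key(edges)), , drop = FALSE]
}

write_fixture <- function(fx, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create fixture directory ", dir)
  a <- fx$associations
  con <- file(file.path(dir, "associations.tsv"), "w", encoding = "UTF-8")
  writeLines(c("snp_id\tchrom\tpos\tphenotype\tpvalue\tpubmed",
               paste(a$snp_id, a$chrom, a$pos, a$phenotype, fmt_num(a$pvalue),
                     a$pubmed, sep = "\t")), con)
  close(con)
  gr <- GenomicRanges::GRanges(
    fx$annotation$chrom,
    IRanges::IRanges(fx$annotation$start, fx$annotation$end),
    strand = fx$annotation$strand)
  gr$name <- fx$annotation$symbol
  gr$score <- 0
  rtracklayer::export(gr, file.path(dir, "genes.bed"), format = "BED")
  s <- fx$sites
  con <- file(file.path(dir, "tfbs.tsv"), "w", encoding = "UTF-8")
  writeLines(c("tf_symbol\tchrom\tpos\tzscore",
               if (nrow(s)) paste(s$tf_symbol, s$chrom, s$pos,
                                  fmt_num(s$zscore), sep = "\t")), con)
  close(con)
  write_edge_file <- function(edges, path) {
    con <- file(path, "w", encoding = "UTF-8")
    writeLines(c("source\ttarget\ttype\tweight\tdirected\tpubmed",
                 if (nrow(edges))
                   paste(edges$source, edges$target, edges$type,
                         fmt_num(edges$weight),
                         ifelse(edges$directed, "true", "false"),
                         ifelse(nzchar(edges$pubmed), edges$pubmed, "."),
                         sep = "\t")), con)
    close(con)
  }
  write_edge_file(as_edge_df(fx$ppi_edges), file.path(dir, "ppi_edges.tsv"))
  write_edge_file(fx$tissue_edges, file.path(dir, "tissue_edges.tsv"))
  write_edge_file(fx$drug_edges, file.path(dir, "drug_edges.tsv"))
  jsonlite::write_json(fx$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Planted-module recovery experiment
#'
#' The benchmark harness for the prioritizers: on each replicate a fresh
#' fixture is generated (seed `rng_seed + replicate`), the network is
#' assembled at a threshold that separates the planted signal from the
#' noise, and each disease's held-out genes — planted members of the module
#' that were emitted with noise-level p-values only, hence candidates, not
#' seeds — are looked up in the candidate ranking. The statistic reported
#' per replicate is the median rank percentile of the held-out genes
#' (100 * rank / number of candidates; lower is better; 50 is the null
#' expectation). `method = "null"` ranks candidates by uniform random
#' scores as a negative control. Held-out genes absent from the assembled
#' network are scored at the 100th percentile.
#'
#' @param config a [fixture_config()].
#' @param method `"rwr"`, `"prince"` or `"null"`.
#' @param params a [propagation_params()]; defaults to the method's
#'   convention (column-stochastic for RWR, symmetric for PRINCE).
#' @param replicates number of independent fixtures.
#' @param tau assembly/seed threshold (default 7, the separator of the
#'   default fixture).
#' @param ds neighbourhood radius used during assembly (default 2, so
#'   held-out genes are almost surely included as candidates).
#' @return data frame with columns `replicate` and `median_percentile`.
#' @export
recovery_experiment <- function(config = fixture_config(),
                                method = c("rwr", "prince", "null"),
                                params = NULL, replicates = 20, tau = 7,
                                ds = 2) {
  method <- match.arg(method)
  if (is.null(params)) {
    params <- if (method == "prince")
      propagation_params(normalization = "symmetric")
    else propagation_params()
  }
  layers <- if (method == "prince") c("ppi", "tfbs", "tissue", "drug")
            else c("ppi", "tfbs")
  acfg <- assembly_config(threshold_tau = tau, ds = ds, layers = layers)
  out <- data.frame(replicate = seq_len(replicates),
                    median_percentile = NA_real_)
  for (rep_i in seq_len(replicates)) {
    cfg <- config
    cfg$rng_seed <- config$rng_seed + rep_i
    fx <- generate_fixture(cfg)
    net <- suppressMessages(suppressWarnings(
      assemble(fx$associations, fx$annotation, sites = fx$sites,
               ppi_edges = fx$ppi_edges, tissue_edges = fx$tissue_edges,
               drug_edges = fx$drug_edges, config = acfg)))
    pct <- with_fixture_seed(cfg$rng_seed + 1000003L, {
      unlist(lapply(names(fx$truth$heldout), function(d) {
        seeds <- associated_genes(net, tau, d)
        if (length(seeds) == 0) return(NULL)
        ranking <- switch(method,
          rwr = rwr(net, seeds = seeds, params = params)$candidate_ranking,
          prince = prince_extended(net, d, tau,
                                   params = params)$candidate_ranking,
          null = {
            genes <- sort(net$nodes$id[net$nodes$type == "gene"])
            sc <- stats::setNames(stats::runif(length(genes)), genes)
            rank_candidates(sc, seeds)
          })
        m <- nrow(ranking)
        vapply(fx$truth$heldout[[d]], function(h) {
          r <- ranking$rank[ranking$gene == h]
          if (length(r)) 100 * r / m else 100
        }, numeric(1))
      }))
    })
    out$median_percentile[rep_i] <- stats::median(pct)
  }
  out
}
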