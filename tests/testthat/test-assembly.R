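test_that("SNP mapping follows gene-body distance with lexicographic ties", {
  ann <- toy_annotation()
  # inside a gene body -> that gene, regardless of neighbours
  expect_equal(map_snp_to_gene("chr1", 1500, ann), "CHR1_G01")
  # strictly nearer gene wins: 10001..12000 is G02, SNP at 9000 is 1001 bp
  # from G02's start and 7000 bp from G01's end
  expect_equal(map_snp_to_gene("chr1", 9000, ann), "CHR1_G02")
  # exactly equidistant (500 bp each side) -> lexicographically smaller
  # symbol wins
  tie_ann <- data.frame(symbol = c("B_GENE", "A_GENE"), chrom = "chrX",
                        start = c(1L, 2000L), end = c(1000L, 3000L),
                        strand = "+", stringsAsFactors = FALSE)
  expect_equal(map_snp_to_gene("chrX", 1500, tie_ann), "A_GENE")
  # adjacency is not containment: a SNP one bp past gene A but inside an
  # immediately adjacent gene B must map to B
  adj_ann <- data.frame(symbol = c("ZLEFT", "ARIGHT"), chrom = "chrY",
                        start = c(1L, 1001L), end = c(1000L, 2000L),
                        strand = "+", stringsAsFactors = FALSE)
  expect_equal(map_snp_to_gene("chrY", 1001, adj_ann), "ARIGHT")
  # no gene on the chromosome
  expect_error(map_snp_to_gene("chr9", 100, ann), "no annotated gene")
  expect_true(is.na(map_snp_to_gene("chr9", 100, ann, on_unmapped = "na")))
})

test_that("SNP mapping equals brute-force minimization on random instances", {
  set.seed(101)
  ann <- toy_annotation(n_per_chrom = 8)
  for (i in 1:200) {
    chrom <- sample(c("chr1", "chr2"), 1)
    pos <- sample(1:90000, 1)
    expect_identical(map_snp_to_gene(chrom, pos, ann),
                     bf_nearest_gene(chrom, pos, ann))
  }
  # vectorized call agrees elementwise
  chroms <- sample(c("chr1", "chr2"), 50, replace = TRUE)
  poss <- sample(1:90000, 50)
  expect_identical(map_snp_to_gene(chroms, poss, ann),
                   mapply(bf_nearest_gene, chroms, poss,
                          MoreArgs = list(ann = ann), USE.NAMES = FALSE))
})

test_that("Fisher combination matches the chi-square tail oracle", {
  # k = 1 identity and the all-ones boundary
  expect_identical(fisher_meta_p(0.01), 0.01)
  expect_equal(fisher_meta_p(c(1, 1)), 1.0)
  # printed two-study case against numerical integration
  expect_equal(fisher_meta_p(c(0.05, 0.05)),
               chisq_tail_oracle(-4 * log(0.05), 4), tolerance = 1e-10)
  # permutation invariance and the oracle over random vectors
  set.seed(7)
  for (i in 1:50) {
    p <- stats::runif(sample(2:6, 1), 0.001, 1)
    expect_equal(fisher_meta_p(p), fisher_meta_p(rev(p)))
    expect_equal(fisher_meta_p(p),
                 chisq_tail_oracle(-2 * sum(log(p)), 2 * length(p)),
                 tolerance = 1e-10)
    # adding a p = 1 study changes df but not X^2; result still matches
    expect_equal(fisher_meta_p(c(p, 1)),
                 chisq_tail_oracle(-2 * sum(log(p)), 2 * (length(p) + 1)),
                 tolerance = 1e-10)
  }
  expect_error(fisher_meta_p(numeric()), "at least one")
  expect_error(fisher_meta_p(c(0.5, 0)), "\\(0, 1]")
  expect_error(fisher_meta_p(1.2), "\\(0, 1]")
})

test_that("disease-gene edges take -log10 of the best combined p per gene", {
  ann <- toy_annotation()
  rec <- function(ph, snp, pos, p, pm = "99999999")
    data.frame(snp_id = snp, chrom = "chr1", pos = pos, phenotype = ph,
               pvalue = p, pubmed = pm, stringsAsFactors = FALSE)

  # single study: weight is exactly -log10(p)
  e1 <- build_disease_gene_edges(rec("MS", "rs1", 1500, 1e-8), ann)
  expect_equal(e1$weight, 8.0)
  expect_equal(e1$source, "MS")
  expect_equal(e1$target, "CHR1_G01")

  # two all-ones studies combine to meta p = 1 -> weight 0
  e2 <- build_disease_gene_edges(
    rbind(rec("MS", "rs1", 1500, 1, "1"), rec("MS", "rs1", 1500, 1, "2")), ann)
  expect_equal(e2$weight, 0.0)
  expect_equal(split_pubmed(e2$pubmed)[[1]], c("1", "2"))

  # two SNPs in one gene: the most significant combined p defines the edge
  e3 <- build_disease_gene_edges(
    rbind(rec("MS", "rs1", 1200, 1e-6, "1"), rec("MS", "rs2", 1800, 1e-9, "2")),
    ann)
  expect_equal(nrow(e3), 1)
  expect_equal(e3$weight, 9.0)
  expect_equal(split_pubmed(e3$pubmed)[[1]], c("1", "2"))

  # replicated phenotype-SNP pair is Fisher-combined before the best-SNP rule
  e4 <- build_disease_gene_edges(
    rbind(rec("MS", "rs1", 1200, 0.05), rec("MS", "rs1", 1200, 0.05)), ann)
  expect_equal(10^(-e4$weight), fisher_meta_p(c(0.05, 0.05)),
               tolerance = 1e-12)

  # p = 0 clamps rather than yielding an infinite weight
  expect_warning(e5 <- build_disease_gene_edges(rec("MS", "rs1", 1200, 0), ann),
                 "clamped")
  expect_equal(e5$weight, 300)

  # records on an unannotated chromosome are skipped with a warning
  bad <- rec("MS", "rs9", 100, 1e-10)
  bad$chrom <- "chrZ"
  expect_warning(e6 <- build_disease_gene_edges(rbind(bad, rec("MS", "rs1", 1500, 1e-4)), ann),
                 "skipped")
  expect_equal(nrow(e6), 1)
})

test_that("threshold filtering is boundary-inclusive and monotone", {
  mk <- function(w) data.frame(source = "MS", target = paste0("G", seq_along(w)),
                               type = "disease_gene", weight = w,
                               directed = FALSE, pubmed = "",
                               stringsAsFactors = FALSE)
  expect_equal(nrow(filter_by_threshold(mk(8.0), 8)), 1)     # retained at tau
  expect_equal(nrow(filter_by_threshold(mk(7.999), 8)), 0)   # just below
  expect_equal(nrow(filter_by_threshold(mk(c(0, 3, 12)), 0)), 3)
  expect_error(filter_by_threshold(mk(1), -1), "tau")
  # non-disease_gene edges pass through untouched
  ppi <- data.frame(source = "A", target = "B", type = "protein_protein",
                    weight = 1, directed = FALSE, pubmed = "")
  expect_equal(nrow(filter_by_threshold(rbind(mk(2), ppi), 5)), 1)

  # monotonicity over random edge sets: higher tau -> subset
  set.seed(21)
  for (i in 1:20) {
    e <- mk(stats::runif(30, 0, 12))
    taus <- sort(stats::runif(2, 0, 12))
    k1 <- filter_by_threshold(e, taus[1])$target
    k2 <- filter_by_threshold(e, taus[2])$target
    expect_true(all(k2 %in% k1))
  }
})

test_that("TFBS edge derivation applies strict Z and inclusive window", {
  ann <- toy_annotation()  # chr1 TSS at 1, 12000, 20001, 32000, 40001
  site <- function(tf, pos, z)
    data.frame(tf_symbol = tf, chrom = "chr1", pos = pos, zscore = z,
               stringsAsFactors = FALSE)
  # Z exactly at the cutoff -> excluded (strict inequality)
  expect_equal(nrow(suppressMessages(
    derive_tfbs_edges(site("CHR1_G03", 100, 4.0), ann))), 0)
  # distance exactly 5000 bp from the TSS -> included (inclusive window)
  e <- suppressMessages(derive_tfbs_edges(site("CHR1_G03", 5001, 5.0), ann))
  expect_equal(e$target, "CHR1_G01")
  expect_true(e$directed)
  expect_equal(e$weight, 1.0)
  # distance 5001 -> excluded
  expect_equal(nrow(suppressMessages(
    derive_tfbs_edges(site("CHR1_G03", 5002, 5.0), ann))), 0)
  # TF binding its own promoter yields a flagged self-edge
  expect_message(
    eself <- derive_tfbs_edges(site("CHR1_G01", 10, 6), ann),
    "self-edge")
  expect_equal(eself$source, "CHR1_G01")
  expect_equal(eself$target, "CHR1_G01")
  # duplicates collapse
  e2 <- suppressMessages(derive_tfbs_edges(
    rbind(site("CHR1_G03", 100, 5), site("CHR1_G03", 200, 6)), ann))
  expect_equal(nrow(e2), 1)
})

test_that("TFBS derivation equals the brute-force site-by-gene scan", {
  set.seed(31)
  ann <- toy_annotation(n_per_chrom = 10)
  for (i in 1:10) {
    n_sites <- 120
    sites <- data.frame(
      tf_symbol = sample(ann$symbol, n_sites, replace = TRUE),
      chrom = sample(c("chr1", "chr2", "chr3"), n_sites, replace = TRUE),
      pos = sample(1:110000, n_sites, replace = TRUE),
      zscore = round(stats::runif(n_sites, 3, 6), 2),
      stringsAsFactors = FALSE)
    got <- suppressMessages(derive_tfbs_edges(sites, ann))
    got_keys <- sort(paste0(got$source, "->", got$target))
    expect_identical(got_keys, bf_tfbs_edges(sites, ann))
  }
})

test_that("neighbourhood expansion matches ds semantics and BFS", {
  assoc <- hetero_network(
    rbind(data.frame(id = "MS", type = "disease"), gene_nodes(c("A", "B"))),
    data.frame(source = c("MS", "MS"), target = c("A", "B"),
               type = "disease_gene", weight = 8))
  universe <- data.frame(source = c("A", "B", "C"), target = c("B", "C", "D"),
                         type = "protein_protein", stringsAsFactors = FALSE)
  # ds = 0: only the A-B interaction joins; C stays out
  e0 <- expand_neighborhood(assoc, universe, 0)
  expect_setequal(e0$nodes$id, c("MS", "A", "B"))
  expect_equal(sum(e0$edges$type == "protein_protein"), 1)
  # ds = 1: first neighbours (C) and the B-C edge join
  e1 <- expand_neighborhood(assoc, universe, 1)
  expect_setequal(e1$nodes$id, c("MS", "A", "B", "C"))
  expect_equal(sum(e1$edges$type == "protein_protein"), 2)
  # ds = 2 reaches D
  e2 <- expand_neighborhood(assoc, universe, 2)
  expect_true("D" %in% e2$nodes$id)
  expect_error(expand_neighborhood(assoc, universe, 3), "ds")
  # no associated genes -> unchanged
  iso <- hetero_network(data.frame(id = "MS", type = "disease"))
  expect_equal(expand_neighborhood(iso, universe, 1)$n, 1)

  # oracle equivalence: reached gene set equals depth-limited BFS
  set.seed(41)
  for (i in 1:20) {
    net <- random_ppi_net(25, 0.08)
    seeds <- sample(net$nodes$id, 3)
    start <- hetero_network(gene_nodes(seeds))
    for (k in 1:2) {
      got <- sort(expand_neighborhood(start, net$edges, k)$nodes$id)
      expect_identical(got, bf_bfs(net$edges, sort(seeds), k))
    }
  }
})

test_that("assembly pipeline wires the stages together", {
  ann <- toy_annotation()
  rec <- data.frame(snp_id = "rs1", chrom = "chr1", pos = 1500,
                    phenotype = "MS", pvalue = 1e-9, pubmed = "123",
                    stringsAsFactors = FALSE)
  # minimal path: one disease, one gene, one edge
  net <- suppressMessages(assemble(rec, ann,
                                   config = assembly_config(threshold_tau = 8)))
  expect_equal(net$n, 2)
  expect_equal(nrow(net$edges), 1)

  # threshold above every weight: empty unless isolated diseases are kept
  net0 <- suppressMessages(assemble(rec, ann,
                                    config = assembly_config(threshold_tau = 20)))
  expect_equal(net0$n, 0)
  netk <- suppressMessages(assemble(
    rec, ann, config = assembly_config(threshold_tau = 20,
                                       keep_isolated_diseases = TRUE)))
  expect_equal(netk$nodes$type, "disease")

  # filtering monotonicity on a full fixture
  fx <- generate_fixture(small_fixture_config())
  cfg4 <- assembly_config(threshold_tau = 4, ds = 0, layers = "ppi")
  cfg8 <- assembly_config(threshold_tau = 8, ds = 0, layers = "ppi")
  n4 <- suppressMessages(suppressWarnings(
    assemble(fx$associations, fx$annotation, ppi_edges = fx$ppi_edges,
             config = cfg4)))
  n8 <- suppressMessages(suppressWarnings(
    assemble(fx$associations, fx$annotation, ppi_edges = fx$ppi_edges,
             config = cfg8)))
  expect_lte(nrow(n8$edges), nrow(n4$edges))

  # tissue and drug layers attach only around the retained core
  cfgT <- assembly_config(threshold_tau = 7, ds = 0,
                          layers = c("ppi", "tissue", "drug"))
  nT <- suppressMessages(suppressWarnings(
    assemble(fx$associations, fx$annotation, ppi_edges = fx$ppi_edges,
             tissue_edges = fx$tissue_edges, drug_edges = fx$drug_edges,
             config = cfgT)))
  expect_silent(validate_network(nT))
  tg <- nT$edges[nT$edges$type == "tissue_gene", ]
  gene_ids <- nT$nodes$id[nT$nodes$type == "gene"]
  expect_true(all(tg$source %in% gene_ids | tg$target %in% gene_ids))
})
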