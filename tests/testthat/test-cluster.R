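# Toy protein set: two 3-member families at high identity, one lone gene.
toy_genes <- function() {
  base1 <- "MKVLATTRSDQEWLNKAGHILVEDSPRTYQMKVLATTRSDQEWLNK"
  base2 <- "GHWPFERTYLVNMASDKQIECGHWPFERTYLVNMASDKQIECRRRR"
  mut <- function(s, pos, to) {
    v <- strsplit(s, "")[[1]]; v[pos] <- to; paste(v, collapse = "")
  }
  genes_tbl(
    g1 = c(a1 = base1, b1 = base2, lone = random_protein(40)),
    g2 = c(a2 = mut(base1, c(3, 10), c("W", "W")), b2 = mut(base2, 5, "A")),
    g3 = c(a3 = mut(base1, 20, "P")))
}

test_that("a single gene yields no edges", {
  g <- genes_tbl(g1 = c(x = random_protein(50)))
  expect_equal(nrow(all_vs_all(g)), 0)
})

test_that("edge set equals brute-force evaluation of every pair", {
  set.seed(31)
  g <- toy_genes()  # 6 genes -> 15 pairs
  cl <- clustering_params()
  sp <- scoring_params("protein")
  got <- all_vs_all(g, cl, sp)
  # oracle: align all 15 pairs directly and apply the three thresholds
  exp_rows <- list()
  for (i in 1:(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
    aln <- align_local(g$seq[i], g$seq[j], sp)
    if (aln$alignment_length == 0) next
    em <- edge_metrics(aln, nchar(g$seq[i]), nchar(g$seq[j]))
    ev <- evalue(aln$score, nchar(g$seq[i]), nchar(g$seq[j]), sp)
    if (em$percent_identity >= cl$min_identity &&
        em$coverage_longer >= cl$min_coverage && ev <= cl$max_evalue)
      exp_rows[[length(exp_rows) + 1]] <-
        sort(c(g$gene_id[i], g$gene_id[j]))
  }
  exp_pairs <- do.call(rbind, exp_rows)
  expect_equal(nrow(got), nrow(exp_pairs))
  expect_equal(got[c("gene_a", "gene_b")],
               tibble::tibble(gene_a = exp_pairs[, 1],
                              gene_b = exp_pairs[, 2]) |>
                 dplyr::arrange(gene_a, gene_b))
  # the two engineered families are connected, the lone gene is not
  expect_true(all(c("a1", "a2", "a3", "b1", "b2") %in%
                  c(got$gene_a, got$gene_b)))
  expect_false("lone" %in% c(got$gene_a, got$gene_b))
})

test_that("edges are invariant under input order permutation", {
  set.seed(13)
  g <- toy_genes()
  e1 <- all_vs_all(g)
  e2 <- all_vs_all(g[sample(nrow(g)), ])
  expect_equal(e1, e2)
})

test_that("prefilter output equals the unfiltered computation", {
  set.seed(91)
  sim <- simulate_pangenome(sim_params(n_genomes = 3, n_core = 8,
                                       new_rate = 2, singleton_rate = 1,
                                       protein_len_mean = 120,
                                       protein_len_sd = 30, seed = 6))
  expect_lte(nrow(sim$proteins), 50)
  e_pre <- all_vs_all(sim$proteins, prefilter = TRUE)
  e_all <- all_vs_all(sim$proteins, prefilter = FALSE)
  expect_equal(e_pre, e_all)
})

test_that("raising min_identity never adds edges", {
  sim <- simulate_pangenome(sim_params(n_genomes = 3, n_core = 10,
                                       new_rate = 2, seed = 8,
                                       within_family_divergence = 0.25))
  counts <- vapply(c(30, 50, 70, 90), function(t)
    nrow(all_vs_all(sim$proteins, clustering_params(min_identity = t))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("duplicate gene ids are rejected", {
  g <- genes_tbl(g1 = c(x = "MKVLI"), g2 = c(x = "MKVLI"))
  expect_error(all_vs_all(g), class = "panforge_input")
})

test_that("families are connected components (chain closure, singletons)", {
  g <- genes_tbl(g1 = c(a = "M", b = "M", c = "M", d = "M"))
  none <- tibble::tibble(gene_a = character(0), gene_b = character(0))
  f0 <- build_families(none, g)
  expect_equal(nrow(f0), 4)
  expect_equal(dplyr::n_distinct(f0$family_id), 4)
  chain <- tibble::tibble(gene_a = c("a", "b"), gene_b = c("b", "c"))
  f1 <- build_families(chain, g)
  expect_equal(dplyr::n_distinct(f1$family_id), 2)
  expect_equal(sort(f1$gene_id[f1$family_id == "fam|a"]), c("a", "b", "c"))
  expect_error(build_families(tibble::tibble(gene_a = "zz", gene_b = "a"), g),
               class = "panforge_input")
})

test_that("components match a BFS reachability oracle on random graphs", {
  set.seed(19)
  for (rep in 1:15) {
    n <- sample(5:30, 1)
    ids <- sprintf("n%02d", 1:n)
    g <- tibble::tibble(genome_id = "g1", gene_id = ids,
                        seq = rep("M", n))
    m <- sample(0:(2 * n), 1)
    edges <- tibble::tibble(gene_a = sample(ids, m, TRUE),
                            gene_b = sample(ids, m, TRUE)) |>
      dplyr::filter(gene_a != gene_b)
    fams <- build_families(edges, g)
    oracle <- oracle_components(ids, edges)
    expect_equal(rand_index(fams$family_id[match(ids, fams$gene_id)],
                            oracle), 1.0)
  }
})

test_that("no gene is lost or duplicated by family construction", {
  sim <- simulate_pangenome(sim_params(n_genomes = 4, n_core = 12,
                                       new_rate = 4, seed = 21))
  fams <- build_families(all_vs_all(sim$proteins), sim$proteins)
  expect_equal(sort(fams$gene_id), sort(sim$proteins$gene_id))
})

test_that("classification follows the core/accessory/strain-specific rules", {
  fam <- tibble::tibble(
    family_id = c("F1", "F1", "F1", "F2", "F3", "F3"),
    genome_id = c("g1", "g2", "g3", "g1", "g2", "g3"),
    gene_id = paste0("x", 1:6))
  part <- classify_families(fam, c("g1", "g2", "g3"))
  expect_equal(part$n_core, 1)
  expect_equal(part$n_accessory, 1)
  expect_equal(part$n_strain_specific, 1)
  expect_equal(part$pan_total, 3)
  expect_equal(part$per_genome_unique$n_unique[
    part$per_genome_unique$genome_id == "g1"], 1L)
  expect_equal(part$single_copy_core_ids, "F1")
  expect_equal(sum(glance(part)[c("n_core", "n_accessory",
                                  "n_strain_specific")]),
               part$pan_total)
})

test_that("a paralogous core family is core but not single-copy core", {
  fam <- tibble::tibble(
    family_id = "F1", genome_id = c("g1", "g1", "g2", "g3"),
    gene_id = paste0("x", 1:4))
  part <- classify_families(fam, c("g1", "g2", "g3"))
  expect_equal(part$n_core, 1)
  expect_equal(part$single_copy_core_ids, character(0))
})

test_that("partition counts are invariant under genome relabeling", {
  sim <- simulate_pangenome(sim_params(n_genomes = 5, n_core = 10,
                                       new_rate = 5, seed = 33))
  p1 <- classify_families(sim$pa)
  pa2 <- sim$pa
  names(pa2)[-1] <- rev(names(pa2)[-1])
  p2 <- classify_families(pa2)
  expect_equal(glance(p1)[c("pan_total", "n_core", "n_accessory",
                            "n_strain_specific")],
               glance(p2)[c("pan_total", "n_core", "n_accessory",
                            "n_strain_specific")])
})

test_that("recovered families reproduce the simulator truth partition", {
  sim <- simulate_pangenome(sim_params(n_genomes = 8, n_core = 20,
                                       new_rate = 5, singleton_rate = 2,
                                       within_family_divergence = 0.1,
                                       seed = 14))
  gids <- sort(unique(sim$proteins$genome_id))
  fams <- build_families(all_vs_all(sim$proteins), sim$proteins)
  ord <- sim$truth$gene_id
  expect_equal(rand_index(fams$family_id[match(ord, fams$gene_id)],
                          sim$truth$family_id), 1.0)
  got <- glance(classify_families(fams, gids))
  want <- glance(classify_families(sim$pa, gids))
  expect_equal(got[c("pan_total", "n_core", "n_accessory",
                     "n_strain_specific")],
               want[c("pan_total", "n_core", "n_accessory",
                      "n_strain_specific")])
})
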