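test_that("single-copy core extraction applies both requirements", {
  fam <- tibble::tibble(
    family_id = c("F1", "F1", "F1",          # single-copy core
                  "F2", "F2", "F2", "F2",    # core but paralogous in g1
                  "F3"),                     # strain-specific
    genome_id = c("g1", "g2", "g3", "g1", "g1", "g2", "g3", "g2"),
    gene_id = paste0("x", 1:8))
  expect_equal(extract_single_copy_core(fam, c("g1", "g2", "g3")), "F1")
})

test_that("simulated core families are recovered as single-copy core", {
  sim <- simulate_pangenome(sim_params(n_genomes = 5, n_core = 12,
                                       new_rate = 3, singleton_rate = 1,
                                       within_family_divergence = 0.08,
                                       seed = 18))
  gids <- sort(unique(sim$proteins$genome_id))
  fams <- build_families(all_vs_all(sim$proteins), sim$proteins)
  scc <- extract_single_copy_core(fams, gids)
  expect_length(scc, 12)
  # each recovered family maps onto exactly one truth core family
  members <- fams$gene_id[fams$family_id %in% scc]
  truth_f <- sim$truth$family_id[match(members, sim$truth$gene_id)]
  expect_true(all(startsWith(unique(truth_f), "core")))
})

test_that("identical genomes are at distance zero", {
  g <- genes_tbl(g1 = c(a = "MKVLATTRSDQEW"), g2 = c(b = "MKVLATTRSDQEW"),
                 g3 = c(c = "MKVLATTRSDQEW"))
  fam <- tibble::tibble(family_id = "F1", genome_id = c("g1", "g2", "g3"),
                        gene_id = c("a", "b", "c"))
  dm <- core_distances(g, fam, "F1")
  expect_equal(unname(dm$d), matrix(0, 3, 3))
})

test_that("a known substitution fraction gives the Poisson-corrected value", {
  set.seed(61)
  s <- random_protein(100)
  v <- strsplit(s, "")[[1]]
  flip <- sample(100, 10)  # exactly p = 0.1
  v[flip] <- vapply(v[flip], function(x) setdiff(AA_LETTERS, x)[1],
                    character(1))
  s2 <- paste(v, collapse = "")
  g <- genes_tbl(g1 = c(a = s), g2 = c(b = s2))
  fam <- tibble::tibble(family_id = "F1", genome_id = c("g1", "g2"),
                        gene_id = c("a", "b"))
  dm <- core_distances(g, fam, "F1")
  expect_equal(dm$p["g1", "g2"], 0.1, tolerance = 1e-9)
  expect_equal(dm$d["g1", "g2"], -log(0.9), tolerance = 1e-9)
  dp <- core_distances(g, fam, "F1", correction = "p")
  expect_equal(dp$d["g1", "g2"], 0.1, tolerance = 1e-9)
})

test_that("pooled p equals a recount from concatenated gapped alignments", {
  set.seed(29)
  sim <- simulate_pangenome(sim_params(n_genomes = 3, n_core = 6,
                                       new_rate = 0, singleton_rate = 0,
                                       within_family_divergence = 0.12,
                                       protein_len_mean = 80,
                                       protein_len_sd = 10, seed = 3))
  fams <- build_families(all_vs_all(sim$proteins), sim$proteins)
  scc <- extract_single_copy_core(fams, sort(unique(sim$proteins$genome_id)))
  dm <- core_distances(sim$proteins, fams, scc)
  sp <- scoring_params("protein")
  seq_of <- setNames(sim$proteins$seq, sim$proteins$gene_id)
  for (pair in list(c("g01", "g02"), c("g02", "g03"))) {
    mism <- 0; tot <- 0
    for (f in scc) {
      m <- fams[fams$family_id == f & fams$genome_id %in% pair, ]
      aln <- align_global(seq_of[m$gene_id[m$genome_id == pair[1]]],
                          seq_of[m$gene_id[m$genome_id == pair[2]]], sp)
      ga <- strsplit(aln$aligned_a, "")[[1]]
      gb <- strsplit(aln$aligned_b, "")[[1]]
      mism <- mism + sum(!(ga == gb & ga != "-"))
      tot <- tot + length(ga)
    }
    expect_equal(dm$p[pair[1], pair[2]], mism / tot, tolerance = 1e-12)
  }
})

test_that("three-taxon NJ reproduces the closed-form pendant lengths", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))
  expect_error(nj_tree(d[1:2, 1:2]), class = "panforge_input")
})

test_that("NJ recovers the generating topology of additive 5-taxon matrices", {
  skip_if_not_installed("phangorn")
  set.seed(37)
  labs <- LETTERS[1:5]
  for (rep in 1:50) {
    gen <- ape::rtree(5, tip.label = sample(labs))
    gen$edge.length <- runif(nrow(gen$edge), 0.05, 1)
    dmat <- ape::cophenetic.phylo(gen)[labs, labs]
    tr <- nj_tree(dmat)
    # oracle: best least-squares fit over all 15 unrooted topologies
    ssqs <- vapply(five_taxon_topologies(labs), topology_ssq, numeric(1),
                   dmat = dmat)
    best <- ape::read.tree(text = names(which.min(ssqs)))
    best$edge.length <- rep(1, nrow(best$edge))
    expect_lt(min(ssqs), 1e-12)  # additive: generating topology fits exactly
    expect_equal(phangorn::RF.dist(ape::unroot(tr), best), 0)
    # branch lengths reproduced within 1e-9 on additive input
    expect_equal(ape::cophenetic.phylo(tr)[labs, labs], dmat,
                 tolerance = 1e-9)
    expect_equal(attr(tr, "clamped_deficit"), 0)
  }
})

test_that("tree bipartitions separate two simulated clades", {
  skip_if_not_installed("phangorn")
  set.seed(83)
  anc1 <- random_protein(120); anc2 <- random_protein(120)
  mut <- function(s, d) {
    v <- strsplit(s, "")[[1]]
    hit <- runif(length(v)) < d
    v[hit] <- vapply(v[hit], function(x) sample(setdiff(AA_LETTERS, x), 1),
                     character(1))
    paste(v, collapse = "")
  }
  gs <- lapply(setNames(1:6, paste0("g", 1:6)), function(i) {
    anc <- if (i <= 3) anc1 else mut(anc1, 0.3)
    setNames(mut(anc, 0.02), paste0("p", i))
  })
  g <- do.call(genes_tbl, gs)
  fam <- tibble::tibble(family_id = "F1", genome_id = g$genome_id,
                        gene_id = g$gene_id)
  tr <- nj_tree(core_distances(g, fam, "F1"))
  rooted <- ape::root(tr, outgroup = c("g4", "g5", "g6"),
                      resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, c("g1", "g2", "g3")))
  expect_true(ape::is.monophyletic(rooted, c("g4", "g5", "g6")))
})

test_that("Newick round-trips preserve topology and branch lengths", {
  skip_if_not_installed("phangorn")
  expect_match(write_newick(ape::read.tree(text = "(A:1.0,B:2.0);")),
               "^\\(.*A:1.*B:2.*\\);$")
  set.seed(90)
  for (rep in 1:10) {
    tr <- ape::rtree(sample(4:12, 1))
    back <- read_newick(write_newick(tr))
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(back)), 0)
    expect_equal(sort(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label]),
                 sort(ape::cophenetic.phylo(tr)), tolerance = 1e-9)
  }
  tf <- withr::local_tempfile(fileext = ".nwk")
  tr <- ape::rtree(6)
  write_newick(tr, tf)
  expect_match(readLines(tf), ";$")
  expect_equal(read_newick(path = tf)$tip.label, tr$tip.label)
  expect_error(read_newick("((A,B);"), class = "panforge_io")
})

test_that("labels with Newick-hostile characters survive a round trip", {
  tr <- ape::rtree(4)
  tr$tip.label <- c("a b", "c(d", "e:f", "plain")
  back <- read_newick(write_newick(tr))
  expect_setequal(gsub("[_']", " ", back$tip.label)[1],
                  c("a b"))
})

test_that("family bootstrap yields full support for a clean split", {
  set.seed(51)
  sim <- simulate_pangenome(sim_params(n_genomes = 4, n_core = 5,
                                       new_rate = 0, singleton_rate = 0,
                                       within_family_divergence = 0.1,
                                       protein_len_mean = 60,
                                       protein_len_sd = 5, seed = 6))
  fams <- build_families(all_vs_all(sim$proteins), sim$proteins)
  tr <- nj_bootstrap(sim$proteins, fams, n_boot = 20, seed = 2)
  expect_length(tr$node.label, tr$Nnode)
  expect_true(all(tr$node.label >= 0 & tr$node.label <= 1))
})
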