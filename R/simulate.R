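# Synthetic pan-genome and genome-pair simulators.
#
# The generator produces per-genome protein sets whose gene families follow a
# core / accessory / strain-specific structure with a constant per-genome
# innovation rate, so pan-genome openness, clustering recovery and ANI are all
# checkable against ground truth. All randomness flows from a single seed.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# fixed arbitrary codon per amino acid for back-translation
CODON1 <- c(A="GCT", R="CGT", N="AAT", D="GAT", C="TGT", Q="CAA", E="GAA",
            G="GGT", H="CAT", I="ATT", L="CTT", K="AAA", M="ATG", F="TTT",
            P="CCT", S="TCT", T="ACT", W="TGG", Y="TAT", V="GTT")

#' Simulation parameters for a synthetic pan-genome
#'
#' Defaults describe a scaled-down bacterial strain set: 10 genomes sharing
#' 50 core families, a constant innovation rate of 10 new accessory families
#' per added genome (an open pan-genome by construction), 50% retention of
#' previously seen accessory families, 5 strain-specific families per genome,
#' and proteins diverged so that mean pairwise within-family identity is
#' about `100 * (1 - within_family_divergence)` percent.
#'
#' @param n_genomes Number of genomes G (>= 2).
#' @param n_core Number of core families present in every genome.
#' @param new_rate Expected number of new accessory families introduced per
#'   genome (Poisson mean).
#' @param p_keep Probability an already-introduced accessory family appears in
#'   each later genome.
#' @param singleton_rate Expected strain-specific families per genome.
#' @param protein_len_mean,protein_len_sd Protein length distribution (aa).
#' @param within_family_divergence Target expected pairwise amino-acid
#'   divergence between two members of a family, in substitutions/site
#'   (each copy is mutated at half this rate relative to the family ancestor).
#' @param intergenic_len_mean Mean spacer length (bp) between back-translated
#'   CDSs in the nucleotide genomes.
#' @param seed Integer seed driving every random draw.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_genomes = 10L, n_core = 50L, new_rate = 10,
                       p_keep = 0.5, singleton_rate = 5,
                       protein_len_mean = 250, protein_len_sd = 50,
                       within_family_divergence = 0.1,
                       intergenic_len_mean = 100, seed = 1L) {
  p <- list(n_genomes = as.integer(n_genomes), n_core = as.integer(n_core),
            new_rate = new_rate, p_keep = p_keep,
            singleton_rate = singleton_rate,
            protein_len_mean = protein_len_mean,
            protein_len_sd = protein_len_sd,
            within_family_divergence = within_family_divergence,
            intergenic_len_mean = intergenic_len_mean, seed = as.integer(seed))
  if (p$n_genomes < 2) pf_stop("n_genomes must be >= 2", "input")
  if (p$n_core < 0 || p$new_rate < 0 || p$singleton_rate < 0)
    pf_stop("rates must be non-negative", "input")
  if (p$p_keep < 0 || p$p_keep > 1) pf_stop("p_keep must be in [0,1]", "input")
  if (p$within_family_divergence < 0 || p$within_family_divergence >= 0.5)
    pf_stop("within_family_divergence must be in [0, 0.5)", "input")
  if (p$protein_len_mean < 10) pf_stop("protein_len_mean too small", "input")
  structure(p, class = "sim_params")
}

# mutate a protein: each site substituted with prob `rate` to a different
# residue chosen uniformly
mutate_protein <- function(res, rate) {
  if (rate <= 0) return(res)
  hit <- runif(length(res)) < rate
  n <- sum(hit)
  if (n > 0) {
    cur <- res[hit]
    idx <- sample.int(19L, n, replace = TRUE)
    res[hit] <- vapply(seq_len(n), function(k) setdiff(AA20, cur[k])[idx[k]],
                       character(1))
  }
  res
}

#' Simulate a pan-genome with known family structure
#'
#' Genome `i` receives one gene per core family, a Bernoulli(`p_keep`) draw of
#' every accessory family introduced by earlier genomes, `Poisson(new_rate)`
#' newly introduced accessory families, and `Poisson(singleton_rate)`
#' strain-specific families. Each gene's protein is the family's ancestral
#' protein with i.i.d. per-site substitutions at half the within-family
#' divergence, so two family members differ at about
#' `within_family_divergence` of their sites. Output is deterministic for a
#' given parameter set (including seed).
#'
#' @param params A [sim_params()] object.
#' @param dir Optional directory; when given, per-genome protein
#'   (`<genome>.faa`) and nucleotide (`<genome>.fna`) FASTA files, a truth TSV
#'   and a JSON parameter sidecar are written there.
#' @param nucleotide If `TRUE`, also build nucleotide genomes (back-translated
#'   CDSs joined by random spacers).
#' @return An object of class `synthetic_pangenome`: a list with
#'   * `proteins`: tibble (`genome_id`, `gene_id`, `seq`),
#'   * `truth`: tibble (`gene_id`, `genome_id`, `family_id`),
#'   * `pa`: truth presence/absence tibble (first column `family_id`),
#'   * `genomes`: named list of `DNAStringSet` (when `nucleotide = TRUE`),
#'   * `params`: the input parameters.
#' @examples
#' sim <- simulate_pangenome(sim_params(n_genomes = 3, n_core = 5,
#'                                      new_rate = 0, singleton_rate = 0,
#'                                      within_family_divergence = 0))
#' sim$pa
#' @export
simulate_pangenome <- function(params = sim_params(), dir = NULL,
                               nucleotide = !is.null(dir)) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  G <- params$n_genomes
  genome_ids <- sprintf("g%02d", seq_len(G))

  # --- family inventory -----------------------------------------------------
  fam <- tibble(family_id = character(), type = character(),
                origin = integer())
  if (params$n_core > 0)
    fam <- bind_rows(fam, tibble(
      family_id = sprintf("core%04d", seq_len(params$n_core)),
      type = "core", origin = 0L))
  presence <- list()  # family_id -> integer vector of genomes present
  for (f in fam$family_id) presence[[f]] <- seq_len(G)

  acc_count <- 0L; sng_count <- 0L
  for (i in seq_len(G)) {
    # previously introduced accessory families: Bernoulli(p_keep) each
    prior <- fam$family_id[fam$type == "accessory" & fam$origin < i]
    if (length(prior)) {
      keep <- prior[runif(length(prior)) < params$p_keep]
      for (f in keep) presence[[f]] <- c(presence[[f]], i)
    }
    n_new <- rpois(1, params$new_rate)
    if (n_new > 0) {
      ids <- sprintf("acc%04d", acc_count + seq_len(n_new))
      acc_count <- acc_count + n_new
      fam <- bind_rows(fam, tibble(family_id = ids, type = "accessory",
                                   origin = i))
      for (f in ids) presence[[f]] <- i
    }
    n_sng <- rpois(1, params$singleton_rate)
    if (n_sng > 0) {
      ids <- sprintf("sng%04d", sng_count + seq_len(n_sng))
      sng_count <- sng_count + n_sng
      fam <- bind_rows(fam, tibble(family_id = ids, type = "singleton",
                                   origin = i))
      for (f in ids) presence[[f]] <- i
    }
  }

  # --- sequences ------------------------------------------------------------
  half_rate <- params$within_family_divergence / 2
  lens <- pmax(30L, as.integer(round(rnorm(nrow(fam), params$protein_len_mean,
                                           params$protein_len_sd))))
  anc <- lapply(lens, function(L) sample(AA20, L, replace = TRUE))
  names(anc) <- fam$family_id
  # ancestral intergenic spacer per family: conserved across genomes, so the
  # nucleotide genomes of conspecific strains stay alignable between genes
  spacer <- vapply(rpois(nrow(fam), params$intergenic_len_mean),
                   function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                                     collapse = ""), character(1))
  names(spacer) <- fam$family_id

  rows <- vector("list", nrow(fam))
  for (k in seq_len(nrow(fam))) {
    f <- fam$family_id[k]
    gs <- sort(unique(presence[[f]]))
    seqs <- vapply(gs, function(i)
      paste(mutate_protein(anc[[f]], half_rate), collapse = ""), character(1))
    rows[[k]] <- tibble(genome_id = genome_ids[gs],
                        gene_id = NA_character_, family_id = f, seq = seqs)
  }
  genes <- bind_rows(rows) %>% arrange(.data$genome_id, .data$family_id)
  genes <- genes %>% group_by(.data$genome_id) %>%
    mutate(gene_id = sprintf("%s_%04d", .data$genome_id, dplyr::row_number())) %>%
    ungroup()

  truth <- genes %>% select("gene_id", "genome_id", "family_id")
  pa_tbl <- truth %>% count(.data$family_id, .data$genome_id) %>%
    tidyr::pivot_wider(names_from = "genome_id", values_from = "n",
                       values_fill = 0L)
  missing_g <- setdiff(genome_ids, names(pa_tbl))
  for (g in missing_g) pa_tbl[[g]] <- 0L
  pa_tbl <- pa_tbl[c("family_id", genome_ids)] %>% arrange(.data$family_id)

  out <- structure(list(proteins = genes %>% select("genome_id", "gene_id", "seq"),
                        truth = truth, pa = pa_tbl, params = params,
                        genomes = NULL),
                   class = "synthetic_pangenome")

  if (isTRUE(nucleotide)) {
    out$genomes <- lapply(setNames(genome_ids, genome_ids), function(g) {
      gg <- genes %>% filter(.data$genome_id == g)
      pieces <- purrr::map2_chr(gg$seq, gg$family_id, function(s, f) {
        cds <- paste(CODON1[strsplit(s, "")[[1]]], collapse = "")
        paste0(cds, spacer[[f]])
      })
      Biostrings::DNAStringSet(setNames(paste(pieces, collapse = ""),
                                        paste0(g, "_chr")))
    })
  }

  if (!is.null(dir)) write_pangenome(out, dir)
  out
}

#' Write a simulated pan-genome to disk
#'
#' Writes `<genome>.faa` (proteins), `<genome>.fna` (nucleotide, when
#' present), `truth.tsv` (gene_id, genome_id, family_id), `pa_matrix.tsv` and
#' `params.json` into `dir`.
#'
#' @param sim A `synthetic_pangenome` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pangenome <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_pangenome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in unique(sim$proteins$genome_id)) {
    gg <- sim$proteins[sim$proteins$genome_id == g, ]
    write_fasta(Biostrings::AAStringSet(setNames(gg$seq, gg$gene_id)),
                file.path(dir, paste0(g, ".faa")))
  }
  if (!is.null(sim$genomes))
    for (g in names(sim$genomes))
      write_fasta(sim$genomes[[g]], file.path(dir, paste0(g, ".fna")))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  write_pa_matrix(sim$pa, file.path(dir, "pa_matrix.tsv"))
  jsonlite::write_json(unclass(sim$params), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.synthetic_pangenome <- function(x, ...) {
  cat(sprintf("<synthetic_pangenome> %d genomes, %d families (%d genes)\n",
              x$params$n_genomes, nrow(x$pa), nrow(x$proteins)))
  invisible(x)
}

#' Simulate a pair of genomes at known nucleotide divergence
#'
#' The second sequence differs from the first by i.i.d. substitutions at rate
#' `divergence` (no indels), so expected ANI between the pair is exactly
#' `100 * (1 - divergence)`.
#'
#' @param length Genome length in bp.
#' @param divergence Per-site substitution probability, in `[0, 0.3)`.
#' @param seed Integer seed.
#' @return A list with `a` and `b` (single-contig `DNAStringSet`s) and
#'   `realized_divergence`, the realized differing-site fraction.
#' @examples
#' p <- simulate_genome_pair(2000, 0.05, seed = 7)
#' p$realized_divergence
#' @export
simulate_genome_pair <- function(length, divergence, seed = 1L) {
  if (divergence < 0 || divergence >= 0.3)
    pf_stop("divergence must be in [0, 0.3)", "input")
  if (length < 200) pf_stop("length too small", "input")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, length, replace = TRUE)
  b <- a
  hit <- runif(length) < divergence
  n <- sum(hit)
  if (n > 0) {
    idx <- sample.int(3L, n, replace = TRUE)
    b[hit] <- vapply(seq_len(n), function(k) setdiff(bases, a[hit][k])[idx[k]],
                     character(1))
  }
  list(a = Biostrings::DNAStringSet(c(genome_a = paste(a, collapse = ""))),
       b = Biostrings::DNAStringSet(c(genome_b = paste(b, collapse = ""))),
       realized_divergence = mean(a != b))
}
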