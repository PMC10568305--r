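# All-vs-all protein similarity and single-linkage ortholog families.
#
# Edges are unordered gene pairs passing three thresholds at once: percent
# identity, coverage of the longer sequence, and e-value. Families are the
# connected components of the resulting similarity graph.

#' Clustering thresholds for ortholog family construction
#'
#' Defaults are 50% identity, 50% coverage of the longer sequence and an
#' e-value cutoff of 1e-5 — the standard gene-family thresholds for bacterial
#' pan-genome pipelines.
#'
#' @param min_identity Minimum percent identity in `[0, 100]`.
#' @param min_coverage Minimum aligned fraction of the longer sequence, in
#'   `[0, 1]`.
#' @param max_evalue Maximum e-value (> 0).
#' @return A list of class `clustering_params`.
#' @export
clustering_params <- function(min_identity = 50, min_coverage = 0.5,
                              max_evalue = 1e-5) {
  if (min_identity < 0 || min_identity > 100)
    pf_stop("min_identity must be in [0,100]", "input")
  if (min_coverage < 0 || min_coverage > 1)
    pf_stop("min_coverage must be in [0,1]", "input")
  if (max_evalue <= 0) pf_stop("max_evalue must be > 0", "input")
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 max_evalue = max_evalue), class = "clustering_params")
}

# distinct k-mers of one sequence
seq_kmers <- function(s, k = 4L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

# candidate pair list via shared 4-mer prefilter; pairs where either sequence
# is shorter than 100 residues are always kept (cheap to align, and short
# true edges can in principle share few k-mers)
candidate_pairs <- function(seqs, prefilter, k = 4L, min_shared = 2L,
                            short_len = 100L) {
  n <- length(seqs)
  all_pairs <- function() {
    if (n < 2) return(tibble(i = integer(0), j = integer(0)))
    idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    tibble(i = idx[, 1], j = idx[, 2])
  }
  if (!prefilter || n < 2) return(all_pairs())
  lens <- nchar(seqs)
  km <- lapply(seqs, seq_kmers, k = k)
  dt <- tibble(kmer = unlist(km),
               gene = rep.int(seq_len(n), lengths(km)))
  shared <- dt %>% dplyr::inner_join(dt, by = "kmer",
                                     relationship = "many-to-many") %>%
    filter(.data$gene.x < .data$gene.y) %>%
    count(.data$gene.x, .data$gene.y, name = "n_shared")
  long_pairs <- shared %>% filter(.data$n_shared >= min_shared) %>%
    select(i = "gene.x", j = "gene.y")
  short <- which(lens < short_len)
  if (length(short)) {
    ap <- all_pairs()
    extra <- ap[ap$i %in% short | ap$j %in% short, ]
    long_pairs <- distinct(bind_rows(long_pairs, extra))
  }
  arrange(long_pairs, .data$j, .data$i)
}

#' All-vs-all protein similarity edges
#'
#' Locally aligns every unordered gene pair (within- and between-genome pairs
#' included, self-pairs excluded) and keeps exactly those passing
#' `min_identity`, `min_coverage` (of the longer sequence) and `max_evalue`
#' simultaneously. A shared-4-mer prefilter skips pairs that cannot plausibly
#' pass; it is output-equivalent to the unfiltered computation and can be
#' disabled with `prefilter = FALSE`.
#'
#' @param genes A tibble with columns `genome_id`, `gene_id` (globally
#'   unique) and `seq` (amino-acid sequences).
#' @param clustering A [clustering_params()] object.
#' @param scoring A [scoring_params()] object (protein).
#' @param prefilter Use the shared-k-mer prefilter (default `TRUE`).
#' @return A tibble of accepted edges: `gene_a`, `gene_b` (with
#'   `gene_a < gene_b`), `percent_identity`, `coverage_longer`, `evalue`,
#'   `score`.
#' @export
all_vs_all <- function(genes, clustering = clustering_params(),
                       scoring = scoring_params("protein"),
                       prefilter = TRUE) {
  stopifnot(all(c("genome_id", "gene_id", "seq") %in% names(genes)))
  if (anyDuplicated(genes$gene_id))
    pf_stop("duplicate gene ids in input", "input")
  n <- nrow(genes)
  empty <- tibble(gene_a = character(0), gene_b = character(0),
                  percent_identity = numeric(0), coverage_longer = numeric(0),
                  evalue = numeric(0), score = numeric(0))
  if (n < 2) return(empty)
  seqs <- genes$seq
  ids <- genes$gene_id
  lens <- nchar(seqs)
  pairs <- candidate_pairs(seqs, prefilter)
  if (nrow(pairs) == 0) return(empty)
  xset <- Biostrings::AAStringSet(setNames(seqs, ids))

  out <- vector("list", n)
  for (j in sort(unique(pairs$j))) {
    is <- pairs$i[pairs$j == j]
    pwa <- Biostrings::pairwiseAlignment(
      xset[is], xset[[j]], type = "local",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    sc <- Biostrings::score(pwa)
    ident <- Biostrings::nmatch(pwa)
    pat <- Biostrings::pattern(pwa)
    alen <- nchar(as.character(pat))
    sub <- Biostrings::subject(pwa)
    span_i <- BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1L
    span_j <- BiocGenerics::end(sub) - BiocGenerics::start(sub) + 1L
    longer_span <- ifelse(lens[is] >= lens[j], span_i, span_j)
    pid <- ifelse(alen > 0, 100 * ident / alen, 0)
    cov <- longer_span / pmax(lens[is], lens[j])
    ev <- evalue(sc, lens[is], lens[j], scoring)
    ok <- alen > 0 & sc > 0 &
      pid >= clustering$min_identity &
      cov >= clustering$min_coverage &
      ev <= clustering$max_evalue
    if (any(ok)) {
      ia <- pmin(ids[is][ok], ids[j])
      ib <- pmax(ids[is][ok], ids[j])
      out[[j]] <- tibble(gene_a = ia, gene_b = ib,
                         percent_identity = pid[ok],
                         coverage_longer = cov[ok],
                         evalue = ev[ok], score = sc[ok])
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) return(empty)
  arrange(res, .data$gene_a, .data$gene_b)
}

#' Build gene families as connected components of the similarity graph
#'
#' Single-linkage families: the connected components of the accepted edge
#' set. Genes with no edges become size-1 families. A family's id is derived
#' from its lexicographically smallest member, so ids are deterministic under
#' input reordering.
#'
#' @param edges Edge tibble from [all_vs_all()].
#' @param genes Gene tibble (`genome_id`, `gene_id`, ...); every gene appears
#'   in exactly one family.
#' @return A `family_set`: tibble with columns `family_id`, `genome_id`,
#'   `gene_id`.
#' @export
build_families <- function(edges, genes) {
  ids <- genes$gene_id
  unknown <- setdiff(unique(c(edges$gene_a, edges$gene_b)), ids)
  if (length(unknown))
    pf_stop(paste0("edge references unknown gene(s): ",
                   paste(head(unknown, 3), collapse = ", ")), "input")
  g <- igraph::graph_from_data_frame(
    edges[c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  fam <- tibble(gene_id = ids, genome_id = genes$genome_id, comp = comp) %>%
    group_by(.data$comp) %>%
    mutate(family_id = paste0("fam|", min(.data$gene_id))) %>%
    ungroup() %>%
    select("family_id", "genome_id", "gene_id") %>%
    arrange(.data$family_id, .data$genome_id, .data$gene_id)
  class(fam) <- c("family_set", class(fam))
  fam
}

#' Presence/absence matrix from a family set
#'
#' @param families A `family_set` tibble (see [build_families()]).
#' @param genome_ids Full genome roster (columns); genomes with no assigned
#'   family get an all-zero column.
#' @return Presence/absence tibble: first column `family_id`, one integer
#'   occurrence-count column per genome.
#' @export
families_to_pa <- function(families, genome_ids = NULL) {
  if (is.null(genome_ids)) genome_ids <- sort(unique(families$genome_id))
  pa <- families %>% count(.data$family_id, .data$genome_id) %>%
    tidyr::pivot_wider(names_from = "genome_id", values_from = "n",
                       values_fill = 0L)
  for (g in setdiff(genome_ids, names(pa))) pa[[g]] <- 0L
  pa[c("family_id", genome_ids)] %>% arrange(.data$family_id)
}

#' Partition families into core, accessory and strain-specific
#'
#' Core families occur in every genome; strain-specific (singleton) families
#' occur in exactly one genome; accessory families are the rest. A core
#' family is additionally flagged single-copy when every genome carries
#' exactly one member (no paralogs).
#'
#' @param families A `family_set` tibble or a presence/absence tibble.
#' @param genome_ids Full genome roster (required when a genome can be absent
#'   from `families`; defaults to the genomes observed).
#' @return An object of class `pangenome_partition`: list with counts
#'   `n_core`, `n_accessory`, `n_strain_specific`, `pan_total`, the
#'   `per_genome_unique` tibble (`genome_id`, `n_unique`),
#'   `single_copy_core_ids`, and a per-family `classification` tibble
#'   (`family_id`, `class`, `n_genomes`, `total_members`, `is_single_copy`).
#' @export
classify_families <- function(families, genome_ids = NULL) {
  if (!is.null(names(families)) && names(families)[1] == "family_id" &&
      !"gene_id" %in% names(families)) {
    pa <- families  # already a presence/absence tibble
  } else {
    pa <- families_to_pa(families, genome_ids)
  }
  if (is.null(genome_ids)) genome_ids <- names(pa)[-1]
  if (length(genome_ids) == 0) pf_stop("empty genome roster", "input")
  if (!all(names(pa)[-1] %in% genome_ids))
    pf_stop("family genomes outside the genome roster", "input")
  m <- pa_as_matrix(pa[c("family_id", genome_ids)])
  n_present <- rowSums(m > 0)
  G <- length(genome_ids)
  cls <- dplyr::case_when(n_present == G ~ "core",
                          n_present == 1 ~ "strain_specific",
                          TRUE ~ "accessory")
  single_copy <- rowSums(m == 1) == G
  classification <- tibble(family_id = rownames(m), class = cls,
                           n_genomes = as.integer(n_present),
                           total_members = as.integer(rowSums(m)),
                           is_single_copy = single_copy)
  uniq <- m[cls == "strain_specific", , drop = FALSE]
  per_genome_unique <- tibble(genome_id = genome_ids,
                              n_unique = as.integer(colSums(uniq > 0)))
  structure(list(n_core = sum(cls == "core"),
                 n_accessory = sum(cls == "accessory"),
                 n_strain_specific = sum(cls == "strain_specific"),
                 pan_total = nrow(m),
                 per_genome_unique = per_genome_unique,
                 single_copy_core_ids =
                   sort(classification$family_id[cls == "core" & single_copy]),
                 classification = classification),
            class = "pangenome_partition")
}

#' @export
print.pangenome_partition <- function(x, ...) {
  cat(sprintf(paste0("<pangenome_partition> pan %d = core %d + accessory %d",
                     " + strain-specific %d (%d single-copy core)\n"),
              x$pan_total, x$n_core, x$n_accessory, x$n_strain_specific,
              length(x$single_copy_core_ids)))
  invisible(x)
}

#' @rdname classify_families
#' @param x A `pangenome_partition`.
#' @param ... Unused.
#' @method tidy pangenome_partition
#' @export
tidy.pangenome_partition <- function(x, ...) x$classification

#' @rdname classify_families
#' @method glance pangenome_partition
#' @export
glance.pangenome_partition <- function(x, ...) {
  tibble(pan_total = x$pan_total, n_core = x$n_core,
         n_accessory = x$n_accessory, n_strain_specific = x$n_strain_specific,
         n_single_copy_core = length(x$single_copy_core_ids))
}
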