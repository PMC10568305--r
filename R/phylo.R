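# Single-copy core genes -> corrected pairwise distances -> neighbor-joining
# tree -> Newick.
#
# Distances: for each genome pair, every single-copy core family contributes
# a global alignment; the per-family mismatch fraction p is pooled with
# alignment-length weights, then Poisson-corrected to -ln(1 - p)
# substitutions per site. NJ itself is the Saitou-Nei algorithm as
# implemented in ape; negative branch lengths are clamped to zero.

#' Extract single-copy core families
#'
#' Families present in every genome with exactly one member per genome,
#' in deterministic (sorted) order.
#'
#' @param families A `family_set` tibble (see [build_families()]) or a
#'   [classify_families()] result.
#' @param genome_ids Full genome roster.
#' @return Character vector of family ids (possibly empty).
#' @export
extract_single_copy_core <- function(families, genome_ids = NULL) {
  part <- if (inherits(families, "pangenome_partition")) families
          else classify_families(families, genome_ids)
  part$single_copy_core_ids
}

#' Pairwise genome distances from single-copy core genes
#'
#' @param genes Gene tibble (`genome_id`, `gene_id`, `seq`).
#' @param families A `family_set` tibble mapping genes to families.
#' @param family_ids Families to use; defaults to all single-copy core
#'   families of `families`.
#' @param scoring Protein [scoring_params()].
#' @param correction `"poisson"` (`-ln(1 - p)`) or `"p"` (raw p-distance).
#' @return An object of class `core_dist`: list with `d` (symmetric matrix,
#'   substitutions/site, zero diagonal; `Inf` where p >= 1), `p` (pooled
#'   uncorrected mismatch fractions), `taxa`, `family_ids`, `correction`.
#' @export
core_distances <- function(genes, families, family_ids = NULL,
                           scoring = scoring_params("protein"),
                           correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  taxa <- sort(unique(genes$genome_id))
  if (length(taxa) < 2) pf_stop("need at least 2 genomes", "input")
  if (is.null(family_ids))
    family_ids <- extract_single_copy_core(families, taxa)
  if (length(family_ids) == 0) pf_stop("no usable families", "input")
  memb <- families %>% filter(.data$family_id %in% family_ids) %>%
    left_join(genes, by = c("genome_id", "gene_id"))
  # gene sequence lookup: [family, genome] -> seq
  key <- split(setNames(memb$seq, memb$genome_id), memb$family_id)
  G <- length(taxa)
  dmat <- pmat <- matrix(0, G, G, dimnames = list(taxa, taxa))
  for (i in seq_len(G - 1)) for (j in (i + 1):G) {
    mism <- 0; tot <- 0
    for (f in family_ids) {
      sa <- key[[f]][[taxa[i]]]; sb <- key[[f]][[taxa[j]]]
      if (is.null(sa) || is.null(sb)) next
      aln <- align_global(sa, sb, scoring)
      mism <- mism + (aln$alignment_length - aln$identities)
      tot <- tot + aln$alignment_length
    }
    p <- if (tot > 0) mism / tot else NA_real_
    pmat[i, j] <- pmat[j, i] <- p
    d <- if (correction == "p") p
         else if (!is.na(p) && p >= 1) Inf else -log(1 - p)
    dmat[i, j] <- dmat[j, i] <- d
  }
  structure(list(d = dmat, p = pmat, taxa = taxa, family_ids = family_ids,
                 correction = correction), class = "core_dist")
}

#' @export
print.core_dist <- function(x, ...) {
  cat(sprintf("<core_dist> %d taxa from %d families (%s-corrected)\n",
              length(x$taxa), length(x$family_ids), x$correction))
  print(round(x$d, 5))
  invisible(x)
}

#' @rdname core_distances
#' @param x A `core_dist`.
#' @param ... Unused.
#' @method tidy core_dist
#' @export
tidy.core_dist <- function(x, ...) {
  df <- as_tibble(as.data.frame.table(x$d, stringsAsFactors = FALSE))
  names(df) <- c("genome_a", "genome_b", "distance")
  filter(df, df$genome_a < df$genome_b)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (Q-criterion); negative branch lengths are
#' clamped to zero and the total clamped deficit recorded in
#' `attr(tree, "clamped_deficit")`.
#'
#' @param dm A `core_dist` object, symmetric matrix, or `dist`.
#' @return An unrooted `phylo` tree (ape).
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' nj_tree(d)
#' @export
nj_tree <- function(dm) {
  m <- if (inherits(dm, "core_dist")) dm$d
       else if (inherits(dm, "dist")) as.matrix(dm)
       else dm
  if (!is.matrix(m) || nrow(m) < 3)
    pf_stop("neighbor joining needs at least 3 taxa", "input")
  if (any(!is.finite(m))) pf_stop("non-finite distances", "input")
  tree <- ape::nj(stats::as.dist(m))
  neg <- tree$edge.length < 0
  deficit <- -sum(tree$edge.length[neg])
  if (any(neg)) tree$edge.length[neg] <- 0
  attr(tree, "clamped_deficit") <- deficit
  tree
}

#' Serialize / parse Newick
#'
#' `write_newick()` renders a `phylo` tree as a Newick string (branch
#' lengths, ';'-terminated) and optionally writes it to a file;
#' `read_newick()` parses a Newick string or file. Round-tripping preserves
#' topology and branch lengths.
#'
#' @param tree A `phylo` object.
#' @param path Optional file path.
#' @return `write_newick()`: the Newick string (invisibly when `path` is
#'   given); `read_newick()`: a `phylo`.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname write_newick
#' @param text A Newick string (used when `path` is `NULL`).
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (!is.null(path) && !file.exists(path))
    pf_stop(paste0("file not found: ", path), "io")
  tree <- tryCatch({
    if (!is.null(path)) suppressWarnings(ape::read.tree(path))
    else suppressWarnings(ape::read.tree(text = text))
  }, error = function(e) NULL)
  if (is.null(tree)) pf_stop("malformed Newick", "io")
  tree
}

#' Family-resampling bootstrap support for an NJ tree
#'
#' Resamples single-copy core families with replacement, rebuilds the NJ
#' tree per replicate and reports, for each internal edge of the reference
#' tree, the proportion of replicates containing the same bipartition.
#'
#' @param genes,families,family_ids,scoring As in [core_distances()].
#' @param n_boot Number of replicates.
#' @param seed Integer seed.
#' @return The reference `phylo` with `node.label` set to support
#'   proportions (0-1).
#' @export
nj_bootstrap <- function(genes, families, family_ids = NULL,
                         scoring = scoring_params("protein"),
                         n_boot = 100L, seed = 1L) {
  taxa <- sort(unique(genes$genome_id))
  if (is.null(family_ids))
    family_ids <- extract_single_copy_core(families, taxa)
  ref <- nj_tree(core_distances(genes, families, family_ids, scoring))
  set.seed(as.integer(seed))
  reps <- lapply(seq_len(n_boot), function(b) {
    fams <- sample(family_ids, replace = TRUE)
    nj_tree(core_distances(genes, families, fams, scoring))
  })
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- counts / n_boot
  ref
}
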