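# Fragment-based average nucleotide identity (ANIb-style).
#
# The query assembly is cut into ~1020 bp fragments; each fragment is aligned
# to the subject (exact 15-mer seeding onto a modal diagonal, then local DP
# of the fragment against a windowed slice of the subject — contractually
# equivalent to full DP, which is also available as method = "full").
# Fragments are retained when the best hit has >= 30% identity over >= 70% of
# the fragment; directional ANI is the mean identity of retained fragments.

#' ANI parameters
#'
#' Defaults follow the BLAST-based ANI (ANIb) procedure: 1020 bp fragments,
#' retention at >= 30% identity and >= 70% fragment coverage, and a 95%
#' species threshold.
#'
#' @param fragment_length Fragment size in bp (>= 100).
#' @param min_fragment_identity Retention threshold, percent identity.
#' @param min_fragment_coverage Retention threshold, aligned fraction of the
#'   fragment.
#' @param species_threshold ANI above which two genomes are called the same
#'   species (percent).
#' @param scoring Nucleotide [scoring_params()].
#' @param method `"seeded"` (15-mer seeding + windowed local DP) or `"full"`
#'   (local DP of every fragment against the whole subject; exact but slow).
#' @return A list of class `ani_params`.
#' @export
ani_params <- function(fragment_length = 1020L, min_fragment_identity = 30,
                       min_fragment_coverage = 0.7, species_threshold = 95,
                       scoring = scoring_params("nucleotide"),
                       method = c("seeded", "full")) {
  if (fragment_length < 100) pf_stop("fragment_length must be >= 100", "input")
  if (min_fragment_identity < 0 || min_fragment_identity > 100 ||
      min_fragment_coverage < 0 || min_fragment_coverage > 1 ||
      species_threshold < 0 || species_threshold > 100)
    pf_stop("ANI thresholds out of range", "input")
  structure(list(fragment_length = as.integer(fragment_length),
                 min_fragment_identity = min_fragment_identity,
                 min_fragment_coverage = min_fragment_coverage,
                 species_threshold = species_threshold,
                 scoring = scoring, method = match.arg(method)),
            class = "ani_params")
}

#' Cut an assembly into consecutive fragments
#'
#' Non-overlapping windows per contig (0-based, half-open coordinates);
#' fragments never span contigs. A terminal remainder is kept iff >= 100 bp.
#'
#' @param records A `DNAStringSet`.
#' @param fragment_length Fragment size in bp.
#' @return A tibble: `fragment_id`, `contig`, `start`, `end`, `seq`.
#' @examples
#' x <- Biostrings::DNAStringSet(c(c1 = paste(rep("ACGT", 510), collapse = "")))
#' fragment_genome(x, 1020)
#' @export
fragment_genome <- function(records, fragment_length = 1020L) {
  if (length(records) == 0) pf_stop("empty input", "input")
  if (is.null(names(records)))
    names(records) <- paste0("contig", seq_along(records))
  out <- purrr::map_dfr(seq_along(records), function(i) {
    len <- Biostrings::width(records)[i]
    starts <- seq.int(0L, len - 1L, by = fragment_length)
    ends <- pmin(starts + fragment_length, len)
    keep <- (ends - starts) >= fragment_length | (ends - starts) >= 100L
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) return(NULL)
    tibble(contig = names(records)[i], start = starts, end = ends,
           seq = as.character(Biostrings::Views(records[[i]],
                                                start = starts + 1L,
                                                end = ends)))
  })
  out$fragment_id <- sprintf("frag%05d", seq_len(nrow(out)))
  out[c("fragment_id", "contig", "start", "end", "seq")]
}

# k-mer index of a subject string set: positions of every k-mer on the
# concatenated forward and reverse-complement strands
subject_index <- function(subject, k = 15L) {
  fwd <- paste(as.character(subject), collapse = strrep("N", k))
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd)))
  idx_one <- function(s, strand) {
    n <- nchar(s)
    if (n < k) return(NULL)
    km <- substring(s, 1:(n - k + 1L), k:n)
    ok <- !grepl("N", km, fixed = TRUE)
    data.table::data.table(kmer = km[ok], pos = which(ok), strand = strand)
  }
  tab <- data.table::rbindlist(list(idx_one(fwd, "+"), idx_one(rev, "-")))
  data.table::setkeyv(tab, "kmer")
  list(k = k, fwd = fwd, rev = rev, table = tab)
}

# best local alignment of one fragment against the subject via seeding;
# returns c(identity_pct, coverage, score) or NULL when nothing aligns
seeded_fragment_hit <- function(frag, index, scoring, band = 64L) {
  k <- index$k
  n <- nchar(frag)
  qpos <- unique(c(seq.int(1L, n - k + 1L, by = 8L), n - k + 1L))
  qk <- substring(frag, qpos, qpos + k - 1L)
  q <- data.table::data.table(kmer = qk, qpos = qpos)
  hits <- index$table[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0) return(NULL)
  hits <- as_tibble(hits)
  hits$diag <- hits$pos - hits$qpos
  # modal diagonal per strand, binned to tolerate indels
  hits$bin <- round(hits$diag / 32)
  top <- hits %>% count(.data$strand, .data$bin) %>%
    arrange(dplyr::desc(.data$n), .data$bin) %>% head(1)
  hh <- hits[hits$strand == top$strand & hits$bin == top$bin, ]
  diag <- stats::median(hh$diag)
  s <- if (top$strand == "+") index$fwd else index$rev
  from <- max(1L, as.integer(diag + 1L - band))
  to <- min(nchar(s), as.integer(diag + n + band))
  win <- substr(s, from, to)
  pwa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(gsub("N", "A", frag, fixed = TRUE)),
    Biostrings::DNAString(gsub("N", "A", win, fixed = TRUE)),
    type = "local", substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  pat <- Biostrings::pattern(pwa)
  alen <- nchar(as.character(pat))
  if (alen == 0 || Biostrings::score(pwa) <= 0) return(NULL)
  c(identity = 100 * Biostrings::nmatch(pwa) / alen,
    coverage = (BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1L) / n,
    score = Biostrings::score(pwa))
}

full_fragment_hit <- function(frag, subject, scoring) {
  best <- NULL
  for (i in seq_along(subject)) {
    pwa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(frag), subject[[i]], type = "local",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    rc <- Biostrings::pairwiseAlignment(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(frag)),
      subject[[i]], type = "local", substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    for (pwa_i in list(pwa, rc)) {
      sc <- Biostrings::score(pwa_i)
      if (is.null(best) || sc > best["score"]) {
        pat <- Biostrings::pattern(pwa_i)
        alen <- nchar(as.character(pat))
        if (alen > 0 && sc > 0)
          best <- c(identity = 100 * Biostrings::nmatch(pwa_i) / alen,
                    coverage = (BiocGenerics::end(pat) -
                                  BiocGenerics::start(pat) + 1L) / nchar(frag),
                    score = sc)
      }
    }
  }
  best
}

ani_direction <- function(query, subject, params) {
  frags <- fragment_genome(query, params$fragment_length)
  index <- if (params$method == "seeded") subject_index(subject) else NULL
  hits <- purrr::map(frags$seq, function(fr) {
    if (params$method == "seeded")
      seeded_fragment_hit(fr, index, params$scoring)
    else full_fragment_hit(fr, subject, params$scoring)
  })
  ok <- !vapply(hits, is.null, logical(1))
  ident <- vapply(hits[ok], `[[`, numeric(1), "identity")
  cov <- vapply(hits[ok], `[[`, numeric(1), "coverage")
  retained <- ident >= params$min_fragment_identity &
    cov >= params$min_fragment_coverage
  list(ani = if (any(retained)) mean(ident[retained]) else NA_real_,
       fragments_total = nrow(frags),
       fragments_retained = sum(retained))
}

#' Pairwise average nucleotide identity
#'
#' Computes directional ANI query-vs-subject and subject-vs-query plus their
#' arithmetic mean. When no fragment survives the retention filters the ANI
#' is reported as `NA` (undefined), never coerced to a number.
#'
#' @param query,subject Assemblies as `DNAStringSet`s.
#' @param params An [ani_params()] object.
#' @return An object of class `ani_result`: list with `ani_query_vs_subject`,
#'   `ani_subject_vs_query`, `ani_symmetric`, and per-direction
#'   `fragments_total` / `fragments_retained`.
#' @examples
#' p <- simulate_genome_pair(5000, 0.02, seed = 1)
#' ani_pair(p$a, p$b)
#' @export
ani_pair <- function(query, subject, params = ani_params()) {
  if (length(query) == 0 || length(subject) == 0)
    pf_stop("empty assembly", "input")
  qs <- ani_direction(query, subject, params)
  sq <- ani_direction(subject, query, params)
  sym <- if (is.na(qs$ani) || is.na(sq$ani)) NA_real_
         else (qs$ani + sq$ani) / 2
  structure(list(ani_query_vs_subject = qs$ani,
                 ani_subject_vs_query = sq$ani,
                 ani_symmetric = sym,
                 fragments_total = c(query_vs_subject = qs$fragments_total,
                                     subject_vs_query = sq$fragments_total),
                 fragments_retained = c(query_vs_subject = qs$fragments_retained,
                                        subject_vs_query = sq$fragments_retained)),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ani_result> %.2f / %.2f (symmetric %.2f); retained %d/%d and %d/%d fragments\n",
              x$ani_query_vs_subject, x$ani_subject_vs_query, x$ani_symmetric,
              x$fragments_retained[1], x$fragments_total[1],
              x$fragments_retained[2], x$fragments_total[2]))
  invisible(x)
}

#' @rdname ani_pair
#' @param x An `ani_result`.
#' @param ... Unused.
#' @method tidy ani_result
#' @export
tidy.ani_result <- function(x, ...) {
  tibble(direction = c("query_vs_subject", "subject_vs_query", "symmetric"),
         ani = c(x$ani_query_vs_subject, x$ani_subject_vs_query,
                 x$ani_symmetric))
}

#' All-vs-all ANI matrix and species clusters
#'
#' Symmetric ANI for every genome pair (diagonal 100) and species clusters as
#' the connected components of the graph whose edges join pairs with ANI
#' strictly above the species threshold. Undefined pairs (no retained
#' fragments) stay `NA` and are flagged.
#'
#' @param genomes Named list of `DNAStringSet` assemblies (>= 2).
#' @param params An [ani_params()] object.
#' @return An object of class `ani_matrix`: list with `ani` (symmetric
#'   numeric matrix), `clusters` (tibble `genome_id`, `cluster`), `pairs`
#'   (tibble of per-pair results) and `undefined_pairs`.
#' @export
ani_matrix <- function(genomes, params = ani_params()) {
  G <- length(genomes)
  if (G < 2) pf_stop("need at least 2 genomes", "input")
  ids <- names(genomes) %||% paste0("genome", seq_len(G))
  m <- matrix(NA_real_, G, G, dimnames = list(ids, ids))
  diag(m) <- 100
  pairs <- list()
  for (i in seq_len(G - 1)) for (j in (i + 1):G) {
    r <- ani_pair(genomes[[i]], genomes[[j]], params)
    m[i, j] <- m[j, i] <- r$ani_symmetric
    pairs[[length(pairs) + 1]] <-
      tibble(genome_a = ids[i], genome_b = ids[j],
             ani = r$ani_symmetric,
             ani_a_vs_b = r$ani_query_vs_subject,
             ani_b_vs_a = r$ani_subject_vs_query)
  }
  pairs <- bind_rows(pairs)
  und <- pairs[is.na(pairs$ani), c("genome_a", "genome_b")]
  adj <- !is.na(m) & m > params$species_threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  structure(list(ani = m,
                 clusters = tibble(genome_id = ids,
                                   cluster = as.integer(comp[ids])),
                 pairs = pairs, undefined_pairs = und,
                 species_threshold = params$species_threshold),
            class = "ani_matrix")
}

#' @export
print.ani_matrix <- function(x, ...) {
  cat(sprintf("<ani_matrix> %d genomes, %d species cluster(s) at > %.1f%%\n",
              nrow(x$ani), max(x$clusters$cluster), x$species_threshold))
  print(round(x$ani, 2))
  invisible(x)
}

#' @rdname ani_matrix
#' @param x An `ani_matrix`.
#' @param ... Unused.
#' @method tidy ani_matrix
#' @export
tidy.ani_matrix <- function(x, ...) x$pairs

#' ANI heatmap
#'
#' @param object An `ani_matrix`.
#' @param ... Unused.
#' @method autoplot ani_matrix
#' @export
autoplot.ani_matrix <- function(object, ...) {
  df <- as_tibble(as.data.frame.table(object$ani, stringsAsFactors = FALSE))
  names(df) <- c("genome_a", "genome_b", "ani")
  ggplot(df, aes(.data$genome_a, .data$genome_b, fill = .data$ani)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(min(object$ani, na.rm = TRUE), 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "ANI (%)")
}

#' Write an ANI matrix as TSV
#'
#' @param x An `ani_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ani_matrix <- function(x, path) {
  df <- as.data.frame(x$ani)
  df <- cbind(genome_id = rownames(x$ani), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}
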