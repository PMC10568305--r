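# FASTA reading/writing and assembly-level statistics.
#
# Sequences are carried as Biostrings XStringSet objects (DNAStringSet for
# nucleotide, AAStringSet for protein); everything tabular downstream is a
# tibble. Coordinates are 0-based, half-open throughout the package.

#' Read a FASTA file
#'
#' Reads a multi-record FASTA file into a [Biostrings::DNAStringSet] or
#' [Biostrings::AAStringSet]. Residues are uppercased, record order is
#' preserved, and every residue is validated against the declared alphabet
#' (IUPAC ambiguity codes are legal for nucleotide input).
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return An `XStringSet`; names are the FASTA identifiers (first
#'   whitespace-delimited token), with full headers kept in
#'   `attr(, "descriptions")`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 a toy record", "ACGT"), tf)
#' read_fasta(tf, "nucleotide")
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) pf_stop(paste0("FASTA file not found: ", path), "io")
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) pf_stop(paste0("empty FASTA file: ", path), "io")
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0)) {
    bad <- names(raw)[nchar(seqs) == 0][1]
    pf_stop(paste0("record with empty residues: '", bad, "'"), "io")
  }
  legal <- if (alphabet == "nucleotide") "ACGTUNRYSWKMBDHV" else
    "ACDEFGHIKLMNPQRSTVWYXBZJUO*"
  pat <- paste0("[^", legal, "]")
  hit <- regexpr(pat, seqs)
  if (any(hit > 0)) {
    i <- which(hit > 0)[1]
    pf_stop(sprintf("illegal %s residue '%s' in record '%s' at position %d",
                    alphabet, substr(seqs[i], hit[i], hit[i]),
                    names(raw)[i], hit[i]), "alphabet")
  }
  out <- if (alphabet == "nucleotide") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  desc <- names(raw)
  names(out) <- sub("\\s.*$", "", desc)
  attr(out, "descriptions") <- desc
  out
}

#' Write sequences to FASTA
#'
#' @param x An `XStringSet` (or named character vector of sequences).
#' @param path Output path.
#' @param width Line-wrap width (columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Assembly statistics: length, contigs, GC%, windowed GC skew
#'
#' Computes genome-level statistics from a nucleotide assembly. GC% is pooled
#' over all contigs and computed over unambiguous bases only (A/C/G/T;
#' ambiguity codes including N are excluded from numerator and denominator).
#' GC skew is computed per non-overlapping (or strided) window within each
#' contig as (G - C) / (G + C), with 0 where a window contains no G or C.
#'
#' @param records A `DNAStringSet` (see [read_fasta()]).
#' @param window Window size in bp for the GC-skew track.
#' @param step Step between window starts in bp.
#' @param genome_id Label recorded in the result.
#' @return An object of class `genome_stats`: a list with `genome_id`,
#'   `total_length`, `n_contigs`, `gc_percent`, `ambiguous_bases`, and
#'   `gc_skew`, a tibble with columns `contig`, `start`, `end` (0-based,
#'   half-open) and `skew`.
#' @examples
#' x <- Biostrings::DNAStringSet(c(chr = "ATGC"))
#' genome_stats(x)
#' @export
genome_stats <- function(records, window = 10000L, step = 10000L,
                         genome_id = "genome") {
  if (!is(records, "DNAStringSet")) {
    if (is(records, "AAStringSet"))
      pf_stop("genome_stats requires nucleotide records, got protein", "alphabet")
    records <- Biostrings::DNAStringSet(records)
  }
  if (length(records) == 0) pf_stop("empty record set", "input")
  if (window < 1 || step < 1) pf_stop("window and step must be >= 1", "input")
  base_counts <- Biostrings::letterFrequency(records, c("A", "C", "G", "T"))
  widths <- Biostrings::width(records)
  acgt <- sum(base_counts)
  gc <- sum(base_counts[, c("C", "G")])
  skew <- purrr::map_dfr(seq_along(records), function(i) {
    len <- widths[i]
    starts <- seq.int(1L, len, by = step)
    ends <- pmin(starts + window - 1L, len)
    v <- Biostrings::Views(records[[i]], start = starts, end = ends)
    cnt <- Biostrings::letterFrequency(v, c("G", "C"))
    g <- cnt[, "G"]; c_ <- cnt[, "C"]
    tibble(contig = names(records)[i] %||% as.character(i),
           start = starts - 1L, end = ends,
           skew = ifelse(g + c_ == 0, 0, (g - c_) / (g + c_)))
  })
  structure(list(genome_id = genome_id,
                 total_length = sum(widths),
                 n_contigs = length(records),
                 gc_percent = 100 * gc / acgt,
                 ambiguous_bases = sum(widths) - acgt,
                 gc_skew = skew,
                 window = as.integer(window), step = as.integer(step)),
            class = "genome_stats")
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a
}

#' @export
print.genome_stats <- function(x, ...) {
  cat(sprintf("<genome_stats> %s: %s bp in %d contig(s), GC %.2f%%, %d ambiguous\n",
              x$genome_id, format(x$total_length, big.mark = ","), x$n_contigs,
              x$gc_percent, x$ambiguous_bases))
  invisible(x)
}

#' @rdname genome_stats
#' @param x A `genome_stats` object.
#' @param ... Unused.
#' @method tidy genome_stats
#' @export
tidy.genome_stats <- function(x, ...) {
  tibble(genome_id = x$genome_id, total_length = x$total_length,
         n_contigs = x$n_contigs, gc_percent = x$gc_percent,
         ambiguous_bases = x$ambiguous_bases)
}

#' GC-skew track plot
#'
#' @param object A `genome_stats` object.
#' @param ... Unused.
#' @method autoplot genome_stats
#' @export
autoplot.genome_stats <- function(object, ...) {
  ggplot(object$gc_skew, aes(x = (.data$start + .data$end) / 2,
                             y = .data$skew)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~contig, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "(G - C)/(G + C)",
                  title = paste0("GC skew: ", object$genome_id))
}

#' Write / read a presence-absence matrix as TSV
#'
#' The presence/absence matrix is a tibble whose first column is `family_id`
#' and whose remaining columns are per-genome integer occurrence counts.
#' `read_pa_matrix(write_pa_matrix(m, f))` is the identity.
#'
#' @param matrix A presence/absence tibble (first column `family_id`).
#' @param path Output / input TSV path.
#' @return `write_pa_matrix()` returns `path` invisibly; `read_pa_matrix()`
#'   returns the tibble.
#' @export
write_pa_matrix <- function(matrix, path) {
  if (nrow(matrix) == 0 && ncol(matrix) <= 1)
    pf_stop("presence/absence matrix is empty", "input")
  stopifnot(names(matrix)[1] == "family_id")
  num <- matrix[-1]
  if (!all(vapply(num, function(v) all(v == as.integer(v)), logical(1))))
    pf_stop("presence/absence counts must be integers", "input")
  readr::write_tsv(matrix, path)
  invisible(path)
}

#' @rdname write_pa_matrix
#' @export
read_pa_matrix <- function(path) {
  if (!file.exists(path)) pf_stop(paste0("file not found: ", path), "io")
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(m)[1] != "family_id")
    pf_stop("first column must be 'family_id'", "io")
  prob <- readr::problems(m)
  if (nrow(prob) > 0)
    pf_stop(paste0("malformed TSV (row ", prob$row[1], "): ragged or non-tabular"), "io")
  num <- m[-1]
  bad <- !vapply(num, is.numeric, logical(1)) |
    vapply(num, function(v) any(v != as.integer(v) | is.na(v)), logical(1))
  if (any(bad))
    pf_stop(paste0("non-integer cells in column(s): ",
                   paste(names(num)[bad], collapse = ", ")), "io")
  m[-1] <- lapply(num, as.integer)
  m$family_id <- as.character(m$family_id)
  m
}

# internal: pa tibble -> integer matrix (families x genomes)
pa_as_matrix <- function(pa) {
  m <- as.matrix(pa[-1])
  storage.mode(m) <- "integer"
  rownames(m) <- pa$family_id
  m
}
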