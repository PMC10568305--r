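# Pairwise alignment, percent identity / coverage, and Karlin-Altschul
# e-values. Alignment itself is delegated to Biostrings::pairwiseAlignment
# (Needleman-Wunsch / Smith-Waterman with affine gaps); a gap of length L
# costs gap_open + L * gap_extend.

#' Scoring parameters for pairwise alignment
#'
#' Protein defaults are BLOSUM62 with gap open 11 / extend 1 and the gapped
#' BLOSUM62 Karlin-Altschul constants (lambda = 0.267, K = 0.041). Nucleotide
#' defaults are match +2 / mismatch -3 with gap open 5 / extend 2.
#'
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param matrix_name Substitution matrix name (protein only; any matrix
#'   shipped with Biostrings, e.g. `"BLOSUM62"`, `"PAM250"`).
#' @param match,mismatch Nucleotide match/mismatch scores.
#' @param gap_open,gap_extend Positive gap penalties.
#' @param lambda,K Karlin-Altschul scale and constant used by [evalue()].
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(alphabet = c("protein", "nucleotide"),
                           matrix_name = "BLOSUM62",
                           match = 2, mismatch = -3,
                           gap_open = NULL, gap_extend = NULL,
                           lambda = 0.267, K = 0.041) {
  alphabet <- match.arg(alphabet)
  if (is.null(gap_open)) gap_open <- if (alphabet == "protein") 11 else 5
  if (is.null(gap_extend)) gap_extend <- if (alphabet == "protein") 1 else 2
  if (gap_open <= 0 || gap_extend <= 0) pf_stop("gap penalties must be > 0", "input")
  if (lambda <= 0 || K <= 0) pf_stop("lambda and K must be > 0", "input")
  mat <- if (alphabet == "protein") {
    e <- new.env()
    utils::data(list = matrix_name, package = "Biostrings", envir = e)
    get(matrix_name, envir = e)
  } else {
    Biostrings::nucleotideSubstitutionMatrix(match = match,
                                             mismatch = mismatch,
                                             baseOnly = TRUE)
  }
  structure(list(alphabet = alphabet, matrix_name = matrix_name,
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, matrix = mat),
            class = "scoring_params")
}

as_xss <- function(x, alphabet) {
  ctor <- if (alphabet == "protein") Biostrings::AAStringSet
          else Biostrings::DNAStringSet
  if (is.character(x)) ctor(x)
  else if (is(x, "XString")) ctor(as.character(x))
  else if (is(x, "XStringSet")) x
  else pf_stop("sequence must be character or XString(Set)", "input")
}

# shared driver; `b` is a single sequence, `a` may be a set (vectorized)
align_engine <- function(a, b, scoring, type) {
  aa <- as_xss(a, scoring$alphabet)
  bb <- as_xss(b, scoring$alphabet)
  if (any(Biostrings::width(aa) == 0) || any(Biostrings::width(bb) == 0))
    pf_stop("empty sequence", "input")
  Biostrings::pairwiseAlignment(
    aa, bb[[1]], type = type, substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
}

aln_result <- function(pwa, type, i = 1L) {
  sc <- Biostrings::score(pwa)[i]
  pat <- Biostrings::pattern(pwa)
  sub <- Biostrings::subject(pwa)
  ga <- as.character(pat)[i]
  gb <- as.character(sub)[i]
  alen <- nchar(ga)
  if (type == "local" && (sc < 0 || alen == 0)) {
    # true Smith-Waterman allows the empty alignment at score 0
    return(structure(list(score = 0, identities = 0L, alignment_length = 0L,
                          span_a = c(0L, 0L), span_b = c(0L, 0L),
                          aligned_a = "", aligned_b = ""),
                     class = "alignment_result"))
  }
  structure(list(
    score = sc,
    identities = Biostrings::nmatch(pwa)[i],
    alignment_length = alen,
    span_a = c(BiocGenerics::start(pat)[i] - 1L, BiocGenerics::end(pat)[i]),
    span_b = c(BiocGenerics::start(sub)[i] - 1L, BiocGenerics::end(sub)[i]),
    aligned_a = ga, aligned_b = gb), class = "alignment_result")
}

#' Global (Needleman-Wunsch) pairwise alignment
#'
#' Optimal global alignment with affine gap penalties. Spans are 0-based,
#' half-open coordinates on each input sequence.
#'
#' @param a,b Sequences (character, `XString`, or length-1 `XStringSet`) over
#'   the alphabet of `scoring`.
#' @param scoring A [scoring_params()] object.
#' @return An object of class `alignment_result`: list with `score`,
#'   `identities`, `alignment_length` (columns, gap columns included),
#'   `span_a`, `span_b`, `aligned_a`, `aligned_b`.
#' @examples
#' align_global("MKV", "MKV", scoring_params("protein"))
#' @export
align_global <- function(a, b, scoring = scoring_params("protein")) {
  pwa <- align_engine(a, b, scoring, "global")
  aln_result(pwa, "global")
}

#' Local (Smith-Waterman) pairwise alignment
#'
#' As [align_global()] but local; the empty alignment (score 0) is returned
#' when no positive-scoring pair of segments exists.
#'
#' @inheritParams align_global
#' @return An `alignment_result` (see [align_global()]).
#' @export
align_local <- function(a, b, scoring = scoring_params("protein")) {
  pwa <- align_engine(a, b, scoring, "local")
  aln_result(pwa, "local")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> score %.1f, %d/%d identities\n  a[%d,%d): %s\n  b[%d,%d): %s\n",
              x$score, x$identities, x$alignment_length,
              x$span_a[1], x$span_a[2], x$aligned_a,
              x$span_b[1], x$span_b[2], x$aligned_b))
  invisible(x)
}

#' Karlin-Altschul e-value
#'
#' `E = K * m * n * exp(-lambda * score)` for a raw alignment score against
#' sequences of lengths `m` and `n`. Strictly decreasing in score, linear in
#' each length.
#'
#' @param score Raw alignment score (vectorized).
#' @param m,n Sequence lengths (>= 1).
#' @param scoring A [scoring_params()] supplying `lambda` and `K`.
#' @return Numeric e-value(s).
#' @examples
#' evalue(40, 100, 100, scoring_params("protein"))
#' @export
evalue <- function(score, m, n, scoring = scoring_params("protein")) {
  if (any(m < 1) || any(n < 1)) pf_stop("m and n must be >= 1", "input")
  scoring$K * m * n * exp(-scoring$lambda * score)
}

#' Percent identity and coverage of the longer sequence
#'
#' Percent identity uses all alignment columns (gap columns included) as the
#' denominator. Coverage is the aligned span on the *longer* of the two input
#' sequences divided by that sequence's length.
#'
#' @param aln An `alignment_result`.
#' @param len_a,len_b Full lengths of the two input sequences.
#' @return A tibble with `percent_identity` (in \[0,100\]) and
#'   `coverage_longer` (in \[0,1\]).
#' @export
edge_metrics <- function(aln, len_a, len_b) {
  if (aln$alignment_length == 0)
    pf_stop("zero-length alignment has no identity", "input")
  span <- if (len_a >= len_b) aln$span_a else aln$span_b
  tibble(percent_identity = 100 * aln$identities / aln$alignment_length,
         coverage_longer = (span[2] - span[1]) / max(len_a, len_b))
}
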