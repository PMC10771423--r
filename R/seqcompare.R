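# Pairwise global alignment and percent identity for homolog triage.
# The alignment engine is Needleman-Wunsch global alignment with BLOSUM62,
# gap open 10 / gap extend 0.5 (via Biostrings); identity statistics are
# computed from the aligned strings.

AA_ALPHABET_STRICT <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]

#' Global pairwise alignment with percent identity
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gaps
#' (open 10, extend 0.5). Percent identity uses gap-free aligned columns as
#' the denominator (closest to the "identities / aligned length" convention
#' for near-full-length homologs); alternative denominators are available.
#'
#' @param a,b Protein sequences (single strings over the 20 amino-acid
#'   letters; `X` is allowed and scores 0).
#' @param denominator `"aligned_columns"` (default: columns where neither
#'   sequence is gapped), `"alignment_length"` (all columns) or
#'   `"shorter_sequence"`.
#' @return A one-row tibble (`alignment_result`): `aligned_a`, `aligned_b`,
#'   `score`, `identities`, `aligned_columns`, `percent_identity`.
#' @export
global_align <- function(a, b, denominator = c("aligned_columns",
                                               "alignment_length",
                                               "shorter_sequence")) {
  denominator <- match.arg(denominator)
  check_seq <- function(s, what) {
    if (!is.character(s) || length(s) != 1 || nchar(s) == 0) {
      abort(sprintf("%s must be a single non-empty sequence string", what))
    }
    s <- toupper(s)
    bad <- setdiff(strsplit(s, "")[[1]], AA_ALPHABET_STRICT)
    if (length(bad) > 0) {
      abort(sprintf("illegal residue character(s) in %s: %s", what,
                    paste(unique(bad), collapse = ", ")))
    }
    s
  }
  a <- check_seq(a, "a")
  b <- check_seq(b, "b")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 0.5
  )
  sa <- as.character(Biostrings::alignedPattern(aln))
  sb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(sa, "")[[1]]
  cb <- strsplit(sb, "")[[1]]
  no_gap <- ca != "-" & cb != "-"
  identities <- sum(ca == cb & no_gap)
  aligned_cols <- sum(no_gap)
  denom <- switch(denominator,
    aligned_columns = aligned_cols,
    alignment_length = length(ca),
    shorter_sequence = min(nchar(a), nchar(b))
  )
  out <- tibble(
    aligned_a = sa, aligned_b = sb,
    score = Biostrings::score(aln),
    identities = identities,
    aligned_columns = aligned_cols,
    percent_identity = 100 * identities / denom
  )
  class(out) <- c("alignment_result", class(out))
  out
}

#' Filter homolog candidates by percent identity to a query
#'
#' Strictly-greater-than threshold (candidates sharing more than `threshold`
#' percent identity with the query are retained); output preserves input
#' order.
#'
#' @param query Query sequence string.
#' @param candidates Named character vector (or tibble with `id`,
#'   `sequence`) of candidate sequences.
#' @param threshold Percent identity threshold (default 60).
#' @return A tibble with `id`, `percent_identity`, `retained`.
#' @export
homolog_filter <- function(query, candidates, threshold = 60) {
  if (is.data.frame(candidates)) {
    ids <- candidates$id
    seqs <- candidates$sequence
  } else {
    ids <- names(candidates) %||% as.character(seq_along(candidates))
    seqs <- unname(candidates)
  }
  pid <- vapply(seqs, function(s) global_align(query, s)$percent_identity, 0)
  tibble(id = ids, percent_identity = unname(pid),
         retained = unname(pid) > threshold)
}
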