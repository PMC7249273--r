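# Shared alignment engine. Global affine-gap alignment, local alignment
# scoring, gapped percent identity, and reference-anchored star alignment.
# The dynamic programming itself is delegated to Biostrings; this module owns
# the conventions (scores, gap model, identity definition) used everywhere in
# the pipeline.

sp_default_scores <- function(match = 1, mismatch = -1, gap_open = 3, gap_extend = 1) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

sp_submat <- function(scores) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = scores$match, mismatch = scores$mismatch, baseOnly = FALSE)
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman–Wunsch with affine gap penalties: a gap of length L costs
#' `gap_open + gap_extend * L`; terminal gaps are penalized. Used to project
#' contigs onto their locus reference and as the elementary step of
#' [star_align()].
#'
#' @param a,b ungapped nucleotide strings.
#' @param scores scoring scheme from `sp_scores()`.
#' @return list with equal-length gapped strings `a`, `b` and the optimal
#'   `score`.
#' @examples
#' align_pair("ACGT", "AGT")
#' @export
align_pair <- function(a, b, scores = sp_scores()) {
  if (!nzchar(a) || !nzchar(b)) abort("align_pair: empty sequence")
  if (grepl("-", paste0(a, b), fixed = TRUE)) abort("align_pair: inputs must be ungapped")
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = sp_submat(scores),
    gapOpening = scores$gap_open, gapExtension = scores$gap_extend)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Alignment scoring scheme
#'
#' @param match,mismatch per-column substitution scores.
#' @param gap_open,gap_extend affine gap costs (a length-L gap costs
#'   `gap_open + gap_extend * L`).
#' @return a named list consumed by the alignment functions.
#' @export
sp_scores <- sp_default_scores

#' Best local alignments of queries against one subject
#'
#' Smith–Waterman scores for a set of query sequences against a single
#' subject, with per-hit identity and span. This is the engine behind
#' reciprocal-best-hit search and the organelle/decoy screens.
#'
#' @param queries character vector of query sequences.
#' @param subject single subject sequence.
#' @param scores scoring scheme.
#' @param both_strands also align the reverse complement of each query and
#'   keep the better strand.
#' @return tibble, one row per query: `score`, `identity_pct` (matches over
#'   alignment columns), `aln_len` (columns), `subject_start`, `subject_end`
#'   (0-based half-open), `query_start`, `query_end`, `strand`.
#' @export
local_align <- function(queries, subject, scores = sp_scores(), both_strands = FALSE) {
  one_pass <- function(qs) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(qs), Biostrings::DNAString(subject),
      type = "local", substitutionMatrix = sp_submat(scores),
      gapOpening = scores$gap_open, gapExtension = scores$gap_extend)
    pat <- Biostrings::pattern(aln)
    sub <- Biostrings::subject(aln)
    ncol_aln <- nchar(as.character(pat))
    tibble(score = Biostrings::score(aln),
           identity_pct = 100 * Biostrings::nmatch(aln) / pmax(ncol_aln, 1),
           aln_len = ncol_aln,
           subject_start = Biostrings::start(sub) - 1L,
           subject_end = Biostrings::end(sub),
           query_start = Biostrings::start(pat) - 1L,
           query_end = Biostrings::end(pat))
  }
  fwd <- one_pass(queries)
  fwd$strand <- "+"
  if (!both_strands) return(fwd)
  rev <- one_pass(revcomp(queries))
  rev$strand <- "-"
  take_rev <- rev$score > fwd$score
  out <- fwd
  out[take_rev, ] <- rev[take_rev, ]
  # query coordinates of '-' hits are on the reverse-complemented query
  out
}

#' Gapped percent identity between two aligned rows
#'
#' Identity over *all* alignment columns: matching, non-gap columns divided by
#' the total number of columns, so internal gaps and trailing ends both count
#' against identity. A short contig globally aligned to a long reference
#' therefore scores low even where the overlap is perfect, mirroring how
#' capture-evaluation identity is reported.
#'
#' @param row_a,row_b equal-length gapped strings.
#' @return percentage in `[0, 100]`.
#' @examples
#' percent_identity_gapped("AC-GT", "ACTGT")  # 80
#' @export
percent_identity_gapped <- function(row_a, row_b) {
  if (nchar(row_a) != nchar(row_b)) {
    abort("percent_identity_gapped: rows must be equal length")
  }
  if (nchar(row_a) == 0) abort("percent_identity_gapped: zero-length alignment")
  a <- strsplit(row_a, "", fixed = TRUE)[[1]]
  b <- strsplit(row_b, "", fixed = TRUE)[[1]]
  100 * sum(a == b & a != "-") / length(a)
}

#' Reference-anchored star alignment
#'
#' Aligns every sequence pairwise to a designated reference (global, affine
#' gaps) and projects all rows into a common column space. Reference columns
#' are preserved in order; insertions relative to the reference open gap
#' blocks whose width is the longest insertion observed at that point.
#' A lightweight stand-in for a full progressive aligner, adequate for
#' reference-guided template curation.
#'
#' @param seqs tibble with columns `id`, `seq` (ungapped), including the
#'   reference.
#' @param ref_id id of the reference row.
#' @param scores scoring scheme.
#' @return object of class `star_alignment`: list with `rows` (named
#'   character vector of equal-length gapped strings), `ref_id`, and
#'   `ref_intervals` (tibble `id`, `ref_start`, `ref_end`: 0-based half-open
#'   span of each row on reference coordinates).
#' @export
star_align <- function(seqs, ref_id, scores = sp_scores()) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  if (!ref_id %in% seqs$id) abort(sprintf("reference '%s' not among sequences", ref_id))
  if (anyDuplicated(seqs$id)) abort("duplicate sequence ids in star_align")
  ref_seq <- seqs$seq[seqs$id == ref_id]
  L <- nchar(ref_seq)
  others <- seqs[seqs$id != ref_id, , drop = FALSE]

  # Per row: chars at each reference position (or '-'), plus insertion
  # strings keyed by the reference position they precede (0..L).
  parse_row <- function(seq) {
    pr <- align_pair(seq, ref_seq, scores = scores)
    p <- strsplit(pr$a, "", fixed = TRUE)[[1]]
    s <- strsplit(pr$b, "", fixed = TRUE)[[1]]
    is_ref <- s != "-"
    at_ref <- p[is_ref]                      # length L, in order
    refpos_after <- cumsum(is_ref)           # insertions precede position refpos_after
    ins <- character(L + 1)
    if (any(!is_ref)) {
      ins_chars <- split(p[!is_ref], refpos_after[!is_ref])
      ins[as.integer(names(ins_chars)) + 1L] <-
        vapply(ins_chars, paste, character(1), collapse = "")
    }
    covered <- which(at_ref != "-")
    list(at_ref = at_ref, ins = ins,
         ref_start = if (length(covered)) covered[1] - 1L else NA_integer_,
         ref_end = if (length(covered)) covered[length(covered)] else NA_integer_)
  }

  parsed <- lapply(others$seq, parse_row)
  ins_width <- rep(0L, L + 1)
  for (pr in parsed) ins_width <- pmax(ins_width, nchar(pr$ins))

  pad <- function(s, w) paste0(s, strrep("-", w - nchar(s)))
  build_row <- function(at_ref, ins) {
    pieces <- character(2 * L + 1)
    pieces[seq(1, 2 * L + 1, by = 2)] <-
      ifelse(ins_width > 0, mapply(pad, ins, ins_width), "")
    pieces[seq(2, 2 * L, by = 2)] <- at_ref
    paste(pieces, collapse = "")
  }

  rows <- c(setNames(build_row(strsplit(ref_seq, "", fixed = TRUE)[[1]],
                               character(L + 1)), ref_id),
            setNames(vapply(parsed, function(pr) build_row(pr$at_ref, pr$ins),
                            character(1)), others$id))
  rows <- rows[seqs$id]  # original order

  ref_intervals <- tibble(
    id = c(ref_id, others$id),
    ref_start = c(0L, vapply(parsed, function(p) p$ref_start, integer(1))),
    ref_end = c(L, vapply(parsed, function(p) p$ref_end, integer(1))))
  ref_intervals <- ref_intervals[match(seqs$id, ref_intervals$id), ]

  structure(list(rows = rows, ref_id = ref_id, ref_intervals = ref_intervals),
            class = "star_alignment")
}

#' @export
print.star_alignment <- function(x, ...) {
  cat(sprintf("star_alignment: %d rows x %d columns (reference: %s)\n",
              length(x$rows), nchar(x$rows[1]), x$ref_id))
  invisible(x)
}
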