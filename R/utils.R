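# Shared helpers: alphabet handling, rounding, reverse complement.

# IUPAC nucleotide codes (uppercase) plus gap; 'U' is normalized to 'T' on read.
sp_iupac <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
              "V", "H", "D", "B", "N")

# code -> compatible unambiguous bases, alphabetical
sp_iupac_map <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

#' Round half away from zero
#'
#' Fixed-point rounding with halves going up, matching how percentages are
#' conventionally reported in summary tables (in contrast to [round()]'s
#' round-half-to-even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(c(0.25, 0.35), 1)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # epsilon guards against binary representation of decimals like 9.45
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of (possibly IUPAC-ambiguous) nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Normalize raw sequence text: uppercase, RNA 'U' -> 'T'.
sp_normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# Validate sequence alphabet. `allow_gap` admits '-' (alignment rows only).
sp_check_alphabet <- function(seqs, ids, allow_gap = FALSE, context = "sequence") {
  pat <- if (allow_gap) paste0("[^", paste(sp_iupac, collapse = ""), "\\-]")
         else paste0("[^", paste(sp_iupac, collapse = ""), "]")
  bad <- stringr::str_detect(seqs, pat)
  if (any(bad)) {
    abort(sprintf("invalid character in %s '%s'", context, ids[which(bad)[1]]))
  }
  invisible(TRUE)
}

# 0-based half-open interval validator used across modules.
sp_check_interval <- function(start, end, len, what = "interval") {
  ok <- !is.na(start) & !is.na(end) & start >= 0 & end >= start & end <= len
  if (!all(ok)) {
    i <- which(!ok)[1]
    abort(sprintf("%s [%s, %s) out of bounds for length %s",
                  what, start[i], end[i], len[i]))
  }
  invisible(TRUE)
}

# Seed helper: derive a stream-specific 32-bit seed from a base seed.
sp_derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
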