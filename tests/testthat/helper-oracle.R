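# Independent oracles used to cross-check the alignment engine and the
# reciprocal-best-hit logic. Deliberately naive implementations.

# Exhaustive enumeration of every global alignment (affine gaps, end gaps
# penalized): recursion over (i, j, previous move). Exponential; for
# sequences of length <= 5 only.
oracle_enum_score <- function(a, b, scores = sp_scores()) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  na_ <- length(av); nb <- length(bv)
  gap_cost <- function(prev, move) {
    scores$gap_extend + if (prev == move) 0 else scores$gap_open
  }
  rec <- function(i, j, prev) {
    if (i == na_ && j == nb) return(0)
    best <- -Inf
    if (i < na_ && j < nb) {
      s <- if (av[i + 1] == bv[j + 1]) scores$match else scores$mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i < na_) best <- max(best, -gap_cost(prev, "X") + rec(i + 1, j, "X"))
    if (j < nb) best <- max(best, -gap_cost(prev, "Y") + rec(i, j + 1, "Y"))
    best
  }
  rec(0, 0, "M")
}

# Gotoh three-state dynamic program, written independently of the package's
# engine: global alignment, affine gaps (length-L gap costs open + ext * L),
# end gaps penalized.
oracle_gotoh_score <- function(a, b, scores = sp_scores()) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  open <- scores$gap_open; ext <- scores$gap_extend
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # a consumed, gap in b
  Y <- matrix(NEG, n + 1, m + 1)  # b consumed, gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -open - ext * i
  for (j in seq_len(m)) Y[1, j + 1] <- -open - ext * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) scores$match else scores$mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext,
                             X[i + 1, j] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# All-vs-all reciprocal-best-hit oracle: full Smith-Waterman score matrix via
# a direct Biostrings call, then the best-hit/reciprocity logic derived from
# first principles (unique argmax in both directions, both >= min_score).
oracle_rbh <- function(set_a, set_b, min_score, scores = sp_scores()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scores$match, mismatch = scores$mismatch, baseOnly = FALSE)
  sm <- matrix(NA_real_, nrow(set_a), nrow(set_b))
  for (i in seq_len(nrow(set_a))) {
    for (j in seq_len(nrow(set_b))) {
      sm[i, j] <- Biostrings::pairwiseAlignment(
        set_a$seq[i], set_b$seq[j], type = "local",
        substitutionMatrix = mat, gapOpening = scores$gap_open,
        gapExtension = scores$gap_extend, scoreOnly = TRUE)
    }
  }
  out <- list()
  for (i in seq_len(nrow(set_a))) {
    jj <- which(sm[i, ] == max(sm[i, ]))
    if (length(jj) != 1) next
    ii <- which(sm[, jj] == max(sm[, jj]))
    if (length(ii) != 1 || ii != i) next
    if (sm[i, jj] < min_score) next
    out[[length(out) + 1]] <- data.frame(id_a = set_a$id[i], id_b = set_b$id[jj])
  }
  if (length(out)) do.call(rbind, out)[order(sapply(out, `[[`, "id_a")), ]
  else data.frame(id_a = character(), id_b = character())
}

# Random sequence helpers for property tests.
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

mutate_at_rate <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}
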