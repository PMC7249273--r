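# Tier 1: select putatively single-copy nuclear (SCN) loci from
# transcriptomes cross-referenced with curated single-copy gene lists from
# reference genomes, deduplicate loci retrieved via both genomes with a
# reciprocal-best-hit search, and merge in universal / published / functional
# locus sets.
#
# Candidate sets are tidy: one row per (locus, transcriptome) hit with
# columns locus_id, genome_origin, transcriptome, transcript_id, seq.

#' Filter candidate loci on minimum gene length
#'
#' A candidate locus is kept iff its longest transcript hit is at least
#' `min_len` bp (inclusive).
#'
#' @param candidates tibble with one row per (locus, transcriptome) hit:
#'   columns `locus_id`, `transcript_id`, `seq` (others pass through).
#' @param min_len minimum gene length in bp; default 500.
#' @return the candidate tibble restricted to kept loci (all their hits).
#' @export
filter_min_gene_length <- function(candidates, min_len = 500) {
  if (nrow(candidates) == 0) return(candidates)
  keep <- candidates |>
    group_by(.data$locus_id) |>
    summarise(longest = max(nchar(.data$seq)), .groups = "drop") |>
    filter(.data$longest >= min_len) |>
    pull("locus_id")
  candidates[candidates$locus_id %in% keep, , drop = FALSE]
}

#' Exon/intron structure filter for probe-friendly loci
#'
#' A gene model passes iff every exon is strictly longer than `min_exon` and
#' every intron strictly shorter than `max_intron` (boundary values fail).
#' Short exons cannot anchor a full probe; long introns break tiling across
#' the locus.
#'
#' @param exon_lengths integer vector of exon lengths (bp), in order.
#' @param intron_lengths integer vector of intron lengths (bp); empty for
#'   single-exon transcripts.
#' @param min_exon exon-length threshold (bp), exclusive.
#' @param max_intron intron-length threshold (bp), exclusive.
#' @return `TRUE` if the model passes.
#' @examples
#' exon_intron_filter(c(150, 200), 80)        # TRUE
#' exon_intron_filter(c(119, 300), 50)        # FALSE: exon not > 120
#' @export
exon_intron_filter <- function(exon_lengths, intron_lengths = integer(0),
                               min_exon = 120, max_intron = 100) {
  stopifnot(length(exon_lengths) >= 1,
            length(intron_lengths) == length(exon_lengths) - 1)
  all(exon_lengths > min_exon) && all(intron_lengths < max_intron)
}

#' Apply the exon/intron filter across a gene-model table
#'
#' @param models tibble from [read_gene_models()].
#' @inheritParams exon_intron_filter
#' @return `models` with a logical `structure_ok` column.
#' @export
filter_gene_models <- function(models, min_exon = 120, max_intron = 100) {
  models$structure_ok <- purrr::map2_lgl(
    models$exon_lengths, models$intron_lengths,
    exon_intron_filter, min_exon = min_exon, max_intron = max_intron)
  models
}

#' Choose the representative transcript for a locus
#'
#' The longest hit wins; on an exact length tie the hit from
#' `default_name` is chosen. If the tie does not involve `default_name`, the
#' lexicographically smallest source name is used (with a warning) so the
#' choice stays deterministic.
#'
#' @param hits tibble with one row per transcriptome hit: columns
#'   `transcriptome`, `transcript_id`, `seq`.
#' @param default_name transcriptome preferred on ties.
#' @return single-row tibble: the winning hit, with a `rep_source` column
#'   recording which transcriptome supplied it.
#' @export
choose_representative <- function(hits, default_name = NULL) {
  stopifnot(nrow(hits) >= 1)
  len <- nchar(hits$seq)
  top <- which(len == max(len))
  pick <- if (length(top) == 1) {
    top
  } else if (!is.null(default_name) && any(hits$transcriptome[top] == default_name)) {
    top[hits$transcriptome[top] == default_name][1]
  } else {
    warn(sprintf(
      "length tie among {%s} without default source; using lexicographically first",
      paste(hits$transcriptome[top], collapse = ", ")))
    top[order(hits$transcriptome[top])][1]
  }
  out <- hits[pick, , drop = FALSE]
  out$rep_source <- out$transcriptome
  out
}

#' Reciprocal best hits between two locus sets
#'
#' All-vs-all local alignment; a pair (a, b) is emitted iff b is a's unique
#' best hit in B, a is b's unique best hit in A, and both scores reach
#' `min_score`. A tied best hit suppresses the pairing for that query (a tie
#' is a paralogy signal, and dropping is the conservative action for a
#' single-copy pipeline); suppressed queries are recorded in the
#' `tie_suppressed` attribute.
#'
#' @param set_a,set_b tibbles with columns `id`, `seq`.
#' @param min_score minimum local-alignment score in both directions; the
#'   default equals a perfect 60-bp match under the default scoring.
#' @param scores scoring scheme (see [sp_scores()]).
#' @return tibble `id_a`, `id_b`, `score_ab`, `score_ba`, sorted by `id_a`,
#'   with attribute `tie_suppressed` (character vector of query ids whose
#'   best hit was tied).
#' @export
reciprocal_best_hit_pairs <- function(set_a, set_b, min_score = 60,
                                      scores = sp_scores()) {
  stopifnot(nrow(set_a) > 0, nrow(set_b) > 0)
  score_mat <- matrix(0, nrow = nrow(set_a), ncol = nrow(set_b),
                      dimnames = list(set_a$id, set_b$id))
  for (j in seq_len(nrow(set_b))) {
    score_mat[, j] <- local_align(set_a$seq, set_b$seq[j], scores = scores)$score
  }
  best_unique <- function(v) {
    m <- max(v)
    idx <- which(v == m)
    if (length(idx) == 1) idx else NA_integer_
  }
  best_in_b <- apply(score_mat, 1, best_unique)
  best_in_a <- apply(score_mat, 2, best_unique)
  ties <- c(set_a$id[is.na(best_in_b)], set_b$id[is.na(best_in_a)])
  if (length(ties) > 0) {
    inform(sprintf("RBH: best-hit tie suppressed for: %s",
                   paste(ties, collapse = ", ")))
  }
  pairs <- list()
  for (i in seq_len(nrow(set_a))) {
    j <- best_in_b[i]
    if (is.na(j)) next
    if (!is.na(best_in_a[j]) && best_in_a[j] == i &&
        score_mat[i, j] >= min_score && score_mat[i, j] >= min_score) {
      s_ab <- score_mat[i, j]
      # reverse-direction score: alignment is symmetric under these scores
      s_ba <- s_ab
      if (s_ab >= min_score && s_ba >= min_score) {
        pairs[[length(pairs) + 1]] <- tibble(
          id_a = set_a$id[i], id_b = set_b$id[j],
          score_ab = s_ab, score_ba = s_ba)
      }
    }
  }
  out <- if (length(pairs)) arrange(bind_rows(pairs), .data$id_a) else
    tibble(id_a = character(), id_b = character(),
           score_ab = numeric(), score_ba = numeric())
  attr(out, "tie_suppressed") <- unique(ties)
  out
}

#' Merge two genome-derived registries, deduplicating RBH-paired loci
#'
#' Loci paired by [reciprocal_best_hit_pairs()] were retrieved from both
#' reference genomes and are collapsed to a single record represented by the
#' longer transcript (tie broken toward `genome_precedence`); their
#' `genome_origin` becomes `"both"`. The merged registry has exactly
#' `|A| + |B| - |pairs|` loci.
#'
#' @param reg_a,reg_b registry tibbles (columns `locus_id`, `source_method`,
#'   `genome_origin`, `rep_id`, `rep_source`, `rep_seq`).
#' @param pairs tibble from [reciprocal_best_hit_pairs()] with `id_a` in
#'   `reg_a` and `id_b` in `reg_b`.
#' @param genome_precedence `"genomeA"` or `"genomeB"`: which member wins a
#'   length tie.
#' @return merged registry tibble.
#' @export
dedupe_overlapping <- function(reg_a, reg_b, pairs, genome_precedence = "genomeB") {
  if (nrow(pairs) > 0) {
    if (!all(pairs$id_a %in% reg_a$locus_id)) {
      abort(sprintf("pair references unknown locus '%s' in registry A",
                    setdiff(pairs$id_a, reg_a$locus_id)[1]))
    }
    if (!all(pairs$id_b %in% reg_b$locus_id)) {
      abort(sprintf("pair references unknown locus '%s' in registry B",
                    setdiff(pairs$id_b, reg_b$locus_id)[1]))
    }
  }
  a_only <- reg_a[!reg_a$locus_id %in% pairs$id_a, , drop = FALSE]
  b_only <- reg_b[!reg_b$locus_id %in% pairs$id_b, , drop = FALSE]
  merged <- purrr::pmap(pairs, function(id_a, id_b, ...) {
    ra <- reg_a[reg_a$locus_id == id_a, , drop = FALSE]
    rb <- reg_b[reg_b$locus_id == id_b, , drop = FALSE]
    la <- nchar(ra$rep_seq); lb <- nchar(rb$rep_seq)
    win <- if (la > lb) ra else if (lb > la) rb else
      if (genome_precedence == "genomeA") ra else rb
    win$genome_origin <- "both"
    win
  })
  out <- bind_rows(a_only, b_only, bind_rows(merged))
  stopifnot(nrow(out) == nrow(reg_a) + nrow(reg_b) - nrow(pairs))
  arrange(out, .data$locus_id)
}

#' Filter a universal locus set by taxon source
#'
#' Keeps a universal locus iff at least one of its source taxa is in
#' `allowed_taxa`; the representative is the longest sequence among hits from
#' allowed taxa.
#'
#' @param universal tibble with one row per (locus, taxon) sequence: columns
#'   `locus_id`, `taxon`, `id`, `seq`.
#' @param allowed_taxa non-empty character vector of permitted taxa.
#' @return registry tibble (`source_method = "universal"`,
#'   `genome_origin = "none"`), one row per kept locus.
#' @export
filter_universal_by_taxon <- function(universal, allowed_taxa) {
  if (length(allowed_taxa) == 0) abort("allowed_taxa must be non-empty")
  kept <- universal |>
    filter(.data$taxon %in% allowed_taxa) |>
    group_by(.data$locus_id) |>
    slice(which.max(nchar(.data$seq))) |>
    ungroup()
  tibble(locus_id = kept$locus_id, source_method = "universal",
         genome_origin = "none", rep_id = kept$id,
         rep_source = kept$taxon, rep_seq = kept$seq) |>
    arrange(.data$locus_id)
}

#' Map external (published/functional) query loci onto transcriptomes
#'
#' For each query, the best local hit per transcriptome is found; the
#' representative transcript is then chosen with [choose_representative()].
#' Queries with no hit reaching `min_score` in any transcriptome are reported
#' unmapped.
#'
#' @param queries tibble `id`, `seq` of external locus sequences.
#' @param transcriptomes named list of transcriptome tibbles (`id`, `seq`).
#' @param min_score minimum local-alignment score for a hit.
#' @param default_name transcriptome preferred on representative ties.
#' @param scores scoring scheme.
#' @return list with `mapped` (tibble `query_id`, `transcriptome`,
#'   `transcript_id`, `seq`) and `unmapped` (character vector of query ids).
#' @export
map_external_loci <- function(queries, transcriptomes, min_score = 60,
                              default_name = NULL, scores = sp_scores()) {
  stopifnot(nrow(queries) > 0, length(transcriptomes) > 0)
  mapped <- list()
  unmapped <- character(0)
  for (qi in seq_len(nrow(queries))) {
    hits <- purrr::imap(transcriptomes, function(tx, tx_name) {
      la <- local_align(tx$seq, queries$seq[qi], scores = scores)
      best <- which.max(la$score)
      if (la$score[best] < min_score) return(NULL)
      tibble(transcriptome = tx_name, transcript_id = tx$id[best],
             seq = tx$seq[best], score = la$score[best])
    })
    hits <- bind_rows(hits)
    if (nrow(hits) == 0) {
      unmapped <- c(unmapped, queries$id[qi])
      next
    }
    rep <- choose_representative(hits, default_name = default_name)
    rep$query_id <- queries$id[qi]
    mapped[[length(mapped) + 1]] <- rep
  }
  mapped <- if (length(mapped)) bind_rows(mapped) else
    tibble(transcriptome = character(), transcript_id = character(),
           seq = character(), score = numeric(), rep_source = character(),
           query_id = character())
  list(mapped = select(mapped, "query_id", "transcriptome", "transcript_id",
                       "seq", "rep_source"),
       unmapped = unmapped)
}

#' Merge the four locus sources into the final Tier-1 registry
#'
#' Locus ids are namespaced by source method (`mm::`, `univ::`, `pub::`,
#' `fun::`); any id collision after namespacing is an error. The merged size
#' is exactly the sum of the four inputs.
#'
#' @param markerminer,universal,published,functional registry tibbles
#'   (possibly empty; `NULL` treated as empty).
#' @return combined registry tibble with namespaced `locus_id` and
#'   `source_method` set per input.
#' @export
merge_sources <- function(markerminer = NULL, universal = NULL,
                          published = NULL, functional = NULL) {
  empty <- tibble(locus_id = character(), source_method = character(),
                  genome_origin = character(), rep_id = character(),
                  rep_source = character(), rep_seq = character())
  prep <- function(reg, method, prefix) {
    if (is.null(reg) || nrow(reg) == 0) return(empty)
    reg$source_method <- method
    reg$locus_id <- paste0(prefix, "::", reg$locus_id)
    reg[, names(empty)]
  }
  out <- bind_rows(prep(markerminer, "markerminer", "mm"),
                   prep(universal, "universal", "univ"),
                   prep(published, "published", "pub"),
                   prep(functional, "functional", "fun"))
  if (anyDuplicated(out$locus_id)) {
    abort(sprintf("locus id collision across sources: '%s'",
                  out$locus_id[duplicated(out$locus_id)][1]))
  }
  n_in <- sum(vapply(list(markerminer, universal, published, functional),
                     function(r) if (is.null(r)) 0L else nrow(r), integer(1)))
  stopifnot(nrow(out) == n_in)
  out
}
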