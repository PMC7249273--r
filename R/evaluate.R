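# Capture-experiment evaluation: per-template recovery against the panel,
# paralog flagging, on-target fraction, per-locus rollups, clade summaries
# and alignment-variation (parsimony-informative-site) statistics.

#' Best recovered sequence for a template
#'
#' Each contig is globally aligned to the template; its decision identity is
#' the fraction of *contig* bases that match the template in that alignment
#' (the exonerate-style similarity over the whole query, so a short
#' high-fidelity contig passes while a diverged one fails even if it
#' contains small well-matching islands). The best-scoring contig with
#' decision identity >= `min_identity` and template coverage >=
#' `min_cov_fraction` is returned. The reported `identity_pct` uses the
#' gapped definition ([percent_identity_gapped()]), so trailing ends of a
#' short contig count against the reported identity.
#'
#' @param template_seq the template sequence.
#' @param contigs tibble of the sample's contigs for this template (`seq`,
#'   optionally `contig_id`); may be empty.
#' @param min_identity decision-identity floor, percent (default 55).
#' @param min_cov_fraction minimum fraction of the template spanned by the
#'   contig's alignment (default 0: no length floor).
#' @param scores scoring scheme.
#' @return one-row tibble `recovered`, `recovered_len`, `reference_len`,
#'   `identity_pct`, `contig_id` (`recovered = FALSE` row when nothing
#'   qualifies).
#' @export
recovered_sequence <- function(template_seq, contigs, min_identity = 55,
                               min_cov_fraction = 0, scores = sp_scores()) {
  ref_len <- nchar(template_seq)
  none <- tibble(recovered = FALSE, recovered_len = 0L,
                 reference_len = ref_len, identity_pct = NA_real_,
                 contig_id = NA_character_)
  if (is.null(contigs) || nrow(contigs) == 0) return(none)
  ids <- if ("contig_id" %in% names(contigs)) contigs$contig_id else
    sprintf("contig%d", seq_len(nrow(contigs)))
  best <- NULL
  for (i in seq_len(nrow(contigs))) {
    ap <- align_pair(contigs$seq[i], template_seq, scores = scores)
    a <- strsplit(ap$a, "", fixed = TRUE)[[1]]
    b <- strsplit(ap$b, "", fixed = TRUE)[[1]]
    matches <- sum(a == b & a != "-")
    decision_identity <- 100 * matches / nchar(contigs$seq[i])
    covered <- which(a != "-" & b != "-")
    cov <- if (length(covered)) {
      ref_cols <- cumsum(b != "-")
      (ref_cols[covered[length(covered)]] - ref_cols[covered[1]] + 1) / ref_len
    } else 0
    if (decision_identity >= min_identity && cov >= min_cov_fraction &&
        (is.null(best) || ap$score > best$score)) {
      best <- list(i = i, score = ap$score,
                   identity_pct = percent_identity_gapped(ap$a, ap$b))
    }
  }
  if (is.null(best)) return(none)
  tibble(recovered = TRUE,
         recovered_len = nchar(contigs$seq[best$i]),
         reference_len = ref_len,
         identity_pct = best$identity_pct,
         contig_id = ids[best$i])
}

#' Count templates recovered at half reference length
#'
#' @param stats capture-stats tibble with `recovered`, `recovered_len`,
#'   `reference_len` (one sample).
#' @return integer count of templates with
#'   `recovered_len >= 0.5 * reference_len` (inclusive) among recovered
#'   templates.
#' @export
count_templates_at_50pct <- function(stats) {
  sum(stats$recovered & stats$recovered_len >= 0.5 * stats$reference_len)
}

#' Flag potential paralogs from multiple long contigs
#'
#' A locus is flagged in a sample iff at least two distinct contigs each span
#' `long_fraction` of the template length or more (local alignment span on
#' the template).
#'
#' @param contigs tibble of the sample's contigs for the locus (`seq`).
#' @param template_seq the locus's best template sequence.
#' @param long_fraction span threshold as a fraction of template length.
#' @param scores scoring scheme.
#' @return logical.
#' @export
flag_paralogs <- function(contigs, template_seq, long_fraction = 0.85,
                          scores = sp_scores()) {
  if (is.null(contigs) || nrow(contigs) < 2) return(FALSE)
  la <- local_align(contigs$seq, template_seq, scores = scores)
  span <- (la$subject_end - la$subject_start) / nchar(template_seq)
  sum(span >= long_fraction) >= 2
}

#' Percent of reads on target
#'
#' @param n_placed number of reads with a placement on any template (a
#'   placements tibble is also accepted).
#' @param total_reads total reads for the sample.
#' @return percentage, or `NA` (with a message) when `total_reads` is zero.
#' @export
on_target_fraction <- function(n_placed, total_reads) {
  if (is.data.frame(n_placed)) n_placed <- nrow(n_placed)
  if (total_reads == 0) {
    inform("on_target_fraction: total_reads is zero; reporting NA")
    return(NA_real_)
  }
  stopifnot(n_placed <= total_reads)
  100 * n_placed / total_reads
}

#' Roll per-template capture stats up to loci
#'
#' A locus counts as recovered in a sample iff any of its templates is
#' recovered; the locus recovered length is the maximum over its templates,
#' and per-locus taxon counts are the size of the union of the per-template
#' recovered-sample sets.
#'
#' @param template_stats tibble with `sample_id`, `template_id`, `recovered`,
#'   `recovered_len`, and optionally `identity_pct`, `paralog_flag`.
#' @param template_map tibble `template_id`, `locus_id`.
#' @return list with `per_sample` (tibble `sample_id`, `locus_id`,
#'   `recovered`, `recovered_len`, `paralog_flag`) and `per_locus` (tibble
#'   `locus_id`, `n_taxa`: samples with the locus recovered via any
#'   template).
#' @export
locus_rollup <- function(template_stats, template_map) {
  miss <- setdiff(template_stats$template_id, template_map$template_id)
  if (length(miss) > 0) abort(sprintf("unknown template '%s' in stats", miss[1]))
  x <- left_join(template_stats, template_map[, c("template_id", "locus_id")],
                 by = "template_id")
  per_sample <- x |>
    group_by(.data$sample_id, .data$locus_id) |>
    summarise(recovered = any(.data$recovered),
              recovered_len = if (any(.data$recovered))
                max(.data$recovered_len[.data$recovered]) else 0L,
              identity_pct = if ("identity_pct" %in% names(x) && any(.data$recovered))
                max(.data$identity_pct[.data$recovered], na.rm = TRUE) else NA_real_,
              paralog_flag = if ("paralog_flag" %in% names(x))
                any(.data$paralog_flag) else FALSE,
              .groups = "drop")
  per_locus <- per_sample |>
    group_by(.data$locus_id) |>
    summarise(n_taxa = sum(.data$recovered), .groups = "drop")
  list(per_sample = per_sample, per_locus = per_locus)
}

#' Per-clade summary of sample-level capture statistics
#'
#' Arithmetic mean, minimum and maximum of every numeric column, by clade.
#' When both `exon_len` and `intron_len` columns are present a
#' `supercontig_len` column (their sum) is added before summarizing.
#'
#' @param sample_stats tibble with one row per sample: `sample_id`, `clade`,
#'   plus numeric statistic columns.
#' @return long tibble `clade`, `metric`, `mean`, `min`, `max` (with
#'   `min <= mean <= max` by construction).
#' @export
clade_summary <- function(sample_stats) {
  stopifnot(nrow(sample_stats) >= 1, "clade" %in% names(sample_stats))
  if (all(c("exon_len", "intron_len") %in% names(sample_stats))) {
    sample_stats$supercontig_len <- sample_stats$exon_len + sample_stats$intron_len
  }
  num_cols <- names(sample_stats)[vapply(sample_stats, is.numeric, logical(1))]
  sample_stats |>
    tidyr::pivot_longer(dplyr::all_of(num_cols), names_to = "metric",
                        values_to = "value") |>
    group_by(.data$clade, .data$metric) |>
    summarise(mean = mean(.data$value, na.rm = TRUE),
              min = suppressWarnings(min(.data$value, na.rm = TRUE)),
              max = suppressWarnings(max(.data$value, na.rm = TRUE)),
              .groups = "drop")
}

#' Variation statistics from per-locus alignments
#'
#' Concatenates the locus alignments column-wise and classifies each column:
#' parsimony-informative iff at least two distinct non-missing states each
#' occur in at least two sequences; constant iff exactly one non-missing
#' state occurs; `N` and `-` are missing. `pis_pct` is reported half-up to
#' one decimal.
#'
#' @param alignments a single alignment (character vector of equal-length
#'   rows) or a list of such alignments, over `{A,C,G,T,N,-}`.
#' @param partition label for the partition summarized (`"exons"`,
#'   `"introns"`, `"supercontigs"`, ...).
#' @return one-row tibble: `partition`, `n_loci`, `alignment_length`,
#'   `pis_count`, `pis_pct`, `constant_sites`, `variable_uninformative`,
#'   `missing_pct`.
#' @export
alignment_variation_stats <- function(alignments, partition = "supercontigs") {
  if (is.character(alignments)) alignments <- list(alignments)
  if (length(alignments) == 0) abort("no alignments supplied")
  tot_cols <- 0L; pis <- 0L; constant <- 0L; variable_un <- 0L
  missing_cells <- 0; total_cells <- 0
  for (alnrows in alignments) {
    widths <- nchar(alnrows)
    stopifnot(length(unique(widths)) == 1)
    if (widths[1] == 0) abort("zero-column alignment")
    m <- do.call(rbind, strsplit(alnrows, "", fixed = TRUE))
    tot_cols <- tot_cols + ncol(m)
    total_cells <- total_cells + length(m)
    is_missing <- m == "N" | m == "-"
    missing_cells <- missing_cells + sum(is_missing)
    for (j in seq_len(ncol(m))) {
      col <- m[!is_missing[, j], j]
      if (length(col) == 0) next
      tab <- table(col)
      if (length(tab) == 1) {
        constant <- constant + 1L
      } else if (sum(tab >= 2) >= 2) {
        pis <- pis + 1L
      } else {
        variable_un <- variable_un + 1L
      }
    }
  }
  if (tot_cols == 0) abort("zero-column alignment")
  tibble(partition = partition, n_loci = length(alignments),
         alignment_length = tot_cols, pis_count = pis,
         pis_pct = round_half_up(100 * pis / tot_cols, 1),
         constant_sites = constant, variable_uninformative = variable_un,
         missing_pct = round_half_up(100 * missing_cells / total_cells, 1))
}

#' Variation statistics from pre-computed counts
#'
#' The arithmetic used to report parsimony-informative-site percentages:
#' `pis_pct = 100 * pis_count / alignment_length`, half-up to one decimal.
#'
#' @param pis_count number of parsimony-informative columns.
#' @param alignment_length total columns.
#' @param constant_sites,missing_pct optional extras carried through.
#' @return one-row tibble mirroring [alignment_variation_stats()].
#' @export
variation_stats <- function(pis_count, alignment_length,
                            constant_sites = NA_integer_, missing_pct = NA_real_) {
  stopifnot(alignment_length > 0, pis_count >= 0, pis_count <= alignment_length)
  if (!is.na(constant_sites)) {
    stopifnot(pis_count + constant_sites <= alignment_length)
  }
  tibble(pis_count = pis_count, alignment_length = alignment_length,
         pis_pct = round_half_up(100 * pis_count / alignment_length, 1),
         constant_sites = constant_sites, missing_pct = missing_pct)
}
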