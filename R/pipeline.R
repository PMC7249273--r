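# Stage drivers: thin orchestration over the module functions, taking the
# synthetic (or file-loaded) input bundle from one stage to the next. Each
# driver returns plain tibbles plus a log list, so stages are resumable from
# their TSV checkpoints.

#' Run Tier 1: locus selection and source merging
#'
#' For each reference genome: assemble candidate loci from its single-copy
#' gene list and the transcriptome hits, apply the minimum-gene-length and
#' exon/intron structure filters, and choose a representative transcript per
#' locus. The two genome-derived sets are then deduplicated by reciprocal
#' best hit, the universal set is filtered by taxon source, external
#' published/functional loci are mapped onto the transcriptomes, and all four
#' sources are merged into the Tier-1 registry.
#'
#' @param space input bundle from [make_gene_space()] (or assembled from
#'   files with the same shape).
#' @param min_len minimum gene length (bp, inclusive).
#' @param min_exon,max_intron structure-filter thresholds (strict).
#' @param min_score local-alignment score floor for RBH and external mapping.
#' @param default_name transcriptome preferred on representative-length ties.
#' @param genome_precedence genome whose transcript wins a dedupe length tie.
#' @return list: `registry` (merged Tier-1 registry), `per_genome`
#'   registries, `rbh_pairs`, `log` (filter/tie/unmapped bookkeeping).
#' @export
run_tier1 <- function(space, min_len = 500, min_exon = 120, max_intron = 100,
                      min_score = 60, default_name = "txomeA",
                      genome_precedence = "genomeB") {
  models <- filter_gene_models(space$models, min_exon = min_exon,
                               max_intron = max_intron)
  log <- list()
  per_genome <- list()
  for (genome in names(space$sc_lists)) {
    sc <- space$sc_lists[[genome]]
    cand <- bind_rows(lapply(names(space$transcriptomes), function(tx) {
      txt <- space$transcriptomes[[tx]]
      hit_id <- paste0(sc$locus_id, "@", tx)
      found <- hit_id %in% txt$id
      tibble(locus_id = sc$gene_id[found],
             transcriptome = tx,
             transcript_id = hit_id[found],
             seq = txt$seq[match(hit_id[found], txt$id)])
    }))
    n0 <- dplyr::n_distinct(cand$locus_id)
    cand <- filter_min_gene_length(cand, min_len = min_len)
    n1 <- dplyr::n_distinct(cand$locus_id)
    cand <- left_join(cand, models[, c("transcript_id", "structure_ok")],
                      by = "transcript_id")
    keep <- cand |>
      group_by(.data$locus_id) |>
      summarise(ok = all(.data$structure_ok), .groups = "drop") |>
      filter(.data$ok) |>
      pull("locus_id")
    cand <- cand[cand$locus_id %in% keep, , drop = FALSE]
    reps <- cand |>
      group_by(.data$locus_id) |>
      dplyr::group_modify(~ choose_representative(.x, default_name = default_name)) |>
      ungroup()
    per_genome[[genome]] <- tibble(
      locus_id = reps$locus_id, source_method = "markerminer",
      genome_origin = genome, rep_id = reps$transcript_id,
      rep_source = reps$rep_source, rep_seq = reps$seq)
    log[[genome]] <- tibble(genome = genome, candidates = n0,
                            after_length = n1,
                            after_structure = length(keep))
  }
  pairs <- reciprocal_best_hit_pairs(
    tibble(id = per_genome$genomeA$locus_id, seq = per_genome$genomeA$rep_seq),
    tibble(id = per_genome$genomeB$locus_id, seq = per_genome$genomeB$rep_seq),
    min_score = min_score)
  markerminer <- dedupe_overlapping(per_genome$genomeA, per_genome$genomeB,
                                    pairs, genome_precedence = genome_precedence)
  universal <- filter_universal_by_taxon(space$universal, space$allowed_taxa)
  map_one <- function(queries) {
    m <- map_external_loci(queries, space$transcriptomes,
                           min_score = min_score, default_name = default_name)
    reg <- tibble(locus_id = m$mapped$query_id, source_method = "external",
                  genome_origin = "none", rep_id = m$mapped$transcript_id,
                  rep_source = m$mapped$rep_source, rep_seq = m$mapped$seq)
    list(reg = reg, unmapped = m$unmapped)
  }
  pub <- map_one(space$queries$published)
  fun <- map_one(space$queries$functional)
  registry <- merge_sources(markerminer = markerminer, universal = universal,
                            published = pub$reg, functional = fun$reg)
  list(registry = registry, per_genome = per_genome, rbh_pairs = pairs,
       log = list(filters = bind_rows(log),
                  tie_suppressed = attr(pairs, "tie_suppressed"),
                  unmapped = list(published = pub$unmapped,
                                  functional = fun$unmapped)))
}

#' Run Tier 2: template recovery from genome skims
#'
#' Maps each clade's genome-skim reads to the Tier-1 representative
#' sequences, assembles majority-vote consensus contigs per locus and clade,
#' star-aligns reference plus contigs, selects 1-4 templates per locus, and
#' screens the final templates against the organellar references.
#'
#' @param registry Tier-1 registry.
#' @param skims named list of read tibbles, one per clade (names become the
#'   `skim_<clade>` source classes).
#' @param plastid,mito organellar reference sequences (or `NULL` to skip the
#'   screen).
#' @param k k-mer size for the read-mapping index.
#' @param min_identity read-placement identity floor.
#' @param min_depth consensus depth floor.
#' @param flank_bp pileup extension beyond reference ends.
#' @param ident_threshold,min_contig,max_templates template-selection
#'   parameters (see [select_templates()]).
#' @return list: `templates` (post-screen), `screened_out`, `alignments`
#'   (per-locus `star_alignment`s), `contigs`, `log`.
#' @export
run_tier2 <- function(registry, skims, plastid = NULL, mito = NULL, k = 13,
                      min_identity = 0.80, min_depth = 2, flank_bp = 200,
                      ident_threshold = 90, min_contig = 300, max_templates = 4) {
  refs <- tibble(id = registry$locus_id, seq = registry$rep_seq)
  index <- index_reference(refs, k = k)
  placements <- lapply(skims, function(reads)
    map_reads(reads, index, min_identity = min_identity))
  contigs <- list()
  for (clade in names(placements)) {
    pl <- placements[[clade]]
    for (locus in unique(pl$ref_id)) {
      ct <- consensus_contigs(pl[pl$ref_id == locus, , drop = FALSE],
                              refs[refs$id == locus, , drop = FALSE],
                              min_depth = min_depth, flank_bp = flank_bp)
      if (nrow(ct) > 0) {
        ct$contig_id <- sprintf("%s::%s::c%d", locus, clade, seq_len(nrow(ct)))
        ct$source_class <- paste0("skim_", clade)
        contigs[[length(contigs) + 1]] <- ct
      }
    }
  }
  contigs <- if (length(contigs)) bind_rows(contigs) else
    tibble(locus_id = character(), seq = character(), ref_start = numeric(),
           ref_end = numeric(), mean_depth = numeric(),
           contig_id = character(), source_class = character())
  templates <- list()
  alignments <- list()
  omitted <- character(0)
  for (i in seq_len(nrow(registry))) {
    locus <- registry$locus_id[i]
    ref_class <- if (registry$source_method[i] == "universal") "universal"
                 else "transcriptome"
    lc <- contigs[contigs$locus_id == locus, , drop = FALSE]
    seqs <- bind_rows(tibble(id = locus, seq = registry$rep_seq[i]),
                      tibble(id = lc$contig_id, seq = lc$seq))
    aln <- star_align(seqs, ref_id = locus)
    alignments[[locus]] <- aln
    meta <- tibble(id = seqs$id,
                   source_class = c(ref_class, lc$source_class))
    tpl <- select_templates(aln, meta, locus_id = locus,
                            source_method = registry$source_method[i],
                            ident_threshold = ident_threshold,
                            min_contig = min_contig,
                            max_templates = max_templates)
    if (nrow(tpl) == 0) omitted <- c(omitted, locus)
    else templates[[length(templates) + 1]] <- tpl
  }
  templates <- if (length(templates)) bind_rows(templates) else
    tibble(template_id = character(), locus_id = character(),
           source_class = character(), seq = character(),
           aligned_row = character(), provenance = list())
  screen <- organelle_screen(templates, plastid = plastid, mito = mito)
  list(templates = screen$kept, screened_out = screen$flagged,
       alignments = alignments, contigs = contigs,
       log = list(
         omitted_loci = omitted,
         mapping = tibble(
           clade = names(placements),
           reads = vapply(skims, nrow, integer(1)),
           placed = vapply(placements, nrow, integer(1)),
           ambiguous = vapply(placements, function(p)
             attr(p, "n_ambiguous") %||% 0L, integer(1)))))
}

#' Run probe construction
#'
#' Sanitizes each template against its locus alignment, tiles probes, and
#' applies the homopolymer and decoy screens.
#'
#' @param tier2 output of [run_tier2()] (or a list with `templates` and
#'   `alignments`).
#' @param plastid,mito,nuclear_decoy decoy references for [decoy_screen()].
#' @param probe_len,tiling tiling parameters.
#' @param max_run homopolymer rejection threshold.
#' @param min_ident,min_len decoy-screen thresholds.
#' @param registry optional registry for [panel_summary()] consistency
#'   checks.
#' @return list: `probes` (the panel), `report` (flagged probes), `summary`
#'   (a `panel_summary`), `templates` (sanitized).
#' @export
run_probes <- function(tier2, plastid = NULL, mito = NULL, nuclear_decoy = NULL,
                       probe_len = 120, tiling = 3, max_run = 10,
                       min_ident = 90, min_len = 60, registry = NULL) {
  templates <- tier2$templates
  alignments <- tier2$alignments
  clean <- character(nrow(templates))
  for (i in seq_len(nrow(templates))) {
    locus <- templates$locus_id[i]
    aln <- alignments[[locus]]
    row_origin <- templates$provenance[[i]]
    row_id <- if (!is.null(row_origin) && nrow(row_origin) == 1)
      row_origin$origin[1] else NULL
    arow <- templates$aligned_row[i]
    if (!is.null(aln) && !is.na(arow) && !is.null(row_id)) {
      clean[i] <- sanitize_template(arow, alignment = aln, row_id = row_id)
    } else {
      clean[i] <- sanitize_template(templates$seq[i])
    }
  }
  templates$seq <- clean
  probes <- tile_probes(templates, probe_len = probe_len, tiling = tiling)
  hp_ok <- homopolymer_filter(probes$seq, max_run = max_run)
  hp_flagged <- probes[!hp_ok, , drop = FALSE]
  if (nrow(hp_flagged) > 0) {
    hp_flagged$flags <- ifelse(nzchar(hp_flagged$flags),
                               paste(hp_flagged$flags, "homopolymer", sep = ","),
                               "homopolymer")
    hp_flagged$decoy <- NA_character_
    hp_flagged$identity_pct <- NA_real_
    hp_flagged$aln_len <- NA_real_
  }
  probes <- probes[hp_ok, , drop = FALSE]
  dec <- decoy_screen(probes, plastid = plastid, mito = mito,
                      nuclear_decoy = nuclear_decoy,
                      min_ident = min_ident, min_len = min_len)
  report <- bind_rows(hp_flagged, dec$flagged)
  summary <- panel_summary(dec$kept, templates, registry = registry)
  list(probes = dec$kept, report = report, summary = summary,
       templates = templates)
}

#' Run capture evaluation
#'
#' Maps each sample's capture reads to the template panel, assembles
#' per-template consensus contigs, scores recovery, flags paralogs, and
#' summarizes per sample, per locus, and per clade.
#'
#' @param templates template tibble (`template_id`, `locus_id`, `seq`).
#' @param sample_reads named list: `sample_id` -> reads tibble.
#' @param sample_clades tibble `sample_id`, `clade`.
#' @param k,min_identity,min_depth mapping/assembly parameters.
#' @param min_recovery_identity percent-identity floor for calling a
#'   template recovered.
#' @param long_fraction paralog-flag span threshold.
#' @return list: `template_stats` (per sample x template), `rollup`
#'   (locus-level), `sample_stats`, `clade_stats`.
#' @export
run_evaluate <- function(templates, sample_reads, sample_clades, k = 13,
                         min_identity = 0.80, min_depth = 2,
                         min_recovery_identity = 55, long_fraction = 0.85) {
  refs <- tibble(id = templates$template_id, seq = templates$seq)
  index <- index_reference(refs, k = k)
  template_stats <- list()
  sample_stats <- list()
  for (s in names(sample_reads)) {
    reads <- sample_reads[[s]]
    pl <- map_reads(reads, index, min_identity = min_identity)
    on_target <- on_target_fraction(nrow(pl), nrow(reads))
    per_tpl <- list()
    for (i in seq_len(nrow(templates))) {
      tid <- templates$template_id[i]
      sub <- pl[pl$ref_id == tid, , drop = FALSE]
      ct <- consensus_contigs(sub, refs[refs$id == tid, , drop = FALSE],
                              min_depth = min_depth, flank_bp = 0)
      if (nrow(ct) > 0) ct$contig_id <- sprintf("%s::c%d", tid, seq_len(nrow(ct)))
      rec <- recovered_sequence(templates$seq[i], ct,
                                min_identity = min_recovery_identity)
      rec$sample_id <- s
      rec$template_id <- tid
      rec$paralog_flag <- flag_paralogs(ct, templates$seq[i],
                                        long_fraction = long_fraction)
      per_tpl[[i]] <- rec
    }
    per_tpl <- bind_rows(per_tpl)
    template_stats[[s]] <- per_tpl
    sample_stats[[s]] <- tibble(
      sample_id = s,
      total_reads = nrow(reads),
      on_target_pct = on_target,
      n_templates_recovered = sum(per_tpl$recovered),
      n_templates_at_50pct = count_templates_at_50pct(per_tpl),
      mean_recovered_len = mean(per_tpl$recovered_len[per_tpl$recovered]),
      n_paralog_templates = sum(per_tpl$paralog_flag))
  }
  template_stats <- bind_rows(template_stats)
  rollup <- locus_rollup(template_stats,
                         templates[, c("template_id", "locus_id")])
  sample_stats <- bind_rows(sample_stats) |>
    left_join(sample_clades, by = "sample_id") |>
    left_join(
      rollup$per_sample |>
        group_by(.data$sample_id) |>
        summarise(n_loci_recovered = sum(.data$recovered),
                  n_paralog_loci = sum(.data$paralog_flag), .groups = "drop"),
      by = "sample_id")
  clade_stats <- clade_summary(sample_stats)
  list(template_stats = template_stats, rollup = rollup,
       sample_stats = sample_stats, clade_stats = clade_stats)
}
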