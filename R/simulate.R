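# Seeded synthetic-data generator. Emulates the data a two-clade probe-design
# study works from: an ancestral gene space with exon/intron structure, two
# diverged clades, transcriptomes from two related taxa, curated single-copy
# gene lists keyed to two reference genomes, a universal locus set with taxon
# metadata, external query loci, organellar/decoy references, shallow
# genome-skim reads, and enrichment-biased capture reads. Every generator is
# deterministic under a fixed seed.

#' Simulation configuration
#'
#' Defaults describe the regime the pipeline is designed for: 15x
#' genome-skim coverage of 150-bp reads at 1% substitution error, two clades
#' at 15% nucleotide divergence from their common ancestor's transcriptome,
#' and capture enrichment odds of 5.67 (an ~85% on-target regime).
#'
#' @param seed integer seed controlling every stochastic choice.
#' @param n_loci number of candidate (MarkerMiner-style) loci.
#' @param exon_count_range,exon_len_range,intron_len_range gene-model
#'   structure for well-formed loci (bp).
#' @param clade_divergence per-site substitution fraction separating each
#'   clade from the ancestral sequence.
#' @param indel_rate per-site indel initiation rate in clade genomic copies
#'   (geometric lengths, mean 3 bp).
#' @param transcriptome_divergence per-site substitution fraction of each
#'   transcriptome from the ancestor.
#' @param skim_coverage mean fold-coverage of genome-skim reads.
#' @param read_len read length (bp).
#' @param read_error per-base substitution error rate in simulated reads.
#' @param organelle_len length of the simulated plastid/mitochondrial/decoy
#'   references (bp).
#' @param enrichment_ratio on-target : off-target sampling odds for capture
#'   reads; expected on-target fraction is `ratio / (1 + ratio)`.
#' @param capture_coverage mean fold-coverage of on-target capture reads.
#' @param frac_violation fraction of loci planted with a structure violation
#'   (an exon <= 120 bp or an intron >= 100 bp).
#' @param frac_short fraction of loci planted with total length < 500 bp.
#' @param frac_duplicate fraction of loci duplicated verbatim (paralog
#'   simulation; duplicates enter both genome lists).
#' @param n_universal,n_published,n_functional sizes of the auxiliary locus
#'   sets.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1, n_loci = 30,
                       exon_count_range = c(2, 4),
                       exon_len_range = c(250, 450),
                       intron_len_range = c(20, 90),
                       clade_divergence = 0.15,
                       indel_rate = 0.003,
                       transcriptome_divergence = 0.02,
                       skim_coverage = 15,
                       read_len = 150,
                       read_error = 0.01,
                       organelle_len = 2000,
                       enrichment_ratio = 5.67,
                       capture_coverage = 15,
                       frac_violation = 0.15,
                       frac_short = 0.05,
                       frac_duplicate = 0.10,
                       n_universal = 6, n_published = 2, n_functional = 2) {
  rates <- c(clade_divergence, indel_rate, transcriptome_divergence,
             read_error, frac_violation, frac_short, frac_duplicate)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (skim_coverage <= 0 || capture_coverage <= 0) abort("coverage must be > 0")
  if (exon_len_range[1] < 1) abort("exon lengths must be >= 1")
  if (read_len < 21) abort("read_len must be at least the k-mer size")
  structure(as.list(environment()), class = "sim_config")
}

sp_random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Per-site Bernoulli substitutions (uniform alternative base), optional
# geometric-length indels (mean 3 bp).
sp_mutate_seq <- function(seq, sub_rate, indel_rate = 0) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  subs <- which(stats::runif(n) < sub_rate)
  for (i in subs) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  if (indel_rate > 0) {
    sites <- which(stats::runif(n) < indel_rate)
    if (length(sites) > 0) {
      pieces <- as.list(chars)
      for (i in sites) {
        len <- 1L + stats::rgeom(1, 1 / 3)
        if (stats::runif(1) < 0.5) {
          for (j in i:min(n, i + len - 1)) pieces[[j]] <- character(0)
        } else {
          pieces[[i]] <- c(strsplit(sp_random_seq(len), "", fixed = TRUE)[[1]],
                           pieces[[i]])
        }
      }
      chars <- unlist(pieces)
    }
  }
  paste(chars, collapse = "")
}

#' Generate the synthetic gene space and all pipeline inputs
#'
#' Builds ancestral gene models, two diverged clade genomes, two
#' transcriptomes, single-copy gene lists for two reference genomes (with
#' planted structure violations, short loci, and verbatim duplicates), a
#' taxon-annotated universal locus set, published/functional query sets, and
#' organellar/nuclear decoy references. One locus carries a planted plastid
#' segment (organelle contamination) and the nuclear decoy carries a verbatim
#' copy of one locus segment, so both screens have true positives.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `cfg`, `truth` (per-locus ground truth),
#'   `models`, `transcriptomes`, `sc_lists`, `universal`, `allowed_taxa`,
#'   `queries`, `clade_genomes`, `organelle`, `nuclear_decoy`.
#' @export
make_gene_space <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tx_names <- c("txomeA", "txomeB")

  n_struct <- round(cfg$frac_violation * cfg$n_loci)
  n_short <- max(if (cfg$frac_short > 0) 1L else 0L,
                 round(cfg$frac_short * cfg$n_loci))
  n_normal <- cfg$n_loci - n_struct - n_short
  stopifnot(n_normal > 4)

  gen_model <- function(kind) {
    k <- sample(seq(cfg$exon_count_range[1], cfg$exon_count_range[2]), 1)
    exons <- sample(seq(cfg$exon_len_range[1], cfg$exon_len_range[2]), k,
                    replace = TRUE)
    introns <- if (k > 1) sample(seq(cfg$intron_len_range[1],
                                     cfg$intron_len_range[2]), k - 1,
                                 replace = TRUE) else integer(0)
    if (kind == "structure") {
      if (k > 1 && stats::runif(1) < 0.5) {
        introns[sample(k - 1, 1)] <- sample(100:220, 1)   # intron not < 100
      } else {
        exons[sample(k, 1)] <- sample(60:120, 1)          # exon not > 120
      }
    }
    if (kind == "short") {
      k <- sample(1:2, 1)
      exons <- sample(170:230, k, replace = TRUE)  # keeps loci readable at 150 bp
      introns <- if (k > 1) sample(seq(cfg$intron_len_range[1],
                                       cfg$intron_len_range[2]), k - 1,
                                   replace = TRUE) else integer(0)
    }
    list(exons = as.integer(exons), introns = as.integer(introns))
  }

  kinds <- c(rep("none", n_normal), rep("structure", n_struct),
             rep("short", n_short))
  loci <- tibble(
    locus_id = sprintf("L%03d", seq_len(cfg$n_loci)),
    violation = kinds[sample.int(cfg$n_loci)])

  # duplicates: verbatim copies of normal loci, present in both genome lists
  n_dup <- max(if (cfg$frac_duplicate > 0) 1L else 0L,
               round(cfg$frac_duplicate * n_normal))
  dup_parents <- sample(loci$locus_id[loci$violation == "none"], n_dup)
  dup_ids <- sprintf("L%03dd", match(dup_parents, loci$locus_id))

  splice <- function(exon_seqs) paste(exon_seqs, collapse = "")
  interleave <- function(exon_seqs, intron_seqs) {
    paste0(paste0(exon_seqs, c(intron_seqs, "")[seq_along(exon_seqs)]),
           collapse = "")
  }
  build_locus <- function(locus_id, violation) {
    gm <- gen_model(violation)
    exon_seqs <- vapply(gm$exons, sp_random_seq, character(1))
    intron_seqs <- vapply(gm$introns, sp_random_seq, character(1))
    list(locus_id = locus_id, exons = gm$exons, introns = gm$introns,
         exon_seqs = exon_seqs, intron_seqs = intron_seqs,
         spliced = splice(exon_seqs),
         genomic = interleave(exon_seqs, intron_seqs))
  }

  anc <- purrr::map2(loci$locus_id, loci$violation, build_locus)
  names(anc) <- loci$locus_id

  # organelle references; plant a plastid segment into one normal locus
  plastid <- sp_random_seq(cfg$organelle_len)
  mito <- sp_random_seq(cfg$organelle_len)
  normal_ids <- loci$locus_id[loci$violation == "none"]
  organelle_locus <- sample(setdiff(normal_ids, dup_parents), 1)
  seg <- substr(plastid, 501, 700)
  ol <- anc[[organelle_locus]]
  e1 <- ol$exon_seqs[1]   # first exon is >= 250 bp by construction
  ol$exon_seqs[1] <- paste0(substr(e1, 1, 50), seg,
                            substr(e1, 251, nchar(e1)))
  ol$spliced <- splice(ol$exon_seqs)
  ol$genomic <- interleave(ol$exon_seqs, ol$intron_seqs)
  anc[[organelle_locus]] <- ol

  # auxiliary locus sets (single-exon): universal + published + functional
  aux_id <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))
  universal_ids <- aux_id("U", cfg$n_universal)
  published_ids <- aux_id("P", cfg$n_published)
  functional_ids <- aux_id("F", cfg$n_functional)
  for (id in c(universal_ids, published_ids, functional_ids)) {
    len <- sample(500:800, 1)
    s <- sp_random_seq(len)
    anc[[id]] <- list(locus_id = id, exons = len, introns = integer(0),
                      exon_seqs = s, intron_seqs = character(0),
                      spliced = s, genomic = s)
  }

  all_ids <- names(anc)
  # clade copies: every exon/intron segment mutated independently, so both
  # the genomic (with introns) and the spliced (exon-only) truth are known
  clades <- list()
  clade_spliced <- list()
  for (clade in c("cladeA", "cladeB")) {
    mut <- lapply(all_ids, function(i) {
      ex <- vapply(anc[[i]]$exon_seqs, sp_mutate_seq, character(1),
                   sub_rate = cfg$clade_divergence, indel_rate = cfg$indel_rate)
      inx <- vapply(anc[[i]]$intron_seqs, sp_mutate_seq, character(1),
                    sub_rate = cfg$clade_divergence, indel_rate = cfg$indel_rate)
      list(spliced = splice(ex), genomic = interleave(ex, inx))
    })
    clades[[clade]] <- tibble(
      id = all_ids, seq = vapply(mut, `[[`, character(1), "genomic"))
    clade_spliced[[clade]] <- vapply(mut, `[[`, character(1), "spliced")
  }

  # duplicates share their parent's sequence exactly (recent duplication)
  dup_tbl <- tibble(locus_id = dup_ids, parent = dup_parents)

  # transcriptomes: lightly diverged spliced copies of candidate + external loci
  tx_loci <- c(loci$locus_id, published_ids, functional_ids)
  transcriptomes <- list()
  for (tx in tx_names) {
    ids <- paste0(tx_loci, "@", tx)
    transcriptomes[[tx]] <- tibble(
      id = ids, desc = "",
      seq = vapply(tx_loci, function(i)
        sp_mutate_seq(anc[[i]]$spliced, cfg$transcriptome_divergence),
        character(1)))
  }

  # gene models follow the transcripts (substitution-only, lengths preserved)
  models <- bind_rows(lapply(tx_names, function(tx) {
    tibble(transcript_id = paste0(tx_loci, "@", tx), taxon = tx,
           exon_lengths = lapply(tx_loci, function(i) anc[[i]]$exons),
           intron_lengths = lapply(tx_loci, function(i) anc[[i]]$introns))
  }))

  # single-copy gene lists per reference genome: overlapping subsets of the
  # candidate loci; duplicates and their parents sit in both lists
  cand <- loci$locus_id
  both_core <- unique(c(dup_parents,
                        sample(cand, round(0.5 * length(cand)))))
  rest <- setdiff(cand, both_core)
  half <- seq_len(floor(length(rest) / 2))
  only_a <- rest[half]
  only_b <- setdiff(rest, only_a)
  mk_list <- function(members, genome, extra_dups) {
    members <- c(members, extra_dups)
    tibble(gene_id = sprintf("%s_%s", ifelse(genome == "genomeA", "gA", "gB"),
                             members),
           locus_id = members)
  }
  sc_lists <- list(
    genomeA = mk_list(c(both_core, only_a), "genomeA", dup_ids),
    genomeB = mk_list(c(both_core, only_b), "genomeB", dup_ids))

  # duplicates need transcripts too (identical to parent's)
  for (tx in tx_names) {
    dt <- transcriptomes[[tx]]
    parents <- paste0(dup_parents, "@", tx)
    add <- tibble(id = paste0(dup_ids, "@", tx), desc = "",
                  seq = dt$seq[match(parents, dt$id)])
    transcriptomes[[tx]] <- bind_rows(dt, add)
  }
  models <- bind_rows(models, bind_rows(lapply(tx_names, function(tx) {
    tibble(transcript_id = paste0(dup_ids, "@", tx), taxon = tx,
           exon_lengths = lapply(dup_parents, function(i) anc[[i]]$exons),
           intron_lengths = lapply(dup_parents, function(i) anc[[i]]$introns))
  })))
  for (clade in c("cladeA", "cladeB")) {
    g <- clades[[clade]]
    add <- tibble(id = dup_ids, seq = g$seq[match(dup_parents, g$id)])
    clades[[clade]] <- bind_rows(g, add)
  }

  # universal set with taxon metadata; some loci only from disallowed taxa
  allowed_taxa <- c("rosid_1", "rosid_2", "malvid_1")
  disallowed <- c("monocot_1", "fern_1")
  universal <- bind_rows(lapply(seq_along(universal_ids), function(i) {
    uid <- universal_ids[i]
    taxa <- if (i %% 3 == 0) sample(disallowed, 1) else
      unique(c(sample(allowed_taxa, sample(1:2, 1)),
               if (stats::runif(1) < 0.3) sample(disallowed, 1)))
    tibble(locus_id = uid, taxon = taxa,
           id = paste0(uid, "@", taxa),
           seq = vapply(taxa, function(t)
             sp_mutate_seq(anc[[uid]]$spliced, 0.05), character(1)))
  }))

  # external queries: fragments of the ancestral spliced sequence
  mk_queries <- function(ids) {
    tibble(id = paste0("q_", ids), locus_id = ids,
           seq = vapply(ids, function(i) {
             s <- anc[[i]]$spliced
             n <- nchar(s)
             substr(s, 1 + round(0.1 * n), round(0.8 * n))
           }, character(1)))
  }

  # nuclear decoy: random backbone with a verbatim copy of one locus segment
  decoy_locus <- sample(setdiff(normal_ids, c(dup_parents, organelle_locus)), 1)
  decoy_seg <- substr(anc[[decoy_locus]]$spliced, 101, 300)
  nuclear_decoy <- paste0(substr(sp_random_seq(cfg$organelle_len), 1, 900),
                          decoy_seg,
                          sp_random_seq(cfg$organelle_len - 900 - nchar(decoy_seg)))

  truth <- tibble(
    locus_id = names(anc),
    class = dplyr::case_when(
      names(anc) %in% universal_ids ~ "universal",
      names(anc) %in% published_ids ~ "published",
      names(anc) %in% functional_ids ~ "functional",
      TRUE ~ "markerminer"),
    violation = ifelse(names(anc) %in% loci$locus_id,
                       loci$violation[match(names(anc), loci$locus_id)], "none"),
    duplicate_of = NA_character_,
    ancestral_spliced = unname(vapply(anc, function(x) x$spliced, character(1))),
    ancestral_genomic = unname(vapply(anc, function(x) x$genomic, character(1))),
    cladeA_genomic = clades$cladeA$seq[match(names(anc), clades$cladeA$id)],
    cladeB_genomic = clades$cladeB$seq[match(names(anc), clades$cladeB$id)],
    cladeA_spliced = clade_spliced$cladeA[match(names(anc), all_ids)],
    cladeB_spliced = clade_spliced$cladeB[match(names(anc), all_ids)],
    organelle_contaminated = names(anc) == organelle_locus,
    decoy_planted = names(anc) == decoy_locus)
  truth <- bind_rows(truth, tibble(
    locus_id = dup_ids, class = "markerminer", violation = "none",
    duplicate_of = dup_parents,
    ancestral_spliced = truth$ancestral_spliced[match(dup_parents, truth$locus_id)],
    ancestral_genomic = truth$ancestral_genomic[match(dup_parents, truth$locus_id)],
    cladeA_genomic = truth$cladeA_genomic[match(dup_parents, truth$locus_id)],
    cladeB_genomic = truth$cladeB_genomic[match(dup_parents, truth$locus_id)],
    cladeA_spliced = truth$cladeA_spliced[match(dup_parents, truth$locus_id)],
    cladeB_spliced = truth$cladeB_spliced[match(dup_parents, truth$locus_id)],
    organelle_contaminated = FALSE, decoy_planted = FALSE))

  list(cfg = cfg, truth = truth, models = models,
       transcriptomes = transcriptomes, sc_lists = sc_lists,
       universal = universal, allowed_taxa = allowed_taxa,
       queries = list(published = mk_queries(published_ids),
                      functional = mk_queries(functional_ids)),
       clade_genomes = clades,
       organelle = list(plastid = plastid, mito = mito),
       nuclear_decoy = nuclear_decoy)
}

#' Simulate genome-skim reads
#'
#' Uniformly positioned single-end reads at `cfg$skim_coverage` mean depth,
#' random strand, per-base substitution errors at `cfg$read_error`.
#'
#' @param genome tibble `id`, `seq` (e.g. one clade's per-locus genomic
#'   sequences).
#' @param cfg a [sim_config()].
#' @param seed seed for this read set (defaults to `cfg$seed`).
#' @param coverage override of `cfg$skim_coverage`.
#' @return reads tibble `id`, `seq`.
#' @export
simulate_skim_reads <- function(genome, cfg = sim_config(), seed = cfg$seed,
                                coverage = cfg$skim_coverage) {
  stopifnot(nrow(genome) > 0)
  if (any(nchar(genome$seq) < cfg$read_len)) {
    abort("read_len exceeds a reference length")
  }
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(genome))) {
    L <- nchar(genome$seq[i])
    n_reads <- ceiling(L * coverage / cfg$read_len)
    pos <- sample.int(L - cfg$read_len + 1L, n_reads, replace = TRUE)
    seqs <- substring(genome$seq[i], pos, pos + cfg$read_len - 1L)
    if (cfg$read_error > 0) {
      seqs <- vapply(seqs, sp_mutate_seq, character(1),
                     sub_rate = cfg$read_error, USE.NAMES = FALSE)
    }
    neg <- stats::runif(n_reads) < 0.5
    seqs[neg] <- revcomp(seqs[neg])
    out[[i]] <- tibble(id = sprintf("%s_r%05d", genome$id[i], seq_len(n_reads)),
                       seq = seqs)
  }
  bind_rows(out)
}

#' Simulate enrichment-biased capture reads
#'
#' Each read is on-target with probability `ratio / (1 + ratio)`; on-target
#' reads are drawn from `targets` (length-weighted), off-target reads from
#' `off_target`. `ratio = Inf` gives a fully on-target library.
#'
#' @param targets tibble `id`, `seq`: sequences the probes enrich (e.g. a
#'   sample's true locus sequences).
#' @param off_target tibble `id`, `seq` of background sequence.
#' @param cfg a [sim_config()].
#' @param seed seed for this read set.
#' @param n_reads total reads; default sizes the library so on-target depth
#'   is about `cfg$capture_coverage`.
#' @return reads tibble `id`, `seq`, `on_target` (simulation truth flag).
#' @export
simulate_capture_reads <- function(targets, off_target, cfg = sim_config(),
                                   seed = cfg$seed, n_reads = NULL) {
  stopifnot(nrow(targets) > 0)
  set.seed(seed)
  ratio <- cfg$enrichment_ratio
  p_on <- if (is.infinite(ratio)) 1 else ratio / (1 + ratio)
  if (is.null(n_reads)) {
    n_on_needed <- ceiling(sum(nchar(targets$seq)) * cfg$capture_coverage /
                             cfg$read_len)
    n_reads <- ceiling(n_on_needed / max(p_on, 1e-6))
  }
  on <- stats::runif(n_reads) < p_on
  draw_from <- function(pool, n, tag) {
    if (n == 0) return(tibble(id = character(), seq = character()))
    w <- pmax(nchar(pool$seq) - cfg$read_len + 1L, 1L)
    src <- sample.int(nrow(pool), n, replace = TRUE, prob = w)
    L <- nchar(pool$seq[src])
    pos <- floor(stats::runif(n) * pmax(L - cfg$read_len + 1L, 1L)) + 1L
    seqs <- substring(pool$seq[src], pos, pmin(pos + cfg$read_len - 1L, L))
    if (cfg$read_error > 0) {
      seqs <- vapply(seqs, sp_mutate_seq, character(1),
                     sub_rate = cfg$read_error, USE.NAMES = FALSE)
    }
    neg <- stats::runif(n) < 0.5
    seqs[neg] <- revcomp(seqs[neg])
    tibble(id = sprintf("%s_%05d", tag, seq_len(n)), seq = seqs)
  }
  on_reads <- draw_from(targets, sum(on), "on")
  off_reads <- draw_from(off_target, sum(!on), "off")
  out <- bind_rows(mutate(on_reads, on_target = TRUE),
                   mutate(off_reads, on_target = FALSE))
  out[sample.int(nrow(out)), , drop = FALSE]
}
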