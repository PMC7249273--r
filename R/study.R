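# One-call synthetic study: generate the gene space, run both tiers, build
# the probe panel, simulate capture, and evaluate. The shape mirrors how the
# pipeline is used on real data, with the simulator standing in for
# sequencing.

#' Run the full pipeline on a seeded synthetic study
#'
#' Generates a two-clade gene space, runs Tier 1 (locus selection) and Tier 2
#' (template recovery from simulated genome skims), constructs and screens
#' the probe panel, simulates enrichment-biased capture reads for each
#' sample, and computes the capture-success statistics.
#'
#' @param seed master seed; read-set seeds are derived from it.
#' @param cfg simulation configuration; defaults to [sim_config()] under
#'   `seed`.
#' @param n_samples_per_clade capture samples simulated per clade.
#' @return list with the stage outputs: `space`, `tier1`, `skims`, `tier2`,
#'   `probes`, `samples` (capture reads with truth flags), `sample_clades`,
#'   `evaluate`.
#' @export
run_synthetic_study <- function(seed = 1, cfg = sim_config(seed = seed),
                                n_samples_per_clade = 1) {
  space <- make_gene_space(cfg)
  tier1 <- run_tier1(space)
  skims <- list(
    cladeA = simulate_skim_reads(space$clade_genomes$cladeA, cfg,
                                 seed = sp_derive_seed(seed, 1)),
    cladeB = simulate_skim_reads(space$clade_genomes$cladeB, cfg,
                                 seed = sp_derive_seed(seed, 2)))
  tier2 <- run_tier2(tier1$registry, skims,
                     plastid = space$organelle$plastid,
                     mito = space$organelle$mito)
  probes <- run_probes(tier2,
                       plastid = space$organelle$plastid,
                       mito = space$organelle$mito,
                       nuclear_decoy = space$nuclear_decoy,
                       registry = tier1$registry)
  off_target <- tibble(
    id = c("plastid", "mito", "nuclear_decoy"),
    seq = c(space$organelle$plastid, space$organelle$mito, space$nuclear_decoy))
  samples <- list()
  sample_clades <- list()
  i <- 0
  for (clade in c("cladeA", "cladeB")) {
    truth_col <- paste0(clade, "_genomic")
    pool <- tibble(id = space$truth$locus_id, seq = space$truth[[truth_col]])
    for (rep in seq_len(n_samples_per_clade)) {
      i <- i + 1
      sid <- sprintf("%s_s%d", clade, rep)
      samples[[sid]] <- simulate_capture_reads(
        pool, off_target, cfg, seed = sp_derive_seed(seed, 10 + i))
      sample_clades[[i]] <- tibble(sample_id = sid, clade = clade)
    }
  }
  sample_clades <- bind_rows(sample_clades)
  evaluate <- run_evaluate(
    probes$templates,
    lapply(samples, function(s) s[, c("id", "seq")]),
    sample_clades)
  list(space = space, tier1 = tier1, skims = skims, tier2 = tier2,
       probes = probes, samples = samples, sample_clades = sample_clades,
       evaluate = evaluate)
}

#' Own-clade vs cross-clade template identity
#'
#' For every recovered (sample, template) pair whose template came from a
#' genome skim, the gapped identity is grouped by whether the template's
#' source clade matches the sample's clade — the directional comparison that
#' shows clade-matched templates capture better.
#'
#' @param study output of [run_synthetic_study()].
#' @return tibble `sample_id`, `own_clade`, `mean_identity`, `n`.
#' @export
clade_identity_contrast <- function(study) {
  ts <- left_join(study$evaluate$template_stats,
                  study$probes$templates[, c("template_id", "source_class")],
                  by = "template_id")
  ts <- ts[ts$recovered & grepl("^skim_", ts$source_class), , drop = FALSE]
  ts <- left_join(ts, study$sample_clades, by = "sample_id")
  ts$own_clade <- ts$source_class == paste0("skim_", ts$clade)
  ts |>
    group_by(.data$sample_id, .data$own_clade) |>
    summarise(mean_identity = mean(.data$identity_pct), n = n(),
              .groups = "drop")
}
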