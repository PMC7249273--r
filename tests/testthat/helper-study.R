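# Shared end-to-end study fixture, built once per test session.

.study_cache <- new.env(parent = emptyenv())

study_fixture <- function(seed = 7) {
  key <- paste0("s", seed)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- suppressWarnings(suppressMessages(
      run_synthetic_study(seed = seed)))
  }
  .study_cache[[key]]
}

# Map registry locus ids (namespaced, genome-prefixed) back to the
# simulator's truth locus ids.
truth_locus_of <- function(study, registry_ids) {
  sc <- rbind(study$space$sc_lists$genomeA, study$space$sc_lists$genomeB)
  q <- rbind(study$space$queries$published, study$space$queries$functional)
  bare <- sub("^(mm|univ|pub|fun)::", "", registry_ids)
  out <- character(length(bare))
  gene_hit <- match(bare, sc$gene_id)
  out[!is.na(gene_hit)] <- sc$locus_id[gene_hit[!is.na(gene_hit)]]
  query_hit <- match(bare, q$id)
  out[!is.na(query_hit)] <- q$locus_id[query_hit[!is.na(query_hit)]]
  out[out == ""] <- bare[out == ""]   # universal ids are already truth ids
  out
}
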