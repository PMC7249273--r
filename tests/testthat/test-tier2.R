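test_that("k-mer index enumerates positions on both strands", {
  set.seed(71)
  core <- rand_seq(11)
  ref <- paste0(core, core, rand_seq(30))   # core at offsets 0 and 11
  idx <- index_reference(tibble::tibble(id = "r", seq = ref), k = 11)
  hit <- lookup_kmer(idx, core)
  fwd <- hit[hit$strand == "+", ]
  expect_true(all(c(0, 11) %in% fwd$pos))
  # reverse complement of a present k-mer hits with strand -
  rc_hit <- lookup_kmer(idx, revcomp(core))
  expect_true(any(rc_hit$strand == "-" & rc_hit$pos %in% c(0, 11)))
  # absent k-mer -> empty
  expect_equal(nrow(lookup_kmer(idx, strrep("A", 11))), 0)
  expect_error(index_reference(tibble::tibble(id = "r", seq = ref), k = 5), ">= 11")
  expect_warning(
    index_reference(tibble::tibble(id = c("r", "tiny"), seq = c(ref, "ACGT")),
                    k = 11), "skipped")
})

test_that("reads place at their true location, orientation, and identity", {
  set.seed(73)
  ref <- rand_seq(500)
  idx <- index_reference(tibble::tibble(id = "ref", seq = ref), k = 13)
  reads <- tibble::tibble(
    id = c("exact", "rc", "junk"),
    seq = c(substr(ref, 38, 137),
            revcomp(substr(ref, 201, 300)),
            rand_seq(100)))
  pl <- map_reads(reads, idx, min_identity = 0.8)
  expect_equal(nrow(pl), 2)
  ex <- pl[pl$read_id == "exact", ]
  expect_equal(ex$ref_start, 37)
  expect_equal(ex$strand, "+")
  expect_equal(ex$identity, 1.0)
  expect_equal(pl[pl$read_id == "rc", ]$strand, "-")
  expect_equal(pl[pl$read_id == "rc", ]$ref_start, 200)
  expect_gte(attr(pl, "n_unplaced"), 1)
})

tiled_reads <- function(ref, read_len = 100, step = 40) {
  offs <- unique(c(seq(0, nchar(ref) - read_len, by = step),
                   nchar(ref) - read_len))
  offs <- rep(offs, each = 2)  # depth >= 2 everywhere, including the ends
  tibble::tibble(id = sprintf("t%03d", seq_along(offs)),
                 seq = substring(ref, offs + 1, offs + read_len))
}

test_that("error-free full-coverage reads reproduce the reference exactly", {
  set.seed(79)
  ref <- rand_seq(600)
  reft <- tibble::tibble(id = "L1", seq = ref)
  idx <- index_reference(reft, k = 13)
  pl <- map_reads(tiled_reads(ref), idx)
  ct <- consensus_contigs(pl, reft, min_depth = 2, flank_bp = 0)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$seq, ref)
  expect_equal(c(ct$ref_start, ct$ref_end), c(0, 600))
})

test_that("a coverage hole splits the assembly into two contigs", {
  set.seed(83)
  ref <- rand_seq(700)
  reft <- tibble::tibble(id = "L1", seq = ref)
  idx <- index_reference(reft, k = 13)
  left <- tiled_reads(substr(ref, 1, 250))
  right <- tiled_reads(substr(ref, 401, 700))
  right$id <- paste0("R", right$id)
  pl <- map_reads(dplyr::bind_rows(left, right), idx)
  ct <- consensus_contigs(pl, reft, min_depth = 2, flank_bp = 0)
  expect_equal(nrow(ct), 2)
  expect_equal(ct$seq[1], substr(ref, 1, 250))
  expect_equal(ct$seq[2], substr(ref, 401, 700))
  expect_equal(ct$ref_start, c(0, 400))
  expect_equal(ct$ref_end, c(250, 700))
})

test_that("no placements yield no contigs", {
  ct <- consensus_contigs(map_reads(tibble::tibble(id = character(),
                                                   seq = character()),
                                    index_reference(tibble::tibble(
                                      id = "r", seq = rand_seq(100)), k = 13)),
                          tibble::tibble(id = "r", seq = rand_seq(100)))
  expect_equal(nrow(ct), 0)
})

mk_star <- function(ref, contigs) {
  star_align(dplyr::bind_rows(tibble::tibble(id = "ref", seq = ref),
                              tibble::tibble(id = names(contigs),
                                             seq = unname(unlist(contigs)))),
             "ref")
}

test_that("template selection follows the identity-clustering rules", {
  set.seed(89)
  ref <- rand_seq(600)
  # two contigs >= 90% identical to the reference -> one template
  near <- list(c1 = mutate_at_rate(ref, 0.02), c2 = mutate_at_rate(ref, 0.03))
  meta <- tibble::tibble(id = c("ref", "c1", "c2"),
                         source_class = c("transcriptome", "skim_cladeA", "skim_cladeB"))
  one <- select_templates(mk_star(ref, near), meta, "L1", "markerminer")
  expect_equal(nrow(one), 1)
  # two mutually divergent full-length contigs -> multiple templates
  far <- list(c1 = mutate_at_rate(ref, 0.18), c2 = ref)
  multi <- select_templates(mk_star(ref, far), meta, "L1", "markerminer")
  expect_gte(nrow(multi), 2)
  expect_true(all(grepl("^L1__t\\d__", multi$template_id)))
})

test_that("markerminer loci without contigs are omitted; others fall back to the reference", {
  ref <- rand_seq(500)
  aln <- star_align(tibble::tibble(id = "ref", seq = ref), "ref")
  meta <- tibble::tibble(id = "ref", source_class = "transcriptome")
  omitted <- select_templates(aln, meta, "L1", "markerminer")
  expect_equal(nrow(omitted), 0)
  kept <- select_templates(aln, meta, "U1", "universal")
  expect_equal(nrow(kept), 1)
  expect_equal(kept$seq, ref)
  # all contigs below min_contig: reference is the sole template
  set.seed(97)
  short <- list(s1 = substr(ref, 1, 250))
  meta2 <- tibble::tibble(id = c("ref", "s1"),
                          source_class = c("transcriptome", "skim_cladeA"))
  solo <- select_templates(mk_star(ref, short), meta2, "L1", "markerminer",
                           min_contig = 300)
  expect_equal(nrow(solo), 1)
  expect_equal(solo$source_class, "transcriptome")
})

test_that("template count is capped with the smallest clusters dropped", {
  set.seed(101)
  ref <- rand_seq(600)
  # six mutually divergent sequences force more clusters than the cap
  contigs <- setNames(lapply(1:6, function(i) rand_seq(600 - 10 * i)),
                      sprintf("c%d", 1:6))
  meta <- tibble::tibble(id = c("ref", names(contigs)),
                         source_class = c("transcriptome",
                                          rep("skim_cladeA", 6)))
  suppressMessages(capped <- select_templates(
    mk_star(ref, contigs), meta, "L1", "markerminer", min_contig = 300))
  expect_lte(nrow(capped), 4)
  expect_gte(length(attr(capped, "dropped")), 1)
})

test_that("hybrid joining splices contigs onto the backbone segment-wise", {
  set.seed(103)
  backbone <- rand_seq(1000)
  contig <- rand_seq(400)
  h <- hybrid_join(contig, 0, 400, backbone)
  expect_equal(nchar(h$seq), 1000)
  expect_equal(substr(h$seq, 1, 400), contig)
  expect_equal(substr(h$seq, 401, 1000), substr(backbone, 401, 1000))
  full <- hybrid_join(contig, 0, 1000, backbone)
  expect_equal(full$seq, contig)
  mid <- hybrid_join(contig, 300, 700, backbone)
  expect_equal(substr(mid$seq, 1, 300), substr(backbone, 1, 300))
  expect_equal(substr(mid$seq, 301, 700), contig)
  expect_equal(substr(mid$seq, 701, 1000), substr(backbone, 701, 1000))
  expect_equal(mid$provenance$origin, c("backbone", "contig", "backbone"))
  expect_error(hybrid_join(contig, 900, 1100, backbone), "out of bounds")
})

test_that("partial cluster representatives are completed into hybrids", {
  set.seed(107)
  ref <- rand_seq(800)
  # divergent contig covering only the first 400 bp
  partial <- mutate_at_rate(substr(ref, 1, 400), 0.15)
  meta <- tibble::tibble(id = c("ref", "p"),
                         source_class = c("transcriptome", "skim_cladeA"))
  tpl <- select_templates(mk_star(ref, list(p = partial)), meta, "L1",
                          "markerminer", min_contig = 300)
  expect_true("hybrid" %in% tpl$source_class)
  hyb <- tpl[tpl$source_class == "hybrid", ]
  expect_equal(nchar(hyb$seq), 800)
  expect_equal(substr(hyb$seq, 401, 800), substr(ref, 401, 800))
})

test_that("organelle screen flags planted plastid content and spares near misses", {
  set.seed(109)
  plastid <- rand_seq(2000)
  templates <- tibble::tibble(
    template_id = c("contaminated", "clean", "short_hit"),
    seq = c(paste0(rand_seq(200), substr(plastid, 301, 500), rand_seq(200)),
            rand_seq(600),
            paste0(rand_seq(300), substr(plastid, 1001, 1050), rand_seq(250))))
  sc <- organelle_screen(templates, plastid = plastid, mito = rand_seq(2000),
                         min_ident = 90, min_len = 60)
  expect_equal(sc$flagged$template_id, "contaminated")
  expect_equal(sc$flagged$organelle, "plastid")
  expect_setequal(sc$kept$template_id, c("clean", "short_hit"))
  expect_warning(sc2 <- organelle_screen(templates), "SKIPPED")
  expect_equal(nrow(sc2$kept), 3)
})
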