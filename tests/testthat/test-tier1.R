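cand_of <- function(lens) {
  tibble::tibble(locus_id = sprintf("L%d", seq_along(lens)),
                 transcriptome = "txomeA",
                 transcript_id = sprintf("t%d", seq_along(lens)),
                 seq = vapply(lens, function(n) strrep("A", n), character(1)))
}

test_that("minimum gene length is inclusive at 500 bp", {
  expect_equal(nrow(filter_min_gene_length(cand_of(499))), 0)
  expect_equal(nrow(filter_min_gene_length(cand_of(500))), 1)
  expect_equal(dplyr::n_distinct(
    filter_min_gene_length(cand_of(c(450, 500, 1200)))$locus_id), 2)
})

test_that("exon/intron thresholds are strict as printed", {
  expect_true(exon_intron_filter(c(150, 200), 80))
  expect_false(exon_intron_filter(c(119, 300), 50))
  expect_false(exon_intron_filter(c(120, 300), 50))  # 120 itself fails
  expect_false(exon_intron_filter(c(150, 300), 100)) # 100 itself fails
  expect_true(exon_intron_filter(300, integer(0)))   # single exon, vacuous
})

test_that("relaxing the structure filter never un-keeps a kept model", {
  set.seed(21)
  for (i in 1:50) {
    k <- sample(1:5, 1)
    exons <- sample(60:400, k, replace = TRUE)
    introns <- if (k > 1) sample(0:200, k - 1, replace = TRUE) else integer(0)
    strict <- exon_intron_filter(exons, introns, min_exon = 120, max_intron = 100)
    relaxed <- exon_intron_filter(exons, introns, min_exon = 100, max_intron = 150)
    if (strict) expect_true(relaxed)
  }
})

test_that("representative choice: longest wins, ties go to the default source", {
  hits <- tibble::tibble(transcriptome = c("miconia", "medinilla"),
                         transcript_id = c("a", "b"),
                         seq = c(strrep("A", 900), strrep("C", 700)))
  expect_equal(choose_representative(hits, "miconia")$transcript_id, "a")
  tie <- tibble::tibble(transcriptome = c("medinilla", "miconia"),
                        transcript_id = c("b", "a"),
                        seq = c(strrep("C", 800), strrep("A", 800)))
  r <- choose_representative(tie, "miconia")
  expect_equal(r$transcriptome, "miconia")
  expect_equal(r$rep_source, "miconia")
  single <- hits[1, ]
  expect_equal(choose_representative(single, "x")$transcript_id, "a")
  expect_warning(r2 <- choose_representative(tie, default_name = "absent"), "tie")
  expect_equal(r2$transcriptome, "medinilla")  # lexicographic fallback
})

test_that("reciprocal best hits: identity, noise rejection, tie suppression", {
  set.seed(31)
  x <- rand_seq(400)
  p <- reciprocal_best_hit_pairs(tibble::tibble(id = "x", seq = x),
                                 tibble::tibble(id = "xp", seq = x))
  expect_equal(nrow(p), 1)
  expect_equal(p$id_a, "x"); expect_equal(p$id_b, "xp")
  # unrelated random 300-mers with min_score above noise -> no pairs
  a <- tibble::tibble(id = c("a1", "a2"), seq = c(rand_seq(300), rand_seq(300)))
  b <- tibble::tibble(id = c("b1", "b2"), seq = c(rand_seq(300), rand_seq(300)))
  expect_equal(nrow(reciprocal_best_hit_pairs(a, b, min_score = 60)), 0)
  # an exact duplicate in B ties the best hit and suppresses the pairing
  dup <- tibble::tibble(id = c("xp", "xq"), seq = c(x, x))
  expect_message(pd <- reciprocal_best_hit_pairs(
    tibble::tibble(id = "x", seq = x), dup), "tie")
  expect_equal(nrow(pd), 0)
  expect_true("x" %in% attr(pd, "tie_suppressed"))
})

test_that("RBH recovers exactly the planted orthologs and matches brute force", {
  set.seed(41)
  anc <- replicate(3, rand_seq(300))
  setA <- tibble::tibble(
    id = c(sprintf("a%d", 1:3), "adec1", "adec2"),
    seq = c(vapply(anc, mutate_at_rate, character(1), rate = 0.025),
            rand_seq(300), rand_seq(300)))
  setB <- tibble::tibble(
    id = c(sprintf("b%d", 1:3), "bdec1", "bdec2"),
    seq = c(vapply(anc, mutate_at_rate, character(1), rate = 0.025),
            rand_seq(300), rand_seq(300)))
  got <- reciprocal_best_hit_pairs(setA, setB, min_score = 60)
  expect_equal(got$id_a, c("a1", "a2", "a3"))
  expect_equal(got$id_b, c("b1", "b2", "b3"))
  ora <- oracle_rbh(setA, setB, min_score = 60)
  expect_equal(got$id_a, ora$id_a)
  expect_equal(got$id_b, ora$id_b)
  # symmetry: swapping the sets transposes the pairing
  rev <- reciprocal_best_hit_pairs(setB, setA, min_score = 60)
  expect_equal(rev$id_a, got$id_b[order(got$id_b)])
  expect_equal(rev$id_b[order(rev$id_a)], got$id_a[order(got$id_b)])
})

reg_of <- function(prefix, n, len = 300) {
  tibble::tibble(locus_id = sprintf("%s%03d", prefix, seq_len(n)),
                 source_method = "markerminer",
                 genome_origin = if (prefix == "a") "genomeA" else "genomeB",
                 rep_id = sprintf("%s%03d_t", prefix, seq_len(n)),
                 rep_source = "txomeA",
                 rep_seq = replicate(n, rand_seq(len)))
}

test_that("dedupe obeys the size identity and keeps the longer transcript", {
  set.seed(51)
  ra <- reg_of("a", 5); rb <- reg_of("b", 7)
  expect_equal(nrow(dedupe_overlapping(ra, rb, ra_pairs <- tibble::tibble(
    id_a = character(), id_b = character(), score_ab = numeric(),
    score_ba = numeric()))), 12)
  pairs <- tibble::tibble(id_a = c("a001", "a002"), id_b = c("b001", "b002"),
                          score_ab = c(100, 100), score_ba = c(100, 100))
  rb$rep_seq[1] <- rand_seq(500)  # longer B member wins that pair
  m <- dedupe_overlapping(ra, rb, pairs, genome_precedence = "genomeB")
  expect_equal(nrow(m), 5 + 7 - 2)
  expect_equal(nchar(m$rep_seq[m$locus_id == "b001"]), 500)
  expect_equal(m$genome_origin[m$locus_id == "b001"], "both")
  # equal lengths: precedence genome wins
  expect_true("b002" %in% m$locus_id && !"a002" %in% m$locus_id)
  # full overlap: A == B collapses to |A|
  pairs_all <- tibble::tibble(id_a = ra$locus_id, id_b = ra$locus_id,
                              score_ab = 1, score_ba = 1)
  expect_equal(nrow(dedupe_overlapping(ra, ra, pairs_all)), 5)
  bad <- tibble::tibble(id_a = "zzz", id_b = "b001", score_ab = 1, score_ba = 1)
  expect_error(dedupe_overlapping(ra, rb, bad), "unknown locus")
})

test_that("universal loci filter by taxon source with longest-allowed representative", {
  uni <- tibble::tibble(
    locus_id = c("u1", "u1", "u2", "u3", "u3"),
    taxon = c("rosidX", "monocotY", "monocotY", "rosidX", "rosidZ"),
    id = sprintf("s%d", 1:5),
    seq = c(strrep("A", 300), strrep("A", 900), strrep("C", 300),
            strrep("G", 200), strrep("G", 400)))
  out <- filter_universal_by_taxon(uni, c("rosidX", "rosidZ"))
  expect_equal(out$locus_id, c("u1", "u3"))
  # representative is longest among ALLOWED taxa, not overall
  expect_equal(nchar(out$rep_seq[out$locus_id == "u1"]), 300)
  expect_equal(nchar(out$rep_seq[out$locus_id == "u3"]), 400)
  expect_error(filter_universal_by_taxon(uni, character(0)), "non-empty")
})

test_that("external loci map to their transcripts; misses are reported", {
  set.seed(61)
  t1 <- rand_seq(700); t2 <- rand_seq(900)
  txs <- list(txomeA = tibble::tibble(id = "tA", seq = t1),
              txomeB = tibble::tibble(id = "tB", seq = t2))
  queries <- tibble::tibble(id = c("q_exact", "q_none"),
                            seq = c(substr(t1, 100, 500), rand_seq(400)))
  m <- map_external_loci(queries, txs, min_score = 60)
  expect_equal(m$mapped$query_id, "q_exact")
  expect_equal(m$mapped$transcript_id, "tA")
  expect_equal(m$unmapped, "q_none")
  # query hitting both transcriptomes: representative is the longer transcript
  shared <- paste0(substr(t1, 1, 300), substr(t2, 1, 300))
  txs2 <- list(txomeA = tibble::tibble(id = "tA", seq = paste0(shared, rand_seq(100))),
               txomeB = tibble::tibble(id = "tB", seq = paste0(shared, rand_seq(500))))
  m2 <- map_external_loci(tibble::tibble(id = "q", seq = shared), txs2, min_score = 60)
  expect_equal(m2$mapped$transcript_id, "tB")
})

test_that("merging sources preserves counts and catches id collisions", {
  mk <- function(n, origin = "none") tibble::tibble(
    locus_id = sprintf("x%d", seq_len(n)), source_method = "any",
    genome_origin = origin, rep_id = sprintf("r%d", seq_len(n)),
    rep_source = "s", rep_seq = strrep("A", 10))
  out <- merge_sources(mk(5), mk(4), mk(2), mk(1))
  expect_equal(nrow(out), 12)
  expect_equal(as.integer(table(out$source_method)[c("markerminer", "universal")]),
               c(5L, 4L))
  expect_equal(nrow(merge_sources(NULL, NULL, NULL, NULL)), 0)
  dup <- mk(2); dup$locus_id <- c("x1", "x1")
  expect_error(merge_sources(dup, NULL, NULL, NULL), "collision")
})
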