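test_that("recovery picks the best qualifying contig with gapped identity", {
  set.seed(139)
  tpl <- rand_seq(400)
  exact <- recovered_sequence(tpl, tibble::tibble(seq = tpl))
  expect_true(exact$recovered)
  expect_equal(exact$recovered_len, 400)
  expect_equal(exact$identity_pct, 100)
  # heavily mutated contig falls below the 55% identity floor
  bad <- recovered_sequence(tpl, tibble::tibble(seq = mutate_at_rate(tpl, 0.6)))
  expect_false(bad$recovered)
  none <- recovered_sequence(tpl, tibble::tibble(seq = character()))
  expect_false(none$recovered)
  # a half-length contig: local identity high, gapped identity ~50
  half <- recovered_sequence(tpl, tibble::tibble(seq = substr(tpl, 1, 200)))
  expect_true(half$recovered)
  expect_lt(half$identity_pct, 60)
})

test_that("the 50%-of-reference count is inclusive", {
  stats <- tibble::tibble(recovered = c(TRUE, TRUE, TRUE, FALSE),
                          recovered_len = c(60, 49, 50, 80),
                          reference_len = c(100, 100, 100, 100))
  expect_equal(count_templates_at_50pct(stats), 2)
  expect_equal(count_templates_at_50pct(stats[0, ]), 0)
})

test_that("paralog flag requires two long contigs", {
  set.seed(149)
  tpl <- rand_seq(500)
  long1 <- substr(tpl, 1, 460); long2 <- mutate_at_rate(substr(tpl, 21, 500), 0.05)
  expect_true(flag_paralogs(tibble::tibble(seq = c(long1, long2)), tpl))
  short <- substr(tpl, 1, 150)
  expect_false(flag_paralogs(tibble::tibble(seq = c(long1, short)), tpl))
  expect_false(flag_paralogs(tibble::tibble(seq = character()), tpl))
})

test_that("on-target percentage handles the edge cases", {
  expect_equal(on_target_fraction(100, 100), 100)
  expect_equal(on_target_fraction(0, 100), 0)
  expect_equal(on_target_fraction(50, 100), 50)
  expect_message(expect_true(is.na(on_target_fraction(0, 0))), "zero")
})

test_that("locus rollup takes unions over templates", {
  samples <- sprintf("s%02d", 1:40)
  tmap <- tibble::tibble(template_id = c("t1", "t2", "u1"),
                         locus_id = c("L1", "L1", "L2"))
  stats <- dplyr::bind_rows(
    tibble::tibble(sample_id = samples, template_id = "t1",
                   recovered = samples %in% sprintf("s%02d", 1:30),
                   recovered_len = ifelse(samples %in% sprintf("s%02d", 1:30), 300L, 0L)),
    tibble::tibble(sample_id = samples, template_id = "t2",
                   recovered = samples %in% sprintf("s%02d", 25:40),
                   recovered_len = ifelse(samples %in% sprintf("s%02d", 25:40), 500L, 0L)),
    tibble::tibble(sample_id = samples, template_id = "u1",
                   recovered = FALSE, recovered_len = 0L))
  r <- locus_rollup(stats, tmap)
  expect_equal(r$per_locus$n_taxa[r$per_locus$locus_id == "L1"], 40)
  expect_equal(r$per_locus$n_taxa[r$per_locus$locus_id == "L2"], 0)
  # union recovery and max length within a sample
  s27 <- r$per_sample[r$per_sample$sample_id == "s27" &
                        r$per_sample$locus_id == "L1", ]
  expect_true(s27$recovered)
  expect_equal(s27$recovered_len, 500)
  # rollup taxon count >= any single template's count
  expect_gte(r$per_locus$n_taxa[r$per_locus$locus_id == "L1"], 30)
  expect_error(locus_rollup(tibble::tibble(sample_id = "s", template_id = "zz",
                                           recovered = TRUE, recovered_len = 1L),
                            tmap), "unknown template")
})

test_that("clade summaries satisfy min <= mean <= max and supercontig additivity", {
  ss <- tibble::tibble(sample_id = c("a", "b", "c"),
                       clade = c("X", "X", "Y"),
                       on_target = c(80, 90, 70),
                       exon_len = c(400, 500, 300),
                       intron_len = c(800, 700, 100))
  cs <- clade_summary(ss)
  ot <- cs[cs$clade == "X" & cs$metric == "on_target", ]
  expect_equal(c(ot$mean, ot$min, ot$max), c(85, 80, 90))
  sup <- cs[cs$clade == "X" & cs$metric == "supercontig_len", ]
  expect_equal(sup$mean, mean(c(1200, 1200)))
  y <- cs[cs$clade == "Y" & cs$metric == "exon_len", ]
  expect_equal(c(y$mean, y$min, y$max), c(300, 300, 300))
  expect_true(all(cs$min <= cs$mean + 1e-9 & cs$mean <= cs$max + 1e-9))
})

test_that("variation statistics classify columns per the PIS definition", {
  same <- rep(strrep("ACGT", 3), 4)
  vs <- alignment_variation_stats(same, "exons")
  expect_equal(vs$pis_count, 0)
  expect_equal(vs$constant_sites, 12)
  expect_equal(vs$missing_pct, 0)
  # 4 x 6 toy: one PIS column (A/A/G/G), one variable-uninformative (A/A/A/G)
  toy <- c("AAACGT", "AAACGT", "GAACGT", "GGACGT")
  vt <- alignment_variation_stats(toy)
  expect_equal(vt$pis_count, 1)
  expect_equal(vt$variable_uninformative, 1)
  expect_equal(vt$constant_sites, 4)
  # three-way partition of non-missing columns
  expect_equal(vt$pis_count + vt$constant_sites + vt$variable_uninformative,
               vt$alignment_length)
  # gaps and N are missing data
  gappy <- c("AC-T", "ACNT", "AC-T")
  vg <- alignment_variation_stats(gappy)
  expect_equal(vg$missing_pct, round(100 * 3 / 12, 1))
  expect_error(alignment_variation_stats(c("", "")), "zero-column")
})

test_that("percentages round half-up to one decimal", {
  expect_equal(round_half_up(9.45, 1), 9.5)
  expect_equal(round_half_up(9.44, 1), 9.4)
  expect_equal(round_half_up(26.05, 1), 26.1)
  expect_equal(variation_stats(95, 1000)$pis_pct, 9.5)
})
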