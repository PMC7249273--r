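test_that("sanitization strips gaps and resolves ambiguity from the column", {
  expect_equal(sanitize_template("AC-GT"), "ACGT")
  expect_equal(sanitize_template("ACGT"), "ACGT")
  # 'R' resolved to the most frequent base among A,A,G in its column
  aln <- structure(list(rows = c(t = "ACRGT", x = "ACAGT", y = "ACAGT",
                                 z = "ACGGT"),
                        ref_id = "t"), class = "star_alignment")
  expect_equal(sanitize_template("ACRGT", alignment = aln, row_id = "t"),
               "ACAGT")
  # without column support: alphabetically first compatible base
  expect_equal(sanitize_template("RYK"), "ACG")
  # idempotent
  set.seed(113)
  for (i in 1:10) {
    s <- paste0(rand_seq(30), "-R-", rand_seq(30), "N")
    once <- sanitize_template(s)
    expect_equal(sanitize_template(once), once)
    expect_false(grepl("[^ACGT]", once))
  }
})

test_that("probe tiling follows the 40-bp step with a terminal probe", {
  t120 <- tile_probes(tibble::tibble(template_id = "a", seq = strrep("ACGT", 30)))
  expect_equal(nrow(t120), 1)
  expect_equal(c(t120$start, t120$end), c(0, 120))
  set.seed(127)
  t200 <- tile_probes(tibble::tibble(template_id = "a", seq = rand_seq(200)))
  expect_equal(t200$start, c(0, 40, 80))
  expect_equal(t200$flags, c("", "", ""))
  t201 <- tile_probes(tibble::tibble(template_id = "a", seq = rand_seq(201)))
  expect_equal(t201$start, c(0, 40, 80, 81))
  expect_equal(t201$flags, c("", "", "", "terminal"))
  expect_warning(short <- tile_probes(tibble::tibble(template_id = "a",
                                                     seq = rand_seq(100))),
                 "shorter than probe length")
  expect_equal(nrow(short), 0)
  expect_error(tile_probes(tibble::tibble(template_id = "a",
                                          seq = rand_seq(200)), tiling = 7),
               "does not divide")
})

test_that("probe counts and coverage match offset enumeration", {
  set.seed(131)
  for (L in c(120, 160, 161, 240, 359, 360, 481, 1000)) {
    probes <- tile_probes(tibble::tibble(template_id = "a", seq = rand_seq(L)))
    n_expected <- floor((L - 120) / 40) + 1 + as.integer((L - 120) %% 40 != 0)
    expect_equal(nrow(probes), n_expected)
    # coverage: every base covered by <= 3 non-terminal probes; interior
    # bases >= 120 from both ends by exactly 3
    cov <- integer(L)
    nt <- probes[probes$flags != "terminal", ]
    for (i in seq_len(nrow(nt))) {
      cov[(nt$start[i] + 1):nt$end[i]] <- cov[(nt$start[i] + 1):nt$end[i]] + 1L
    }
    expect_lte(max(cov), 3)
    interior <- setdiff(seq_len(L), c(1:120, (L - 119):L))
    if (length(interior) > 0) expect_true(all(cov[interior] == 3))
  }
})

test_that("homopolymer screen rejects runs at the threshold", {
  expect_false(homopolymer_filter(paste0(strrep("A", 10), rand_seq(110))))
  expect_true(homopolymer_filter(paste0(strrep("A", 9), "C", rand_seq(110))))
  expect_true(homopolymer_filter(strrep("ACGT", 30)))
})

test_that("decoy screen flags verbatim matches and passes sub-threshold ones", {
  set.seed(137)
  plastid <- rand_seq(2000)
  nuc <- rand_seq(2000)
  probes <- tibble::tibble(
    probe_id = c("p_plastid", "p_random", "p_near"),
    template_id = "t", start = 0L, end = 120L,
    seq = c(substr(plastid, 101, 220),
            rand_seq(120),
            mutate_at_rate(substr(nuc, 501, 620), 0.15)),  # ~85% identity
    flags = "")
  sc <- decoy_screen(probes, plastid = plastid, nuclear_decoy = nuc,
                     min_ident = 90, min_len = 60)
  expect_equal(sc$flagged$probe_id, "p_plastid")
  expect_match(sc$flagged$flags, "organelle_hit")
  expect_setequal(sc$kept$probe_id, c("p_random", "p_near"))
  expect_warning(decoy_screen(probes), "skipped")
})

test_that("panel summary reproduces totals from the multiplicity histogram", {
  mk_panel <- function(hist) {
    rows <- list(); li <- 0
    for (m in seq_along(hist)) {
      for (i in seq_len(hist[m])) {
        li <- li + 1
        rows[[length(rows) + 1]] <- tibble::tibble(
          template_id = sprintf("L%04d__t%d", li, seq_len(m)),
          locus_id = sprintf("L%04d", li))
      }
    }
    dplyr::bind_rows(rows)
  }
  tpl <- mk_panel(c(2, 3, 1))   # 2 + 6 + 3 = 11 templates, 6 loci
  ps <- panel_summary(tpl[0, ] |> dplyr::mutate(start = integer(),
                                                seq = character(),
                                                flags = character()),
                      tpl)
  expect_equal(ps$totals$n_templates, 11)
  expect_equal(ps$totals$n_loci, 6)
  expect_equal(ps$multiplicity$n_loci, c(2, 3, 1))
  expect_equal(glance(ps)$n_templates, 11)
  expect_equal(tidy(ps)$n_loci, c(2, 3, 1))
  # empty panel: all-zero summary
  empty <- panel_summary(tibble::tibble(template_id = character(),
                                        flags = character()),
                         tibble::tibble(template_id = character(),
                                        locus_id = character()))
  expect_equal(unlist(empty$totals), c(n_loci = 0L, n_templates = 0L,
                                       n_probes = 0L))
  # dangling template reference
  bad <- tibble::tibble(probe_id = "p", template_id = "ghost", flags = "")
  expect_error(panel_summary(bad, tpl), "unknown template")
})
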