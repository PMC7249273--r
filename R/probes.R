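# Probe construction: sanitize templates (strip alignment gaps, resolve
# ambiguity codes from the locus alignment), tile into fixed-length probes,
# and screen against homopolymers and organellar/nuclear decoy references.

#' Sanitize a template for probe synthesis
#'
#' Removes alignment gaps and resolves IUPAC ambiguity codes so the output is
#' strictly over `{A, C, G, T}`. When the locus alignment is supplied, each
#' ambiguous position is replaced by the most frequent unambiguous base in
#' its alignment column (ties broken by the alphabetically first base
#' compatible with the code); without column support, the alphabetically
#' first compatible base is used.
#'
#' @param template possibly gapped/ambiguous template sequence, or its
#'   aligned row when `alignment` is given.
#' @param alignment optional `star_alignment` of the template's locus.
#' @param row_id the template's row id within `alignment`.
#' @return cleaned sequence over `{A, C, G, T}`. Idempotent.
#' @examples
#' sanitize_template("AC-GT")   # "ACGT"
#' @export
sanitize_template <- function(template, alignment = NULL, row_id = NULL) {
  chars <- strsplit(template, "", fixed = TRUE)[[1]]
  ambiguous <- !(chars %in% c("A", "C", "G", "T", "-"))
  if (any(ambiguous)) {
    col_support <- NULL
    if (!is.null(alignment) && !is.null(row_id) &&
        row_id %in% names(alignment$rows) &&
        nchar(alignment$rows[[row_id]]) == length(chars)) {
      other <- setdiff(names(alignment$rows), row_id)
      col_support <- lapply(other, function(id)
        strsplit(alignment$rows[[id]], "", fixed = TRUE)[[1]])
    }
    for (i in which(ambiguous)) {
      code <- chars[i]
      compat <- sp_iupac_map[[code]]
      if (is.null(compat)) abort(sprintf("invalid character '%s' in template", code))
      pick <- compat[1]
      if (!is.null(col_support)) {
        col <- vapply(col_support, `[`, character(1), i)
        col <- col[col %in% c("A", "C", "G", "T")]
        if (length(col) > 0) {
          tab <- table(col)
          best <- names(tab)[tab == max(tab)]
          pick <- if (any(best %in% compat)) sort(best[best %in% compat])[1]
                  else sort(best)[1]
        } else {
          inform(sprintf(
            "sanitize_template: no unambiguous support at column %d; using '%s'",
            i, pick))
        }
      }
      chars[i] <- pick
    }
  }
  paste(chars[chars != "-"], collapse = "")
}

#' Tile a template into fixed-length probes
#'
#' Probes of length `probe_len` start at offsets `0, step, 2*step, ...` with
#' `step = probe_len / tiling`, while the probe fits on the template. If the
#' template end is not reached exactly, a final probe flush with the 3' end
#' is added and flagged `terminal`, so no template base is left uncovered.
#' Templates shorter than `probe_len` yield no probes (with a warning).
#'
#' @param templates tibble with `template_id` and sanitized `seq` (a single
#'   sequence string is also accepted).
#' @param probe_len probe length in bp.
#' @param tiling coverage multiplier; must divide `probe_len` exactly.
#' @return probe tibble: `probe_id`, `template_id`, `start`, `end` (0-based
#'   half-open on the template), `seq`, `flags` (comma-separated, `""` or
#'   `"terminal"`).
#' @examples
#' tile_probes(tibble::tibble(template_id = "t", seq = strrep("A", 201)))
#' @export
tile_probes <- function(templates, probe_len = 120, tiling = 3) {
  if (probe_len %% tiling != 0) {
    abort(sprintf("tiling %d does not divide probe_len %d", tiling, probe_len))
  }
  if (is.character(templates)) {
    templates <- tibble(template_id = "template", seq = templates)
  }
  step <- probe_len %/% tiling
  out <- list()
  for (i in seq_len(nrow(templates))) {
    s <- templates$seq[i]
    L <- nchar(s)
    if (L < probe_len) {
      warn(sprintf("template '%s' (%d bp) shorter than probe length %d; no probes",
                   templates$template_id[i], L, probe_len))
      next
    }
    offs <- seq(0L, L - probe_len, by = step)
    flags <- rep("", length(offs))
    if ((L - probe_len) %% step != 0) {
      offs <- c(offs, L - probe_len)
      flags <- c(flags, "terminal")
    }
    out[[length(out) + 1]] <- tibble(
      template_id = templates$template_id[i],
      start = as.integer(offs), end = as.integer(offs + probe_len),
      seq = substring(s, offs + 1, offs + probe_len),
      flags = flags)
  }
  probes <- if (length(out)) bind_rows(out) else
    tibble(template_id = character(), start = integer(), end = integer(),
           seq = character(), flags = character())
  probes$probe_id <- sprintf("%s|%d-%d", probes$template_id, probes$start, probes$end)
  probes[, c("probe_id", "template_id", "start", "end", "seq", "flags")]
}

#' Homopolymer screen
#'
#' @param seq probe sequence(s), sanitized.
#' @param max_run a probe is rejected iff it contains a single-base run of at
#'   least this length.
#' @return logical vector: `TRUE` = keep.
#' @examples
#' homopolymer_filter(c(strrep("A", 10), "ACGTACGT"))
#' @export
homopolymer_filter <- function(seq, max_run = 10) {
  vapply(seq, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    max(r$lengths) < max_run
  }, logical(1), USE.NAMES = FALSE)
}

#' Screen probes against decoy references
#'
#' Probes with a local alignment (either strand) of identity >= `min_ident`
#' percent over >= `min_len` columns to a decoy are flagged — `organelle_hit`
#' for the plastid/mitochondrial decoys, `nuclear_decoy_hit` for the nuclear
#' decoy — and excluded from the panel. With no decoys supplied the screen is
#' skipped with a warning.
#'
#' @param probes probe tibble from [tile_probes()].
#' @param plastid,mito,nuclear_decoy decoy reference sequences or `NULL`.
#' @param min_ident percent-identity threshold.
#' @param min_len minimum aligned columns.
#' @param scores scoring scheme.
#' @return list with `kept` (probes passing, original `flags` preserved) and
#'   `flagged` (probes with an added flag and columns `decoy`,
#'   `identity_pct`, `aln_len`).
#' @export
decoy_screen <- function(probes, plastid = NULL, mito = NULL,
                         nuclear_decoy = NULL, min_ident = 90, min_len = 60,
                         scores = sp_scores()) {
  decoys <- list(plastid = plastid, mito = mito, nuclear_decoy = nuclear_decoy)
  decoys <- decoys[!vapply(decoys, is.null, logical(1))]
  if (length(decoys) == 0) {
    warn("decoy_screen: no decoy reference supplied; screen skipped")
    return(list(kept = probes,
                flagged = probes[0, ]))
  }
  if (nrow(probes) == 0) return(list(kept = probes, flagged = probes[0, ]))
  hit_any <- rep(FALSE, nrow(probes))
  flag_rows <- list()
  for (d in names(decoys)) {
    la <- local_align(probes$seq, decoys[[d]], scores = scores, both_strands = TRUE)
    hit <- la$identity_pct >= min_ident & la$aln_len >= min_len
    if (any(hit)) {
      fl <- probes[hit, , drop = FALSE]
      fl$decoy <- d
      fl$identity_pct <- la$identity_pct[hit]
      fl$aln_len <- la$aln_len[hit]
      flag_class <- if (d == "nuclear_decoy") "nuclear_decoy_hit" else "organelle_hit"
      fl$flags <- ifelse(nzchar(fl$flags), paste(fl$flags, flag_class, sep = ","),
                         flag_class)
      flag_rows[[d]] <- fl
      hit_any <- hit_any | hit
    }
  }
  flagged <- if (length(flag_rows)) bind_rows(flag_rows) else {
    fl <- probes[0, ]
    fl$decoy <- character(0); fl$identity_pct <- numeric(0); fl$aln_len <- numeric(0)
    fl
  }
  list(kept = probes[!hit_any, , drop = FALSE], flagged = flagged)
}

#' Summarize a probe panel
#'
#' Bookkeeping over the final panel: locus/template/probe counts, the
#' template-multiplicity histogram (how many loci have 1, 2, 3, 4 templates),
#' probes-per-template distribution, and flag counts by class. Errors if a
#' probe references a template absent from `templates`, or a template a locus
#' absent from `registry`.
#'
#' @param probes probe tibble (may be empty).
#' @param templates template tibble (`template_id`, `locus_id`).
#' @param registry locus registry tibble (`locus_id`), optional; defaults to
#'   the loci present in `templates`.
#' @return object of class `panel_summary`: list with `totals` (one-row
#'   tibble `n_loci`, `n_templates`, `n_probes`), `multiplicity` (tibble
#'   `n_templates_per_locus`, `n_loci`), `probes_per_template`, and
#'   `flag_counts`.
#' @export
panel_summary <- function(probes, templates, registry = NULL) {
  if (nrow(probes) > 0) {
    dangling <- setdiff(probes$template_id, templates$template_id)
    if (length(dangling) > 0) {
      abort(sprintf("probe references unknown template '%s'", dangling[1]))
    }
  }
  if (!is.null(registry) && nrow(templates) > 0) {
    dangling <- setdiff(templates$locus_id, registry$locus_id)
    if (length(dangling) > 0) {
      abort(sprintf("template references unknown locus '%s'", dangling[1]))
    }
  }
  per_locus <- templates |>
    group_by(.data$locus_id) |>
    summarise(n_templates = n(), .groups = "drop")
  multiplicity <- per_locus |>
    group_by(n_templates_per_locus = .data$n_templates) |>
    summarise(n_loci = n(), .groups = "drop") |>
    arrange(.data$n_templates_per_locus)
  ppt <- if (nrow(probes) > 0) {
    probes |>
      group_by(.data$template_id) |>
      summarise(n_probes = n(), .groups = "drop")
  } else tibble(template_id = character(), n_probes = integer())
  flags <- if (nrow(probes) > 0 && "flags" %in% names(probes)) {
    fl <- unlist(strsplit(probes$flags[nzchar(probes$flags)], ",", fixed = TRUE))
    if (length(fl)) as_tibble(as.data.frame(table(flag = fl),
                                            stringsAsFactors = FALSE)) |>
      rename(n = "Freq") else tibble(flag = character(), n = integer())
  } else tibble(flag = character(), n = integer())
  structure(list(
    totals = tibble(n_loci = nrow(per_locus), n_templates = nrow(templates),
                    n_probes = nrow(probes)),
    multiplicity = multiplicity,
    probes_per_template = ppt,
    flag_counts = flags), class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("probe panel: %d probes from %d templates across %d loci\n",
              x$totals$n_probes, x$totals$n_templates, x$totals$n_loci))
  if (nrow(x$multiplicity) > 0) {
    cat("templates per locus:",
        paste(sprintf("%dx:%d", x$multiplicity$n_templates_per_locus,
                      x$multiplicity$n_loci), collapse = "  "), "\n")
  }
  if (nrow(x$flag_counts) > 0) {
    cat("flags:", paste(sprintf("%s:%d", x$flag_counts$flag, x$flag_counts$n),
                        collapse = "  "), "\n")
  }
  invisible(x)
}
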