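# Readers and writers for FASTA/FASTQ/gene models/probe files and the
# registry tables that tie the pipeline stages together. All coordinates in
# files and tibbles are 0-based half-open (BED convention).

#' Read a FASTA file into a tibble
#'
#' Sequences are uppercased and RNA `U` is normalized to `T`; IUPAC ambiguity
#' codes are accepted and preserved. Record ids must be unique within a file
#' and unaligned sequences must not contain `-`.
#'
#' @param path path to a FASTA file (plain text or gzipped).
#' @param aligned logical; if `TRUE`, gap characters `-` are permitted
#'   (alignment FASTA).
#' @return a tibble with columns `id`, `desc`, `seq`, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a first", "acgt", ">b", "GGTT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    abort(sprintf("%s: empty file (line 1): expected a FASTA header", path))
  }
  if (!startsWith(lines[nonblank[1]], ">")) {
    abort(sprintf("%s: malformed FASTA at line %d: expected '>' header",
                  path, nonblank[1]))
  }
  hdr <- startsWith(lines, ">")
  grp <- cumsum(hdr)
  if (any(grp == 0 & nzchar(lines))) {
    abort(sprintf("%s: sequence before first header at line %d",
                  path, which(grp == 0 & nzchar(lines))[1]))
  }
  headers <- lines[hdr]
  id <- sub("^>\\s*(\\S+).*$", "\\1", headers)
  desc <- trimws(sub("^>\\s*\\S*", "", headers))
  if (any(id == ">") || any(!nzchar(sub("^>", "", headers)))) {
    abort(sprintf("%s: malformed FASTA header at line %d (empty id)",
                  path, which(hdr)[which(!nzchar(sub("^>\\s*", "", headers)))[1]]))
  }
  seq_lines <- lines[!hdr]
  seq_grp <- grp[!hdr]
  seqs <- vapply(split(seq_lines, factor(seq_grp, levels = seq_along(headers))),
                 function(x) paste(gsub("\\s", "", x), collapse = ""),
                 character(1))
  seqs <- sp_normalize_seq(unname(seqs))
  dup <- duplicated(id)
  if (any(dup)) {
    abort(sprintf("%s: duplicate FASTA id '%s'", path, id[dup][1]))
  }
  if (any(!nzchar(seqs))) {
    abort(sprintf("%s: empty sequence for id '%s'", path, id[!nzchar(seqs)][1]))
  }
  if (!aligned && any(grepl("-", seqs, fixed = TRUE))) {
    abort(sprintf("%s: gap character in unaligned sequence '%s'",
                  path, id[grepl("-", seqs, fixed = TRUE)][1]))
  }
  sp_check_alphabet(seqs, id, allow_gap = aligned)
  tibble(id = id, desc = desc, seq = seqs)
}

#' Write a tibble of sequences to FASTA
#'
#' @param x tibble with columns `id` and `seq` (optional `desc`).
#' @param path output path.
#' @param width line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  desc <- if ("desc" %in% names(x)) x$desc else rep("", nrow(x))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    hdr <- if (nzchar(desc[i])) paste0(">", x$id[i], " ", desc[i]) else paste0(">", x$id[i])
    writeLines(hdr, con)
    s <- x$seq[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' Base qualities are discarded: downstream consensus calling is
#' quality-agnostic by design.
#'
#' @param path path to a FASTQ file (plain text or gzipped).
#' @return a tibble with columns `id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(id = sub("\\s.*$", "", names(x)),
         seq = unname(sp_normalize_seq(as.character(x))))
}

#' Write reads to FASTQ with a constant quality string
#'
#' @param reads tibble with columns `id`, `seq`.
#' @param path output path.
#' @param qual_char single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  quals <- vapply(nchar(reads$seq),
                  function(n) strrep(qual_char, n), character(1))
  out <- rbind(paste0("@", reads$id), reads$seq, "+", quals)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read gene models (exon/intron structure) from TSV or GFF3
#'
#' The TSV form has three or four tab-separated columns and no header:
#' transcript id, comma-separated exon lengths (bp), comma-separated intron
#' lengths (bp, empty for single-exon transcripts), and an optional taxon.
#' The GFF3 form is the usual exon-feature subset: `exon` rows grouped by
#' their `Parent` attribute; intron lengths are the gaps between consecutive
#' exons.
#'
#' @param path input path.
#' @param format `"auto"` (by extension), `"tsv"`, or `"gff3"`.
#' @return tibble with columns `transcript_id`, `taxon`, and list-columns
#'   `exon_lengths`, `intron_lengths` with
#'   `length(intron_lengths) == length(exon_lengths) - 1`.
#' @export
read_gene_models <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    g <- rtracklayer::readGFF(path)
    g <- as.data.frame(g)
    ex <- g[g$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0) abort(sprintf("%s: no exon features", path))
    parent <- vapply(ex$Parent, function(p) as.character(p)[1], character(1))
    ord <- order(parent, ex$start)
    sp <- split(ex[ord, , drop = FALSE], parent[ord])
    rows <- purrr::map2(sp, names(sp), function(d, id) {
      d <- d[order(d$start), ]
      exl <- as.integer(d$end - d$start + 1)
      inl <- if (nrow(d) > 1) as.integer(d$start[-1] - d$end[-nrow(d)] - 1) else integer(0)
      if (any(inl < 0)) abort(sprintf("%s: overlapping exons for '%s'", path, id))
      tibble(transcript_id = id, taxon = NA_character_,
             exon_lengths = list(exl), intron_lengths = list(inl))
    })
    return(bind_rows(rows))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("%s: empty gene-model file", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::imap(parts, function(p, i) {
    if (length(p) < 2) {
      abort(sprintf("%s: line %d: expected at least 2 tab-separated fields", path, i))
    }
    parse_ints <- function(s) {
      s <- trimws(s)
      if (!nzchar(s)) return(integer(0))
      v <- suppressWarnings(as.integer(strsplit(s, ",", fixed = TRUE)[[1]]))
      if (anyNA(v)) abort(sprintf("%s: line %d: non-integer length", path, i))
      v
    }
    exl <- parse_ints(p[2])
    inl <- if (length(p) >= 3) parse_ints(p[3]) else integer(0)
    if (length(exl) == 0) abort(sprintf("%s: line %d: no exon lengths", path, i))
    if (any(exl <= 0)) abort(sprintf("%s: line %d: exon length must be positive", path, i))
    if (any(inl < 0)) abort(sprintf("%s: line %d: negative intron length", path, i))
    if (length(inl) != length(exl) - 1) {
      abort(sprintf(
        "%s: line %d: %d exon(s) need %d intron length(s), got %d",
        path, i, length(exl), length(exl) - 1, length(inl)))
    }
    tibble(transcript_id = p[1],
           taxon = if (length(p) >= 4) p[4] else NA_character_,
           exon_lengths = list(exl), intron_lengths = list(inl))
  })
  out <- bind_rows(rows)
  if (anyDuplicated(out$transcript_id)) {
    abort(sprintf("%s: duplicate transcript id '%s'",
                  path, out$transcript_id[duplicated(out$transcript_id)][1]))
  }
  out
}

#' Write probes to FASTA and BED
#'
#' FASTA ids follow the convention `<template_id>|<start>-<end>`; the BED file
#' is 0-based half-open on template coordinates. Probe coordinates are
#' validated against template lengths when `templates` is supplied.
#'
#' @param probes tibble with columns `probe_id`, `template_id`, `start`,
#'   `end`, `seq`.
#' @param fasta_path,bed_path output paths.
#' @param templates optional tibble with `template_id`, `seq` used to check
#'   probe intervals.
#' @return invisible list of the two paths.
#' @export
write_probes <- function(probes, fasta_path, bed_path, templates = NULL) {
  need <- c("template_id", "start", "end", "seq")
  stopifnot(all(need %in% names(probes)))
  if (!is.null(templates) && nrow(probes) > 0) {
    len <- setNames(nchar(templates$seq), templates$template_id)
    unknown <- setdiff(probes$template_id, names(len))
    if (length(unknown) > 0) {
      abort(sprintf("probe references unknown template '%s'", unknown[1]))
    }
    sp_check_interval(probes$start, probes$end, len[probes$template_id],
                      what = "probe interval")
  }
  fa <- tibble(id = sprintf("%s|%d-%d", probes$template_id, probes$start, probes$end),
               seq = probes$seq)
  write_fasta(fa, fasta_path)
  bed <- data.frame(chrom = probes$template_id, start = probes$start,
                    end = probes$end,
                    name = if ("probe_id" %in% names(probes)) probes$probe_id else fa$id)
  utils::write.table(bed[seq_len(nrow(probes)), , drop = FALSE], bed_path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(list(fasta = fasta_path, bed = bed_path))
}

#' Read probes back from a probe FASTA
#'
#' Inverse of [write_probes()]: parses `<template_id>|<start>-<end>` ids.
#'
#' @param fasta_path probe FASTA path.
#' @return tibble with `probe_id`, `template_id`, `start`, `end`, `seq`.
#' @export
read_probes <- function(fasta_path) {
  empty <- !any(nzchar(trimws(readLines(fasta_path, warn = FALSE))))
  fa <- if (empty) tibble(id = character(), desc = character(),
                          seq = character()) else read_fasta(fasta_path)
  if (nrow(fa) == 0) {
    return(tibble(probe_id = character(), template_id = character(),
                  start = integer(), end = integer(), seq = character()))
  }
  m <- stringr::str_match(fa$id, "^(.*)\\|(\\d+)-(\\d+)$")
  if (anyNA(m[, 1])) abort(sprintf("malformed probe id '%s'", fa$id[is.na(m[, 1])][1]))
  tibble(probe_id = fa$id, template_id = m[, 2],
         start = as.integer(m[, 3]), end = as.integer(m[, 4]), seq = fa$seq)
}

# Fixed registry column order; keeping it stable makes every stage resumable
# from its TSV checkpoint.
sp_registry_cols <- c("locus_id", "source_method", "genome_origin",
                      "rep_id", "rep_source", "rep_seq")

#' Write / read a locus registry TSV
#'
#' The registry is the hand-off between pipeline stages: one row per locus
#' with its source method (`markerminer`, `universal`, `published`,
#' `functional`), genome of origin (`genomeA`, `genomeB`, `both`, `none`),
#' and representative sequence. Columns are written in a fixed order so the
#' files are diffable and resumable.
#'
#' @param registry tibble with at least the registry columns.
#' @param path TSV path.
#' @return `path` (write) or the registry tibble (read).
#' @export
write_registry <- function(registry, path) {
  miss <- setdiff(sp_registry_cols, names(registry))
  if (length(miss) > 0) abort(sprintf("registry missing column '%s'", miss[1]))
  readr::write_tsv(registry[, sp_registry_cols], path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' Write / read a template registry TSV
#'
#' One row per template with its locus, source class and ungapped sequence;
#' segment provenance is serialized as `start-end:origin` triplets separated
#' by `;`.
#'
#' @param templates template tibble as produced by [select_templates()].
#' @param path TSV path.
#' @export
write_templates <- function(templates, path) {
  prov <- vapply(templates$provenance %||% rep(list(NULL), nrow(templates)),
                 function(p) {
                   if (is.null(p) || nrow(p) == 0) return("")
                   paste(sprintf("%d-%d:%s", p$start, p$end, p$origin), collapse = ";")
                 }, character(1))
  out <- tibble(template_id = templates$template_id,
                locus_id = templates$locus_id,
                source_class = templates$source_class,
                seq = templates$seq,
                provenance = prov)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  x$provenance <- purrr::map(x$provenance, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(tibble(start = integer(), end = integer(), origin = character()))
    }
    m <- stringr::str_match(strsplit(s, ";", fixed = TRUE)[[1]],
                            "^(\\d+)-(\\d+):(.*)$")
    tibble(start = as.integer(m[, 2]), end = as.integer(m[, 3]), origin = m[, 4])
  })
  x
}
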