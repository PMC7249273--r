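# Tier 2: recover per-locus contigs from genome-skimming reads against the
# Tier-1 references (exact k-mer seeding + local-alignment extension,
# majority-vote consensus), then curate 1-4 probe-design templates per locus
# by identity clustering, with hybrid joining of partial contigs and an
# organellar contamination screen.

#' Build an exact k-mer index over reference sequences
#'
#' Both strands are indexed: a k-mer from the reverse complement of a
#' reference is stored with strand `-` and its position mapped to
#' forward-strand coordinates. References shorter than `k` are skipped with a
#' warning.
#'
#' @param refs tibble with columns `id`, `seq`.
#' @param k k-mer size (>= 11). The default 13 keeps exact seeding
#'   sensitive at the ~15% divergence separating clades from the reference
#'   transcriptome.
#' @return object of class `kmer_index`.
#' @export
index_reference <- function(refs, k = 13) {
  stopifnot(nrow(refs) > 0)
  if (k < 11) abort("k must be >= 11")
  too_short <- nchar(refs$seq) < k
  if (any(too_short)) {
    warn(sprintf("index_reference: %d reference(s) shorter than k=%d skipped: %s",
                 sum(too_short), k, paste(refs$id[too_short], collapse = ", ")))
    refs <- refs[!too_short, , drop = FALSE]
  }
  if (nrow(refs) == 0) abort("no reference longer than k")
  acc <- vector("list", nrow(refs))
  for (i in seq_len(nrow(refs))) {
    s <- refs$seq[i]
    L <- nchar(s)
    n <- L - k + 1L
    starts <- seq_len(n)
    rc <- revcomp(s)
    # rc-kmer at rc-offset j (0-based) covers forward interval starting L-k-j
    acc[[i]] <- list(
      kmer = c(substring(s, starts, starts + k - 1L),
               substring(rc, starts, starts + k - 1L)),
      ref_i = rep.int(i, 2L * n),
      pos = c(starts - 1L, L - k - (starts - 1L)),
      strand = rep(c("+", "-"), each = n))
  }
  kmer <- unlist(lapply(acc, `[[`, "kmer"), use.names = FALSE)
  ref_i <- unlist(lapply(acc, `[[`, "ref_i"), use.names = FALSE)
  pos <- unlist(lapply(acc, `[[`, "pos"), use.names = FALSE)
  strand <- unlist(lapply(acc, `[[`, "strand"), use.names = FALSE)
  env <- list2env(split(seq_along(kmer), kmer),
                  envir = new.env(parent = emptyenv(), size = length(kmer)))
  structure(list(env = env, ref_i = ref_i, pos = pos, strand = strand,
                 refs = refs, k = k),
            class = "kmer_index")
}

#' Look up one k-mer in an index
#'
#' @param index a `kmer_index`.
#' @param kmer k-mer string (length `index$k`).
#' @return tibble `ref_id`, `pos` (0-based forward-strand start), `strand`;
#'   zero rows if absent.
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"), nchar(kmer) == index$k)
  idx <- get0(kmer, envir = index$env, ifnotfound = integer(0))
  tibble(ref_id = index$refs$id[index$ref_i[idx]],
         pos = index$pos[idx], strand = index$strand[idx])
}

#' Map reads to references by k-mer seeding and local extension
#'
#' Each read contributes a handful of evenly spaced k-mer seeds; candidate
#' (reference, strand) locations are voted on, the top candidates are
#' aligned locally (Smith-Waterman), and the read is placed at its single
#' best location iff the alignment identity reaches `min_identity` over at
#' least `min_anchor` columns. Reads whose two best placements score equally
#' are dropped as ambiguous and counted.
#'
#' @param reads tibble `id`, `seq` over `{A,C,G,T,N}`.
#' @param index `kmer_index` over the references.
#' @param min_identity minimum fraction of matching columns in the local
#'   alignment (default 0.80).
#' @param min_anchor minimum aligned columns for a placement (default 50).
#' @param n_seeds seeds per read.
#' @param scores scoring scheme.
#' @return tibble of placements: `read_id`, `ref_id`, `strand`, `ref_start`
#'   (0-based), `ref_end`, `aligned_len`, `identity`, `score`, plus the
#'   oriented read and gapped alignment rows (`read_oriented`, `aln_read`,
#'   `aln_ref`, `read_pre`, `read_post`) consumed by [consensus_contigs()].
#'   Attributes `n_unplaced` and `n_ambiguous` count the reads left out.
#' @export
map_reads <- function(reads, index, min_identity = 0.80, min_anchor = 50,
                      n_seeds = 12, scores = sp_scores()) {
  stopifnot(inherits(index, "kmer_index"))
  k <- index$k
  n_reads <- nrow(reads)
  if (n_reads == 0) {
    out <- sp_empty_placements()
    attr(out, "n_unplaced") <- 0L; attr(out, "n_ambiguous") <- 0L
    return(out)
  }
  # seed voting: candidate (ref, strand) per read
  cand <- vector("list", n_reads)
  for (r in seq_len(n_reads)) {
    s <- reads$seq[r]
    L <- nchar(s)
    if (L < k) next
    offs <- unique(round(seq(0, L - k, length.out = min(n_seeds, L - k + 1))))
    hits <- lapply(offs, function(o) {
      km <- substr(s, o + 1, o + k)
      idx <- get0(km, envir = index$env, ifnotfound = integer(0))
      if (length(idx) == 0) return(NULL)
      data.frame(ref_i = index$ref_i[idx], strand = index$strand[idx])
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits) || nrow(hits) == 0) next
    key <- paste(hits$ref_i, hits$strand)
    votes <- sort(table(key), decreasing = TRUE)
    top <- names(votes)[seq_len(min(2, length(votes)))]
    cand[[r]] <- top
  }
  has_cand <- which(lengths(cand) > 0)
  # group (read, candidate) tasks by candidate for vectorized alignment
  tasks <- data.frame(
    read = rep(has_cand, lengths(cand[has_cand])),
    key = unlist(cand[has_cand]), stringsAsFactors = FALSE)
  results <- vector("list", nrow(tasks))
  if (nrow(tasks) > 0) {
    for (key in unique(tasks$key)) {
      rows <- which(tasks$key == key)
      parts <- strsplit(key, " ", fixed = TRUE)[[1]]
      ref_i <- as.integer(parts[1]); strand <- parts[2]
      ref_seq <- index$refs$seq[ref_i]
      rseqs <- reads$seq[tasks$read[rows]]
      if (strand == "-") rseqs <- revcomp(rseqs)
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(rseqs), Biostrings::DNAString(ref_seq),
        type = "local", substitutionMatrix = sp_submat(scores),
        gapOpening = scores$gap_open, gapExtension = scores$gap_extend)
      pat <- Biostrings::pattern(aln); sub <- Biostrings::subject(aln)
      aln_read <- as.character(pat); aln_ref <- as.character(sub)
      ncols <- nchar(aln_read)
      p_start <- Biostrings::start(pat); p_end <- Biostrings::end(pat)
      for (t in seq_along(rows)) {
        results[[rows[t]]] <- list(
          read = tasks$read[rows[t]], ref_i = ref_i, strand = strand,
          score = Biostrings::score(aln)[t],
          identity = Biostrings::nmatch(aln)[t] / max(ncols[t], 1),
          aligned_len = ncols[t],
          ref_start = Biostrings::start(sub)[t] - 1L,
          ref_end = Biostrings::end(sub)[t],
          aln_read = aln_read[t], aln_ref = aln_ref[t],
          read_oriented = rseqs[t],
          read_pre = substr(rseqs[t], 1L, p_start[t] - 1L),
          read_post = substr(rseqs[t], p_end[t] + 1L, nchar(rseqs[t])))
      }
    }
  }
  # best placement per read; equal-best ties dropped
  placed <- list(); n_ambiguous <- 0L
  by_read <- split(results, vapply(results, function(x) x$read, numeric(1)))
  for (grp in by_read) {
    sc <- vapply(grp, function(x) x$score, numeric(1))
    best <- which(sc == max(sc))
    if (length(best) > 1) { n_ambiguous <- n_ambiguous + 1L; next }
    b <- grp[[best]]
    if (b$identity >= min_identity && b$aligned_len >= min_anchor) {
      placed[[length(placed) + 1]] <- b
    }
  }
  out <- if (length(placed)) {
    tibble(read_id = reads$id[vapply(placed, function(x) x$read, numeric(1))],
           ref_id = index$refs$id[vapply(placed, function(x) x$ref_i, numeric(1))],
           strand = vapply(placed, function(x) x$strand, character(1)),
           ref_start = vapply(placed, function(x) x$ref_start, numeric(1)),
           ref_end = vapply(placed, function(x) x$ref_end, numeric(1)),
           aligned_len = vapply(placed, function(x) x$aligned_len, numeric(1)),
           identity = vapply(placed, function(x) x$identity, numeric(1)),
           score = vapply(placed, function(x) x$score, numeric(1)),
           read_oriented = vapply(placed, function(x) x$read_oriented, character(1)),
           aln_read = vapply(placed, function(x) x$aln_read, character(1)),
           aln_ref = vapply(placed, function(x) x$aln_ref, character(1)),
           read_pre = vapply(placed, function(x) x$read_pre, character(1)),
           read_post = vapply(placed, function(x) x$read_post, character(1)))
  } else sp_empty_placements()
  attr(out, "n_unplaced") <- n_reads - nrow(out) - n_ambiguous
  attr(out, "n_ambiguous") <- n_ambiguous
  out
}

sp_empty_placements <- function() {
  tibble(read_id = character(), ref_id = character(), strand = character(),
         ref_start = numeric(), ref_end = numeric(), aligned_len = numeric(),
         identity = numeric(), score = numeric(), read_oriented = character(),
         aln_read = character(), aln_ref = character(),
         read_pre = character(), read_post = character())
}

#' Majority-vote consensus contigs from read placements
#'
#' Builds a pileup on reference coordinates (optionally extended by
#' `flank_bp` on both sides so overhanging read ends can assemble flanking
#' sequence), calls the majority base per position with ties broken toward
#' the reference base, and emits maximal runs of positions with depth >=
#' `min_depth` as contigs. Positions where a deletion wins the vote are
#' dropped from the contig sequence. Read bases outside the local alignment
#' (soft-clipped tails) are laid down ungapped beyond the alignment
#' boundaries so flanking regions accumulate support.
#'
#' @param placements tibble from [map_reads()], restricted to one reference.
#' @param reference single-row tibble `id`, `seq` (the mapping reference).
#' @param min_depth minimum read depth inside a contig (default 2).
#' @param flank_bp how far beyond the reference ends the pileup extends.
#' @return tibble of contigs: `locus_id`, `seq`, `ref_start`, `ref_end`
#'   (0-based half-open, clipped to the reference), `mean_depth`.
#' @export
consensus_contigs <- function(placements, reference, min_depth = 2, flank_bp = 200) {
  stopifnot(nrow(reference) == 1)
  L <- nchar(reference$seq)
  W <- L + 2L * flank_bp                 # window coords 1..W = ref coords -flank..L+flank-1
  if (nrow(placements) > 0 && !all(placements$ref_id == reference$id)) {
    abort("placements must all be on the given reference")
  }
  if (nrow(placements) == 0) {
    return(tibble(locus_id = character(), seq = character(),
                  ref_start = numeric(), ref_end = numeric(),
                  mean_depth = numeric()))
  }
  bases <- c("A", "C", "G", "T", "-")
  # votes collected as linear indices into a 5 x W count matrix, tallied once
  vote_idx <- function(chars, refpos0) {
    wcol <- refpos0 + flank_bp + 1L
    b <- match(chars, bases)
    ok <- wcol >= 1L & wcol <= W & !is.na(b)
    (wcol[ok] - 1L) * 5L + b[ok]
  }
  votes <- vector("list", 3L * nrow(placements))
  for (p in seq_len(nrow(placements))) {
    ar <- strsplit(placements$aln_read[p], "", fixed = TRUE)[[1]]
    as_ <- strsplit(placements$aln_ref[p], "", fixed = TRUE)[[1]]
    consumes_ref <- as_ != "-"
    refpos <- placements$ref_start[p] + cumsum(consumes_ref) - 1L
    # aligned block: one vote per reference-consuming column (read base or '-')
    votes[[3L * p - 2L]] <- vote_idx(ar[consumes_ref], refpos[consumes_ref])
    # soft-clipped tails laid down ungapped beyond the aligned block
    pre <- placements$read_pre[p]
    if (nzchar(pre)) {
      pc <- strsplit(pre, "", fixed = TRUE)[[1]]
      votes[[3L * p - 1L]] <- vote_idx(pc, placements$ref_start[p] - rev(seq_along(pc)))
    }
    post <- placements$read_post[p]
    if (nzchar(post)) {
      pc <- strsplit(post, "", fixed = TRUE)[[1]]
      votes[[3L * p]] <- vote_idx(pc, placements$ref_end[p] + seq_along(pc) - 1L)
    }
  }
  counts <- matrix(tabulate(unlist(votes, use.names = FALSE), nbins = 5L * W),
                   nrow = 5, ncol = W, dimnames = list(bases, NULL))
  depth <- colSums(counts)
  ref_chars <- strsplit(reference$seq, "", fixed = TRUE)[[1]]
  # consensus call per window position
  call_base <- function(w) {
    v <- counts[, w]
    m <- max(v)
    top <- bases[v == m]
    if (length(top) == 1) return(top)
    refpos0 <- w - flank_bp - 1L
    if (refpos0 >= 0 && refpos0 < L && ref_chars[refpos0 + 1] %in% top) {
      return(ref_chars[refpos0 + 1])
    }
    sort(top)[1]
  }
  covered <- depth >= min_depth
  if (!any(covered)) {
    return(tibble(locus_id = character(), seq = character(),
                  ref_start = numeric(), ref_end = numeric(),
                  mean_depth = numeric()))
  }
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (i in which(runs$values)) {
    w0 <- starts[i]; w1 <- ends[i]
    cons <- vapply(w0:w1, call_base, character(1))
    seq_out <- paste(cons[cons != "-"], collapse = "")
    if (!nzchar(seq_out)) next
    rs <- max(0L, w0 - flank_bp - 1L)          # clip to reference
    re <- min(L, w1 - flank_bp)
    out[[length(out) + 1]] <- tibble(
      locus_id = reference$id, seq = seq_out,
      ref_start = rs, ref_end = max(re, rs),
      mean_depth = mean(depth[w0:w1]))
  }
  bind_rows(out)
}

#' Select 1-4 probe-design templates per locus
#'
#' Given the star alignment of a locus's reference (transcriptome or
#' universal sequence) and its genome-skim contigs, templates are chosen by
#' greedy single-linkage clustering of alignment rows at `ident_threshold`
#' gapped identity, visiting rows in descending ungapped length. One template
#' is emitted per cluster (its longest ungapped member), capped at
#' `max_templates` (smallest-representative clusters dropped, recorded in the
#' `dropped` attribute). Special cases: a `markerminer` locus with no contigs
#' is omitted entirely (empty result); if every contig is shorter than
#' `min_contig`, the reference is the sole template. A cluster represented by
#' a partial contig (covering less than `hybrid_cov` of the reference) is
#' completed into a full-length hybrid with [hybrid_join()].
#'
#' @param aln `star_alignment` of the locus (reference plus contig rows).
#' @param meta tibble `id`, `source_class` for every row of `aln`
#'   (`source_class` of the reference row typically `"transcriptome"` or
#'   `"universal"`; contigs `"skim_<clade>"`).
#' @param locus_id locus identifier stamped on the templates.
#' @param source_method the locus's Tier-1 source method (the
#'   `"markerminer"` no-contig omission rule keys on this).
#' @param ident_threshold percent identity above which rows share a cluster.
#' @param min_contig minimum contig length (bp) to count as usable; strict
#'   (`< min_contig` triggers the reference fallback).
#' @param max_templates cap on templates per locus.
#' @param hybrid_cov reference-coverage fraction below which a contig
#'   representative is hybrid-joined onto the reference backbone.
#' @return tibble of templates: `template_id`, `locus_id`, `source_class`,
#'   `seq`, `aligned_row`, `provenance` (list-column of segment origins);
#'   zero rows only for the markerminer-no-contig case.
#' @export
select_templates <- function(aln, meta, locus_id, source_method,
                             ident_threshold = 90, min_contig = 300,
                             max_templates = 4, hybrid_cov = 0.90) {
  stopifnot(inherits(aln, "star_alignment"))
  ref_id <- aln$ref_id
  if (!ref_id %in% names(aln$rows)) abort("reference row missing from alignment")
  if (!all(names(aln$rows) %in% meta$id)) abort("meta must cover every alignment row")
  ref_row <- aln$rows[[ref_id]]
  ref_seq <- gsub("-", "", ref_row, fixed = TRUE)
  ref_class <- meta$source_class[meta$id == ref_id]
  contig_ids <- setdiff(names(aln$rows), ref_id)
  template_of <- function(seq, class, prov, n, aligned_row = NA_character_) {
    tibble(template_id = sprintf("%s__t%d__%s", locus_id, n, class),
           locus_id = locus_id, source_class = class, seq = seq,
           aligned_row = aligned_row, provenance = list(prov))
  }
  ref_prov <- tibble(start = 0L, end = nchar(ref_seq), origin = ref_id)

  if (length(contig_ids) == 0) {
    if (identical(source_method, "markerminer")) {
      out <- tibble(template_id = character(), locus_id = character(),
                    source_class = character(), seq = character(),
                    aligned_row = character(), provenance = list())
      attr(out, "omitted") <- "markerminer locus with no genome-skim contigs"
      return(out)
    }
    return(template_of(ref_seq, ref_class, ref_prov, 1L))
  }

  ungapped <- vapply(aln$rows, function(r) gsub("-", "", r, fixed = TRUE), character(1))
  contig_len <- nchar(ungapped[contig_ids])
  usable <- contig_ids[contig_len >= min_contig]
  if (length(usable) == 0) {
    out <- template_of(ref_seq, ref_class, ref_prov, 1L, ref_row)
    attr(out, "note") <- "all contigs below min_contig; reference is sole template"
    return(out)
  }

  # greedy single-linkage at ident_threshold, rows visited longest-first
  row_ids <- c(ref_id, usable)
  row_ids <- row_ids[order(-nchar(ungapped[row_ids]))]
  clusters <- list()
  for (id in row_ids) {
    joined <- FALSE
    for (ci in seq_along(clusters)) {
      pid <- vapply(clusters[[ci]], function(m)
        percent_identity_gapped(aln$rows[[id]], aln$rows[[m]]), numeric(1))
      if (any(pid >= ident_threshold)) {
        clusters[[ci]] <- c(clusters[[ci]], id)
        joined <- TRUE
        break
      }
    }
    if (!joined) clusters[[length(clusters) + 1]] <- id
  }

  rep_id <- vapply(clusters, function(m) m[which.max(nchar(ungapped[m]))][1],
                   character(1))
  rep_len <- nchar(ungapped[rep_id])
  ord <- order(-rep_len)
  dropped <- character(0)
  if (length(ord) > max_templates) {
    dropped <- rep_id[ord[(max_templates + 1):length(ord)]]
    inform(sprintf("%s: template cap %d reached; dropping cluster representative(s): %s",
                   locus_id, max_templates, paste(dropped, collapse = ", ")))
    ord <- ord[seq_len(max_templates)]
  }

  out <- list()
  for (n in seq_along(ord)) {
    rid <- rep_id[ord[n]]
    if (rid == ref_id) {
      out[[n]] <- template_of(ref_seq, ref_class, ref_prov, n, ref_row)
      next
    }
    cls <- meta$source_class[meta$id == rid]
    iv <- aln$ref_intervals[aln$ref_intervals$id == rid, ]
    covered <- (iv$ref_end - iv$ref_start) / nchar(ref_seq)
    if (!is.na(covered) && covered < hybrid_cov) {
      hj <- hybrid_join(ungapped[[rid]], iv$ref_start, iv$ref_end, ref_seq,
                        contig_origin = rid, backbone_origin = ref_id)
      out[[n]] <- template_of(hj$seq, "hybrid", hj$provenance, n)
    } else {
      out[[n]] <- template_of(ungapped[[rid]], cls,
                              tibble(start = 0L, end = nchar(ungapped[[rid]]),
                                     origin = rid), n, aln$rows[[rid]])
    }
  }
  out <- bind_rows(out)
  attr(out, "dropped") <- dropped
  out
}

#' Splice a partial contig onto a full-length backbone
#'
#' The contig replaces the backbone over its reference interval; the backbone
#' supplies the remainder, producing a full-length hybrid template. Segment
#' provenance records which origin contributed each piece.
#'
#' @param contig_seq ungapped contig sequence.
#' @param ref_start,ref_end contig interval on the backbone (0-based
#'   half-open).
#' @param backbone ungapped backbone sequence.
#' @param contig_origin,backbone_origin ids recorded in provenance.
#' @return list with `seq` (the hybrid) and `provenance` (tibble `start`,
#'   `end`, `origin` in hybrid coordinates).
#' @export
hybrid_join <- function(contig_seq, ref_start, ref_end, backbone,
                        contig_origin = "contig", backbone_origin = "backbone") {
  Lb <- nchar(backbone)
  sp_check_interval(ref_start, ref_end, Lb, what = "contig interval on backbone")
  pre <- substr(backbone, 1, ref_start)
  post <- substr(backbone, ref_end + 1, Lb)
  seq <- paste0(pre, contig_seq, post)
  prov <- tibble(
    start = c(if (nzchar(pre)) 0L else NULL,
              nchar(pre),
              if (nzchar(post)) nchar(pre) + nchar(contig_seq) else NULL),
    end = c(if (nzchar(pre)) nchar(pre) else NULL,
            nchar(pre) + nchar(contig_seq),
            if (nzchar(post)) nchar(seq) else NULL),
    origin = c(if (nzchar(pre)) backbone_origin else NULL,
               contig_origin,
               if (nzchar(post)) backbone_origin else NULL))
  stopifnot(nchar(seq) == Lb - (ref_end - ref_start) + nchar(contig_seq))
  list(seq = seq, provenance = prov)
}

#' Screen templates against organellar references
#'
#' A template is flagged iff it has a local alignment (either strand) to the
#' plastid or mitochondrial reference with identity >= `min_ident` percent
#' over at least `min_len` aligned columns. Flagged templates are removed
#' from the design set and reported. With neither reference supplied the
#' screen is skipped with a prominent warning.
#'
#' @param templates template tibble (needs `template_id`, `seq`).
#' @param plastid,mito single reference sequences (character) or `NULL`.
#' @param min_ident percent-identity threshold.
#' @param min_len minimum aligned length (bp).
#' @param scores scoring scheme.
#' @return list with `kept` (templates passing) and `flagged` (tibble
#'   `template_id`, `organelle`, `identity_pct`, `aln_len`).
#' @export
organelle_screen <- function(templates, plastid = NULL, mito = NULL,
                             min_ident = 90, min_len = 60, scores = sp_scores()) {
  refs <- list(plastid = plastid, mito = mito)
  refs <- refs[!vapply(refs, is.null, logical(1))]
  if (length(refs) == 0) {
    warn("organelle_screen: no organellar reference supplied; screen SKIPPED")
    return(list(kept = templates,
                flagged = tibble(template_id = character(), organelle = character(),
                                 identity_pct = numeric(), aln_len = numeric())))
  }
  flagged <- list()
  for (org in names(refs)) {
    if (nrow(templates) == 0) break
    la <- local_align(templates$seq, refs[[org]], scores = scores,
                      both_strands = TRUE)
    hit <- la$identity_pct >= min_ident & la$aln_len >= min_len
    if (any(hit)) {
      flagged[[org]] <- tibble(template_id = templates$template_id[hit],
                               organelle = org,
                               identity_pct = la$identity_pct[hit],
                               aln_len = la$aln_len[hit])
    }
  }
  flagged <- if (length(flagged)) bind_rows(flagged) else
    tibble(template_id = character(), organelle = character(),
           identity_pct = numeric(), aln_len = numeric())
  list(kept = templates[!templates$template_id %in% flagged$template_id, , drop = FALSE],
       flagged = flagged)
}
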