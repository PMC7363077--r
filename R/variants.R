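# Per-site allele counts from aligned consensus reads and variant calling.
#
# Alignments are kept in "unwrapped" coordinates: start in [1, L], end may
# exceed L for fragments spanning the origin; pileup wraps positions onto the
# circular genome, which removes the linearisation edge bias by construction.
# A two-window relinearised mode is available for externally mapped SAM input.

#' Place trimmed consensus reads on the reference using the simulator sidecar
#'
#' Converts consensus mates into aligned records using the true template
#' coordinates recorded by [emit_read_families()]: mate 1 covers the fragment
#' start (head-trimmed), mate 2 covers the fragment end and is stored
#' reverse-complemented into reference orientation.
#'
#' Mate 1 of the lexicographically keyed `ab` family is the fragment-left
#' read only when that family came from the top template strand; the
#' sidecar's `tag_top` column disambiguates, and mates are swapped where
#' needed (the role an aligner's reported positions play for real data).
#'
#' @param consensus Trimmed consensus `data.frame` (see [call_consensus()]
#'   and [trim_head()]).
#' @param sidecar Sidecar `data.frame` from [emit_read_families()].
#' @param read_chunk Fragment bases carried per untrimmed read (read length
#'   minus tag and spacer).
#' @param trimmed Head bases removed from each consensus mate.
#' @return Alignment `data.frame`: `template_id`, `sample_id`, `level`,
#'   `orientation`, `mate`, `start` (unwrapped), `seq` (reference
#'   orientation), `mapq`, `paired`, `proper_pair`.
#' @export
align_consensus <- function(consensus, sidecar, read_chunk, trimmed = 12L) {
  idx <- match(consensus$duplex_key, sidecar$duplex_key)
  keep <- !is.na(idx)
  consensus <- consensus[keep, , drop = FALSE]
  idx <- idx[keep]
  start <- sidecar$start[idx]
  frag_len <- sidecar$frag_len[idx]
  ab_is_top <- sidecar$tag_top[idx] == consensus$duplex_key
  flip <- xor(!ab_is_top, consensus$orientation == "ba")
  eff_mate <- ifelse(flip, 3L - consensus$mate, consensus$mate)
  m1 <- eff_mate == 1L
  out_start <- integer(nrow(consensus))
  out_seq <- character(nrow(consensus))
  out_start[m1] <- start[m1] + trimmed
  out_seq[m1] <- consensus$seq[m1]
  out_start[!m1] <- start[!m1] + frag_len[!m1] - read_chunk
  out_seq[!m1] <- revcomp(consensus$seq[!m1])
  data.frame(template_id = sidecar$template_id[idx],
             sample_id = sidecar$sample_id[idx],
             level = consensus$level, orientation = consensus$orientation,
             mate = consensus$mate, start = out_start, seq = out_seq,
             mapq = 60L, paired = TRUE, proper_pair = TRUE,
             stringsAsFactors = FALSE)
}

#' Clip mate overlaps so each template position is counted once
#'
#' Within each (template, level, orientation) mate pair, any reference
#' interval covered by both mates is removed from mate 2, so that one
#' template molecule contributes exactly one observation per position.
#'
#' @param alignments Alignment `data.frame` (see [align_consensus()]).
#' @return Alignment `data.frame` with mate-2 records clipped (empty records
#'   dropped).
#' @export
clip_overlaps <- function(alignments) {
  if (nrow(alignments) == 0L) return(alignments)
  key <- paste(alignments$template_id, alignments$level,
               alignments$orientation, sep = "\r")
  drop <- logical(nrow(alignments))
  for (idx in split(seq_len(nrow(alignments)), key)) {
    if (length(idx) != 2L) next
    # clip the later-starting mate, whichever mate number it carries
    ord <- idx[order(alignments$start[idx])]
    left <- ord[1]; right <- ord[2]
    e1 <- alignments$start[left] + nchar(alignments$seq[left]) - 1L
    s2 <- alignments$start[right]
    e2 <- s2 + nchar(alignments$seq[right]) - 1L
    if (s2 > e1) next                         # disjoint
    if (e2 <= e1) { drop[right] <- TRUE; next }  # fully contained
    cut <- e1 - s2 + 1L
    alignments$seq[right] <- substr(alignments$seq[right], cut + 1L,
                                    nchar(alignments$seq[right]))
    alignments$start[right] <- e1 + 1L
  }
  alignments[!drop, , drop = FALSE]
}

#' Filter alignment records
#'
#' Keeps records with mapping quality strictly above `min_mapq`, flagged as
#' paired and (optionally) properly paired.  Removal counts per reason are
#' attached as the `"removed"` attribute.
#'
#' @param alignments Alignment `data.frame`.
#' @param min_mapq Strict lower bound on mapping quality (default 20; a
#'   record at exactly 20 is removed).
#' @param require_proper_pair Require the proper-pair flag (default TRUE).
#' @return Filtered alignment `data.frame`.
#' @export
filter_alignments <- function(alignments, min_mapq = 20L,
                              require_proper_pair = TRUE) {
  low_mapq <- alignments$mapq <= min_mapq
  unpaired <- !alignments$paired
  improper <- if (require_proper_pair) !alignments$proper_pair
              else rep(FALSE, nrow(alignments))
  keep <- !(low_mapq | unpaired | improper)
  out <- alignments[keep, , drop = FALSE]
  attr(out, "removed") <- c(low_mapq = sum(low_mapq),
                            unpaired = sum(unpaired & !low_mapq),
                            improper = sum(improper & !low_mapq & !unpaired))
  out
}

#' Per-site allele counts from aligned consensus reads
#'
#' Counts base observations per circular genome position, separately at DCS
#' and SSCS level.  `N` bases and bases below the base-quality cutoff are
#' excluded; depth at a site is the number of counted (non-N) observations.
#'
#' @param alignments Alignment `data.frame` (optionally with `qual` strings;
#'   absent qualities are treated as passing).
#' @param genome An [mt_genome].
#' @param min_base_quality Phred cutoff applied when `qual` is present
#'   (default 20; a base at quality 19 is excluded).
#' @return `data.frame` with one row per covered position: `pos`, `ref`,
#'   per-base counts `dcs_A` ... `dcs_T`, `sscs_A` ... `sscs_T`, and depths
#'   `dcs_depth`, `sscs_depth`.
#' @export
pileup <- function(alignments, genome, min_base_quality = 20L) {
  L <- genome$length
  counts <- list(
    DCS = matrix(0L, nrow = L, ncol = 4L,
                 dimnames = list(NULL, c("A", "C", "G", "T"))),
    SSCS = matrix(0L, nrow = L, ncol = 4L,
                  dimnames = list(NULL, c("A", "C", "G", "T"))))
  has_qual <- "qual" %in% names(alignments)
  for (i in seq_len(nrow(alignments))) {
    lvl <- alignments$level[i]
    if (!lvl %in% names(counts)) next
    ch <- strsplit(alignments$seq[i], "")[[1]]
    pos <- wrap_pos(alignments$start[i] + seq_along(ch) - 1L, L)
    ok <- ch %in% c("A", "C", "G", "T")
    if (has_qual && !is.na(alignments$qual[i])) {
      q <- utf8ToInt(alignments$qual[i]) - 33L
      ok <- ok & q >= min_base_quality
    }
    for (b in c("A", "C", "G", "T")) {
      p <- pos[ok & ch == b]
      if (length(p)) {
        tab <- tabulate(p, nbins = L)
        counts[[lvl]][, b] <- counts[[lvl]][, b] + tab
      }
    }
  }
  dcs_depth <- rowSums(counts$DCS)
  sscs_depth <- rowSums(counts$SSCS)
  covered <- which(dcs_depth + sscs_depth > 0)
  if (!length(covered))
    return(data.frame(pos = integer(), ref = character(),
                      dcs_A = integer(), dcs_C = integer(),
                      dcs_G = integer(), dcs_T = integer(),
                      sscs_A = integer(), sscs_C = integer(),
                      sscs_G = integer(), sscs_T = integer(),
                      dcs_depth = numeric(), sscs_depth = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(pos = covered,
             ref = genome_base(genome, covered),
             dcs_A = counts$DCS[covered, "A"], dcs_C = counts$DCS[covered, "C"],
             dcs_G = counts$DCS[covered, "G"], dcs_T = counts$DCS[covered, "T"],
             sscs_A = counts$SSCS[covered, "A"],
             sscs_C = counts$SSCS[covered, "C"],
             sscs_G = counts$SSCS[covered, "G"],
             sscs_T = counts$SSCS[covered, "T"],
             dcs_depth = dcs_depth[covered], sscs_depth = sscs_depth[covered],
             stringsAsFactors = FALSE)
}

#' Call nucleotide substitutions from site counts
#'
#' Every non-reference base with at least `min_reads` supporting DCS
#' observations becomes a call (single-molecule variants are retained).  The
#' reported allele frequency is the DCS fraction, replaced by the SSCS
#' fraction whenever the DCS minor-allele depth is below 5 (low-depth MAFs
#' are better measured at SSCS level, where molecule counts are about 3-fold
#' higher).
#'
#' @param site_counts `data.frame` from [pileup()], or any table with the
#'   same columns.
#' @param sample_id Sample identifier attached to the calls.
#' @param min_reads Minimum DCS support (default 1).
#' @param sscs_min_dcs_depth DCS minor-allele depth below which the SSCS MAF
#'   is substituted (default 5, strict `<`).
#' @return Variant `data.frame`: `sample_id`, `pos`, `ref`, `alt`,
#'   `dcs_count`, `dcs_depth`, `sscs_count`, `sscs_depth`, `maf`,
#'   `maf_source`.
#' @export
call_variants <- function(site_counts, sample_id = "sample",
                          min_reads = 1L, sscs_min_dcs_depth = 5L) {
  rows <- list()
  for (b in c("A", "C", "G", "T")) {
    sel <- site_counts$ref != b & site_counts[[paste0("dcs_", b)]] >= min_reads
    if (!any(sel)) next
    sc <- site_counts[sel, , drop = FALSE]
    dcs <- sc[[paste0("dcs_", b)]]
    sscs <- sc[[paste0("sscs_", b)]]
    rows[[b]] <- data.frame(
      sample_id = sample_id, pos = sc$pos, ref = sc$ref, alt = b,
      dcs_count = dcs, dcs_depth = sc$dcs_depth,
      sscs_count = sscs, sscs_depth = sc$sscs_depth,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(sample_id = character(), pos = integer(),
                      ref = character(), alt = character(),
                      dcs_count = integer(), dcs_depth = integer(),
                      sscs_count = integer(), sscs_depth = integer(),
                      maf = numeric(), maf_source = character(),
                      stringsAsFactors = FALSE))
  calls <- do.call(rbind, rows)
  calls <- calls[order(calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  src <- select_maf_source(calls$dcs_count, calls$dcs_count / calls$dcs_depth,
                           ifelse(calls$sscs_depth > 0,
                                  calls$sscs_count / calls$sscs_depth, NA),
                           min_dcs_depth = sscs_min_dcs_depth)
  calls$maf <- src$maf
  calls$maf_source <- src$source
  calls
}

#' Choose between DCS- and SSCS-level allele frequency
#'
#' DCS frequencies are used when the DCS minor-allele depth is at least
#' `min_dcs_depth`; below that (strict `<`), the SSCS frequency is used when
#' available.
#'
#' @param dcs_minor_depth DCS read count of the minor allele (vectorised).
#' @param dcs_maf,sscs_maf Allele frequencies at the two levels
#'   (`sscs_maf = NA` when unmeasured).
#' @param min_dcs_depth Threshold (default 5).
#' @return List with `maf` and `source` (`"DCS"`/`"SSCS"`).
#' @export
select_maf_source <- function(dcs_minor_depth, dcs_maf, sscs_maf,
                              min_dcs_depth = 5L) {
  use_sscs <- dcs_minor_depth < min_dcs_depth & !is.na(sscs_maf)
  list(maf = ifelse(use_sscs, sscs_maf, dcs_maf),
       source = ifelse(use_sscs, "SSCS", "DCS"))
}

#' Convert alt-allele fractions to the minor-allele convention
#'
#' @param af Alt-allele fractions in `[0, 1]`.
#' @return `pmin(af, 1 - af)`.
#' @export
as_minor_af <- function(af) pmin(af, 1 - af)

#' Read aligned consensus records from a SAM/BAM file
#'
#' Optional input path for externally aligned consensus reads; requires the
#' `Rsamtools` package.  Only records with ungapped (single-`M`) CIGARs are
#' used (substitution-only scope; indel realignment is a no-op here).
#'
#' @param path SAM or BAM file.
#' @param level Consensus level tag for the records (`"DCS"` or `"SSCS"`).
#' @return Alignment `data.frame` compatible with [pileup()].
#' @export
read_sam_alignments <- function(path, level = "DCS") {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("the SAM/BAM input path requires the Rsamtools package")
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  simple <- grepl("^[0-9]+M$", b$cigar) & !is.na(b$pos)
  flag <- b$flag[simple]
  data.frame(template_id = b$qname[simple],
             sample_id = NA_character_, level = level,
             orientation = ifelse(bitwAnd(flag, 16L) > 0L, "ba", "ab"),
             mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
             start = b$pos[simple], seq = as.character(b$seq[simple]),
             qual = as.character(b$qual[simple]),
             mapq = b$mapq[simple],
             paired = bitwAnd(flag, 1L) > 0L,
             proper_pair = bitwAnd(flag, 2L) > 0L,
             stringsAsFactors = FALSE)
}

#' Recompute edge-window counts against a relinearised reference
#'
#' Parity mode for externally mapped data: variants in the configured edge
#' windows of the circular genome are taken from a second alignment pass
#' against a relinearised reference, while the default circular pileup needs
#' no such correction.  Given two call tables, keeps calls from the circular
#' pass outside the windows and calls from the relinearised pass inside
#' them.
#'
#' @param calls_circular,calls_relinearised Variant tables from
#'   [call_variants()].
#' @param windows List of `c(start, end)` position windows taken from the
#'   relinearised pass.
#' @return Merged variant `data.frame`.
#' @export
merge_edge_windows <- function(calls_circular, calls_relinearised,
                               windows = list(c(1L, 500L), c(14800L, 15299L))) {
  in_win <- function(pos) Reduce(`|`, lapply(windows, function(w)
    pos >= w[1] & pos <= w[2]), rep(FALSE, length(pos)))
  rbind(calls_circular[!in_win(calls_circular$pos), , drop = FALSE],
        calls_relinearised[in_win(calls_relinearised$pos), , drop = FALSE])
}
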