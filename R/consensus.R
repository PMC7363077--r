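# Barcode-error-corrected duplex consensus calling: tag-family grouping,
# single-strand consensus (SSCS), duplex consensus (DCS), head trimming.
#
# Geometry convention (matching the simulator): each read is
# tag (tag_length) + invariant spacer (spacer_length) + fragment bases.
# The two strands of one duplex carry swapped tag pairs: the family tagged
# (a,b) and the family tagged (b,a) come from opposite strands of the same
# template, and mate 1 of one strand covers the same fragment end as mate 2
# of the other, so duplex comparison pairs mates crosswise with no further
# orientation transform.

#' Group read pairs into tag families with barcode error correction
#'
#' Extracts the 24-nt combined tag (both mates), tallies tag counts, and
#' greedily merges any tag within `max_mismatch` Hamming distance of a
#' higher-count tag into that tag (largest family wins; ties broken by
#' lexicographic order).  Reads shorter than tag + spacer are rejected and
#' counted.  Member reads are returned with tag and spacer stripped.
#'
#' @param pairs `data.frame` with columns `id`, `seq1`, `seq2` (and optional
#'   `qual1`, `qual2`, carried but unused in voting).
#' @param tag_length,spacer_length Tag geometry (defaults 12 and 5 nt).
#' @param max_mismatch Maximum Hamming distance merged during correction
#'   (default 3).
#' @return List with `families` (list of family records: `tag1`, `tag2`,
#'   `duplex_key`, `orientation` (`"ab"`/`"ba"`), `size`, and character
#'   vectors `seq1`, `seq2` of stripped member reads) and `rejected`
#'   (named counts of rejected records by reason).
#' @export
correct_tags <- function(pairs, tag_length = 12L, spacer_length = 5L,
                         max_mismatch = 3L) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  rejected <- c(too_short = 0L)
  if (nrow(pairs) == 0L) return(list(families = list(), rejected = rejected))
  head_len <- tag_length + spacer_length
  ok <- nchar(pairs$seq1) > head_len & nchar(pairs$seq2) > head_len
  rejected["too_short"] <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0L) return(list(families = list(), rejected = rejected))

  tag1 <- substr(pairs$seq1, 1L, tag_length)
  tag2 <- substr(pairs$seq2, 1L, tag_length)
  combined <- paste0(tag1, tag2)
  corrected <- correct_tag_set(combined, max_mismatch)

  frag1 <- substr(pairs$seq1, head_len + 1L, nchar(pairs$seq1))
  frag2 <- substr(pairs$seq2, head_len + 1L, nchar(pairs$seq2))
  fam_idx <- split(seq_len(nrow(pairs)), corrected)
  families <- lapply(names(fam_idx), function(tag) {
    idx <- fam_idx[[tag]]
    t1 <- substr(tag, 1L, tag_length)
    t2 <- substr(tag, tag_length + 1L, 2L * tag_length)
    ordered <- t1 <= t2
    list(tag1 = t1, tag2 = t2,
         duplex_key = if (ordered) paste0(t1, t2) else paste0(t2, t1),
         orientation = if (ordered) "ab" else "ba",
         size = length(idx), seq1 = frag1[idx], seq2 = frag2[idx])
  })
  list(families = families, rejected = rejected)
}

# Deterministic greedy merge of a vector of combined tags; returns the
# corrected tag for each input element.
correct_tag_set <- function(tags, max_mismatch) {
  counts <- table(tags)
  ord <- order(-as.integer(counts), names(counts))
  uniq <- names(counts)[ord]
  if (length(uniq) == 1L) return(tags)
  tag_mat <- do.call(rbind, strsplit(uniq, ""))
  canonical <- integer(0)  # indices into uniq
  target <- character(length(uniq))
  for (i in seq_along(uniq)) {
    if (length(canonical)) {
      d <- colSums(t(tag_mat[canonical, , drop = FALSE]) != tag_mat[i, ])
      hit <- which(d <= max_mismatch)
    } else hit <- integer(0)
    if (length(hit)) {
      # canonical tags are already sorted by count desc then lexicographic,
      # so the first hit is the largest (tie: lexicographically smallest)
      target[i] <- uniq[canonical[hit[1]]]
    } else {
      canonical <- c(canonical, i)
      target[i] <- uniq[i]
    }
  }
  unname(target[match(tags, uniq)])
}

#' Single-strand consensus of a set of equal-length reads
#'
#' Emits, per position, the base present in at least `threshold` of the
#' `length(seqs)` reads, and `N` where no base reaches the threshold.
#' Returns `NULL` when the family is smaller than `min_family`.  Families
#' with unequal member read lengths are rejected (error).
#'
#' @param seqs Character vector of member read sequences (one strand, one
#'   mate).
#' @param min_family Minimum family size for SSCS formation (default 3).
#' @param threshold Consensus fraction, compared with `>=` (default 0.7).
#' @return Consensus string over `A`,`C`,`G`,`T`,`N`, or `NULL`.
#' @export
build_sscs <- function(seqs, min_family = 3L, threshold = 0.7) {
  n <- length(seqs)
  if (n < min_family) return(NULL)
  if (length(unique(nchar(seqs))) != 1L)
    stop("family members have unequal read lengths")
  m <- do.call(rbind, strsplit(seqs, ""))
  cons <- rep("N", ncol(m))
  for (b in c("A", "C", "G", "T")) {
    frac <- colSums(m == b) / n
    cons[frac >= threshold] <- b
  }
  paste(cons, collapse = "")
}

#' Duplex consensus of two single-strand consensuses
#'
#' Per position, the base is emitted only where the two strand consensuses
#' agree and neither is `N`; any disagreement or `N` yields `N`.
#'
#' @param sscs_a,sscs_b Equal-length SSCS strings.
#' @return DCS string.
#' @export
dcs_consensus <- function(sscs_a, sscs_b) {
  if (nchar(sscs_a) != nchar(sscs_b)) stop("SSCS lengths differ")
  a <- strsplit(sscs_a, "")[[1]]
  b <- strsplit(sscs_b, "")[[1]]
  out <- ifelse(a == b & a != "N", a, "N")
  paste(out, collapse = "")
}

#' Call SSCS and DCS consensus reads for a set of tag families
#'
#' Builds per-mate SSCSs for every family of at least `min_family` members,
#' then pairs the two strand families of each duplex (tag pairs `ab` and
#' `ba`) and forms the DCS by crosswise mate comparison (mate 1 of `ab`
#' against mate 2 of `ba`, and vice versa).  A duplex with only one SSCS
#' yields no DCS.
#'
#' @param families Family list from [correct_tags()].
#' @inheritParams build_sscs
#' @return `data.frame` with one row per consensus mate: `duplex_key`,
#'   `level` (`"SSCS"`/`"DCS"`), `orientation` (`"ab"`, `"ba"` or `"duplex"`),
#'   `mate`, `seq`, `family_size` (for DCS, the two sizes joined `ab+ba`).
#' @export
call_consensus <- function(families, min_family = 3L, threshold = 0.7) {
  rows <- list()
  sscs_by_key <- list()
  for (fam in families) {
    s1 <- build_sscs(fam$seq1, min_family, threshold)
    if (is.null(s1)) next
    s2 <- build_sscs(fam$seq2, min_family, threshold)
    if (is.null(s2)) next
    key <- fam$duplex_key
    rec <- list(mate1 = s1, mate2 = s2, size = fam$size,
                orientation = fam$orientation)
    sscs_by_key[[key]] <- c(sscs_by_key[[key]], list(rec))
    rows[[length(rows) + 1L]] <- data.frame(
      duplex_key = key, level = "SSCS", orientation = fam$orientation,
      mate = c(1L, 2L), seq = c(s1, s2),
      family_size = as.character(fam$size), stringsAsFactors = FALSE)
  }
  for (key in names(sscs_by_key)) {
    recs <- sscs_by_key[[key]]
    ori <- vapply(recs, `[[`, "", "orientation")
    if (!all(c("ab", "ba") %in% ori)) next
    ab <- recs[[match("ab", ori)]]
    ba <- recs[[match("ba", ori)]]
    if (nchar(ab$mate1) != nchar(ba$mate2) ||
        nchar(ab$mate2) != nchar(ba$mate1)) next
    d1 <- dcs_consensus(ab$mate1, ba$mate2)
    d2 <- dcs_consensus(ab$mate2, ba$mate1)
    rows[[length(rows) + 1L]] <- data.frame(
      duplex_key = key, level = "DCS", orientation = "duplex",
      mate = c(1L, 2L), seq = c(d1, d2),
      family_size = paste0(ab$size, "+", ba$size), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(duplex_key = character(), level = character(),
                      orientation = character(), mate = integer(),
                      seq = character(), family_size = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Trim the head of consensus reads
#'
#' Removes the first `n` bases of every consensus mate (false positives are
#' enriched near fragment ends from end repair during library preparation).
#' Records not longer than `n` are dropped and counted.
#'
#' @param consensus Consensus `data.frame` from [call_consensus()].
#' @param n Number of leading bases to remove (default 12).
#' @return List with `consensus` (trimmed `data.frame`) and `dropped`
#'   (number of removed records).
#' @export
trim_head <- function(consensus, n = 12L) {
  keep <- nchar(consensus$seq) > n
  out <- consensus[keep, , drop = FALSE]
  out$seq <- substr(out$seq, n + 1L, nchar(out$seq))
  list(consensus = out, dropped = sum(!keep))
}

#' Summarise a family set
#'
#' @param families Family list from [correct_tags()].
#' @param consensus Optional consensus `data.frame` from [call_consensus()].
#' @return List with the family count, family-size histogram and SSCS/DCS
#'   yields.
#' @export
family_summary <- function(families, consensus = NULL) {
  sizes <- vapply(families, `[[`, 0L, "size")
  out <- list(n_families = length(families),
              size_histogram = table(sizes))
  if (!is.null(consensus)) {
    out$n_sscs <- sum(consensus$level == "SSCS" & consensus$mate == 1L)
    out$n_dcs <- sum(consensus$level == "DCS" & consensus$mate == 1L)
  }
  out
}
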