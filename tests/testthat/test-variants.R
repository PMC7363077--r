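# Pileup, overlap clipping, alignment filtering and variant calling.

aln_row <- function(template = "t1", level = "DCS", mate = 1L, start = 1L,
                    seq = "ACGT", mapq = 60L, paired = TRUE, proper = TRUE,
                    qual = NA_character_) {
  data.frame(template_id = template, sample_id = "s", level = level,
             orientation = "duplex", mate = mate, start = start, seq = seq,
             qual = qual, mapq = mapq, paired = paired, proper_pair = proper,
             stringsAsFactors = FALSE)
}

test_that("mate overlaps are counted exactly once", {
  g <- toy_genome()
  a <- rbind(aln_row(mate = 1L, start = 100L, seq = random_seq(201)),
             aln_row(mate = 2L, start = 250L, seq = random_seq(201)))
  clipped <- clip_overlaps(a)
  counts <- pileup(clipped, g)
  covered <- counts$pos[counts$dcs_depth > 0]
  expect_setequal(covered, 100:450)
  expect_true(all(counts$dcs_depth[counts$pos %in% 100:450] == 1))
  # disjoint mates unchanged
  b <- rbind(aln_row(mate = 1L, start = 1L, seq = random_seq(50)),
             aln_row(mate = 2L, start = 100L, seq = random_seq(50)))
  expect_identical(clip_overlaps(b)$seq, b$seq)
  # identical mates: one retained
  s <- random_seq(80)
  d <- rbind(aln_row(mate = 1L, start = 10L, seq = s),
             aln_row(mate = 2L, start = 10L, seq = s))
  expect_equal(nrow(clip_overlaps(d)), 1L)
})

test_that("alignment filters apply the strict mapping-quality rule", {
  a <- rbind(aln_row(mapq = 20L), aln_row(mapq = 60L),
             aln_row(paired = FALSE), aln_row(proper = FALSE))
  out <- filter_alignments(a)
  expect_equal(nrow(out), 1L)
  expect_equal(out$mapq, 60L)
  rm <- attr(out, "removed")
  expect_equal(unname(rm["low_mapq"]), 1L)
  expect_equal(unname(rm["unpaired"]), 1L)
  expect_equal(unname(rm["improper"]), 1L)
})

test_that("pileup counts bases, excludes N and low qualities, wraps the origin", {
  g <- toy_genome()
  ref3 <- substr(g$sequence, 10, 12)
  alt <- chartr("ACGT", "GTAC", substr(ref3, 2, 2))
  seqs <- c(ref3, ref3, paste0(substr(ref3, 1, 1), alt, substr(ref3, 3, 3)))
  a <- do.call(rbind, lapply(seqs, function(s)
    aln_row(template = paste0("t", s), start = 10L, seq = s)))
  counts <- pileup(a, g)
  at11 <- counts[counts$pos == 11L, ]
  expect_equal(at11$dcs_depth, 3)
  expect_equal(at11[[paste0("dcs_", alt)]], 1)
  expect_equal(at11[[paste0("dcs_", substr(ref3, 2, 2))]], 2)
  # N bases do not contribute to depth
  aN <- aln_row(start = 10L, seq = "NNN")
  cN <- pileup(aN, g)
  expect_equal(nrow(cN), 0L)
  # base quality below the cutoff is excluded ('3' is Phred 18, 'I' is 40)
  aq <- aln_row(start = 10L, seq = ref3, qual = "I3I")
  cq <- pileup(aq, g)
  expect_equal(cq$dcs_depth[cq$pos == 11L], numeric(0))
  expect_equal(cq$dcs_depth[cq$pos == 10L], 1)
  # circular wrap: an alignment past the end covers position 1
  aw <- aln_row(start = g$length, seq = substr(paste0(g$sequence, g$sequence),
                                               g$length, g$length + 1L))
  cw <- pileup(aw, g)
  expect_setequal(cw$pos, c(1L, g$length))
})

test_that("variant calls keep single molecules and switch MAF source below depth 5", {
  counts <- data.frame(pos = c(5L, 6L, 7L), ref = c("A", "A", "A"),
                       dcs_A = c(99L, 996L, 50L), dcs_C = c(1L, 4L, 0L),
                       dcs_G = 0L, dcs_T = 0L,
                       sscs_A = c(297L, 987L, 150L), sscs_C = c(3L, 13L, 0L),
                       sscs_G = 0L, sscs_T = 0L,
                       dcs_depth = c(100L, 1000L, 50L),
                       sscs_depth = c(300L, 1000L, 150L),
                       stringsAsFactors = FALSE)
  calls <- call_variants(counts)
  expect_equal(nrow(calls), 2L)   # all-reference site yields no call
  one <- calls[calls$pos == 5L, ]
  expect_equal(one$dcs_count, 1L)          # single-molecule variant retained
  expect_identical(one$maf_source, "SSCS") # minor depth 1 < 5
  expect_equal(one$maf, 3 / 300)
  low <- calls[calls$pos == 6L, ]
  expect_identical(low$maf_source, "SSCS") # minor depth 4 < 5
  expect_equal(low$maf, 0.013)
})

test_that("MAF source selection uses the strict <5 DCS rule", {
  src <- select_maf_source(c(7, 4, 5), c(0.1, 0.2, 0.3), c(0.11, 0.21, 0.31))
  expect_identical(src$source, c("DCS", "SSCS", "DCS"))
  expect_equal(src$maf, c(0.1, 0.21, 0.3))
  expect_equal(as_minor_af(c(0.2, 0.8)), c(0.2, 0.2))
})

test_that("count conservation holds before and after clipping", {
  set.seed(55)
  g <- toy_genome()
  rows <- lapply(1:40, function(i) {
    st <- sample(g$length, 1)
    len1 <- sample(30:60, 1); len2 <- sample(30:60, 1)
    gap <- sample(-20:40, 1)
    rbind(aln_row(template = paste0("t", i), mate = 1L, start = st,
                  seq = substr(paste0(g$sequence, g$sequence), st,
                               st + len1 - 1L)),
          aln_row(template = paste0("t", i), mate = 2L,
                  start = st + len1 + gap,
                  seq = substr(paste0(g$sequence, g$sequence),
                               st + len1 + gap, st + len1 + gap + len2 - 1L)))
  })
  a <- do.call(rbind, rows)
  before <- pileup(a, g)
  after <- pileup(clip_overlaps(a), g)
  nbases <- function(x) sum(nchar(x$seq))
  expect_equal(sum(before$dcs_depth), nbases(a))
  expect_equal(sum(after$dcs_depth), nbases(clip_overlaps(a)))
  # clipping only ever reduces counts
  m <- merge(before, after, by = "pos", suffixes = c("_b", "_a"))
  expect_true(all(m$dcs_depth_a <= m$dcs_depth_b))
})

test_that("pileup agrees with a per-read scanning oracle on small instances", {
  set.seed(66)
  g <- toy_genome()
  a <- do.call(rbind, lapply(1:12, function(i) {
    st <- sample(g$length, 1)
    aln_row(template = paste0("t", i), start = st,
            seq = random_seq(sample(10:30, 1)))
  }))
  counts <- pileup(a, g)
  # oracle: walk every read base by base into a dictionary
  tally <- new.env()
  for (i in seq_len(nrow(a))) {
    ch <- strsplit(a$seq[i], "")[[1]]
    for (j in seq_along(ch)) {
      p <- ((a$start[i] + j - 2L) %% g$length) + 1L
      key <- paste0(p, ch[j])
      tally[[key]] <- (if (is.null(tally[[key]])) 0L else tally[[key]]) + 1L
    }
  }
  for (r in seq_len(nrow(counts))) {
    for (b in c("A", "C", "G", "T")) {
      key <- paste0(counts$pos[r], b)
      expected <- if (is.null(tally[[key]])) 0L else tally[[key]]
      expect_equal(counts[[paste0("dcs_", b)]][r], expected)
    }
  }
})

test_that("SAM input is parsed into the alignment schema", {
  skip_if_not_installed("Rsamtools")
  g <- toy_genome()
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:toy\tLN:", g$length),
           paste("r1", 99, "toy", 100, 60, "20M", "=", 150, 70,
                 substr(g$sequence, 100, 119), paste(rep("I", 20),
                                                     collapse = ""),
                 sep = "\t"),
           paste("r1", 147, "toy", 150, 60, "20M", "=", 100, -70,
                 substr(g$sequence, 150, 169), paste(rep("I", 20),
                                                     collapse = ""),
                 sep = "\t"))
  path <- tempfile(fileext = ".sam")
  writeLines(sam, path)
  a <- read_sam_alignments(path)
  expect_equal(nrow(a), 2L)
  expect_equal(a$start, c(100L, 150L))
  expect_equal(a$mate, c(1L, 2L))
  expect_true(all(a$proper_pair))
  counts <- pileup(a, g)
  expect_true(all(counts$dcs_depth == 1))
})
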