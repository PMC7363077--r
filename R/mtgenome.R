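# Circular mitochondrial reference genome with functional compartment
# annotation.  Coordinates are 1-based inclusive throughout; positions wrap
# silently around the origin.

COMPARTMENTS <- c("D-loop", "protein-coding", "tRNA", "rRNA", "noncoding")

#' Construct a circular mitochondrial genome object
#'
#' Bundles a circular nucleotide sequence with a functional feature table and
#' precomputes the per-position compartment labelling.  Overlapping features
#' are resolved by the fixed precedence D-loop > protein-coding > tRNA > rRNA >
#' noncoding, so that every position carries exactly one compartment label;
#' unannotated positions are labelled `"noncoding"`.
#'
#' @param sequence Single character string over `A`,`C`,`G`,`T` (the reference
#'   light strand, 5'->3').
#' @param features `data.frame` with columns `kind` (one of `r
#'   paste(COMPARTMENTS, collapse = ", ")`), `name`, `start`, `end` (1-based,
#'   inclusive, `start <= end`) and `strand` (`"L"` for the reference
#'   direction, `"H"` for its reverse complement).
#' @param name Genome name.
#' @return An object of class `mt_genome` with elements `name`, `sequence`,
#'   `length`, `features` and the cached per-position `compartment` vector.
#' @export
mt_genome <- function(sequence, features, name = "mtDNA") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("sequence must contain only A, C, G, T")
  len <- nchar(sequence)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  req <- c("kind", "name", "start", "end", "strand")
  if (!all(req %in% names(features)))
    stop("features must have columns: ", paste(req, collapse = ", "))
  if (!all(features$kind %in% COMPARTMENTS))
    stop("unknown feature kind(s): ",
         paste(setdiff(features$kind, COMPARTMENTS), collapse = ", "))
  if (any(features$start < 1L | features$end > len | features$start > features$end))
    stop("feature coordinates must lie in [1, ", len, "] with start <= end")
  bad <- features$kind == "protein-coding" &
    (features$end - features$start + 1L) %% 3L != 0L
  if (any(bad))
    warning("protein-coding feature(s) with span not divisible by 3: ",
            paste(features$name[bad], collapse = ", "))
  g <- structure(
    list(name = name, sequence = sequence, length = len, features = features),
    class = "mt_genome")
  g$compartment <- resolve_compartments(g)
  g
}

# Fill per-position labels in reverse precedence order so that higher
# precedence features overwrite lower ones.
resolve_compartments <- function(genome) {
  lab <- rep("noncoding", genome$length)
  prec <- rev(COMPARTMENTS)  # noncoding first, D-loop last
  f <- genome$features
  for (kind in prec) {
    for (i in which(f$kind == kind)) lab[f$start[i]:f$end[i]] <- kind
  }
  lab
}

#' @export
print.mt_genome <- function(x, ...) {
  cat("mt_genome:", x$name, "-", x$length, "bp,",
      nrow(x$features), "features\n")
  print(compartment_sizes(x))
  invisible(x)
}

#' Compartment label of one or more positions
#'
#' @param genome An [mt_genome] object.
#' @param position Integer vector of 1-based positions in `[1, length]`.
#' @return Character vector of compartment labels.
#' @export
compartment_of <- function(genome, position) {
  if (any(position < 1L | position > genome$length))
    stop("position out of range [1, ", genome$length, "]")
  genome$compartment[position]
}

#' Total length of each compartment
#'
#' The labelling is an exhaustive, exclusive partition, so the sizes sum to
#' the genome length.
#'
#' @param genome An [mt_genome] object.
#' @return Named integer vector over the five compartment labels.
#' @export
compartment_sizes <- function(genome) {
  tab <- table(factor(genome$compartment, levels = COMPARTMENTS))
  stats::setNames(as.integer(tab), names(tab))
}

# Circular 1-based index.
wrap_pos <- function(position, len) ((position - 1L) %% len) + 1L

# Base(s) at circular position(s), on the reference (L) strand.
genome_base <- function(genome, position) {
  p <- wrap_pos(position, genome$length)
  substring(genome$sequence, p, p)
}

#' Reverse complement of nucleotide strings
#'
#' Thin wrapper kept vectorised over plain character vectors (handles `N`).
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Trinucleotide context and CpG status of a site
#'
#' Returns the 3-mer centred on the queried site on the requested strand
#' (`"H"` gives the reverse complement of the L-strand context), using
#' circular wrap-around at the genome ends.  A site is flagged CpG when it
#' participates in a 5'-CG-3' dinucleotide on either strand, i.e. when the
#' reference base at the site is a C followed by G or a G preceded by C.
#'
#' @param genome An [mt_genome] object.
#' @param position 1-based position (vectorised).
#' @param strand `"L"` (default) or `"H"`.
#' @return `data.frame` with columns `position`, `strand`, `context`, `cpg`.
#' @export
context_of <- function(genome, position, strand = "L") {
  if (any(position < 1L | position > genome$length))
    stop("position out of range [1, ", genome$length, "]")
  strand <- rep_len(strand, length(position))
  left  <- genome_base(genome, position - 1L)
  mid   <- genome_base(genome, position)
  right <- genome_base(genome, position + 1L)
  ctx <- paste0(left, mid, right)
  h <- strand == "H"
  ctx[h] <- revcomp(ctx[h])
  cpg <- (mid == "C" & right == "G") | (mid == "G" & left == "C")
  data.frame(position = position, strand = strand, context = ctx, cpg = cpg,
             stringsAsFactors = FALSE)
}

#' Collapse a directed substitution to the pyrimidine-centred convention
#'
#' Mutation spectra are reported with the mutated base a pyrimidine (C or T):
#' a purine substitution is replaced by its reverse complement and its context
#' reverse-complemented, e.g. `G>T` at L-strand context `TGT` is tallied as
#' `C>A` at `ACA` (both strands carry the same event).
#'
#' @param ref,alt Single-character reference and alternate bases (vectorised).
#' @param context Optional 3-mer context(s) centred on `ref`.
#' @return `data.frame` with columns `ref`, `alt`, `type` and, when `context`
#'   is supplied, `context`, all in the collapsed representation.
#' @export
collapse_substitution <- function(ref, alt, context = NULL) {
  purine <- ref %in% c("A", "G")
  cref <- ifelse(purine, comp_base(ref), ref)
  calt <- ifelse(purine, comp_base(alt), alt)
  out <- data.frame(ref = cref, alt = calt,
                    type = paste0(cref, ">", calt), stringsAsFactors = FALSE)
  if (!is.null(context)) {
    context <- as.character(context)
    context[purine] <- revcomp(context[purine])
    out$context <- context
  }
  out
}

#' Apply pedigree-specific edits to a genome
#'
#' Applies single-base substitutions and insertions (edits observed in a
#' pedigree relative to the reference) and remaps all feature coordinates.
#' An insertion at position p inserts the given base immediately after p;
#' features starting beyond p shift right and features spanning p grow by one.
#'
#' @param genome An [mt_genome] object.
#' @param edits `data.frame` with columns `position`, `op` (`"sub"` or
#'   `"ins"`) and `base`.  Edits must be at distinct positions.
#' @return A new [mt_genome].
#' @export
apply_pedigree_edits <- function(genome, edits) {
  edits <- as.data.frame(edits, stringsAsFactors = FALSE)
  if (nrow(edits) == 0L) return(genome)
  stopifnot(all(c("position", "op", "base") %in% names(edits)),
            all(edits$op %in% c("sub", "ins")))
  if (any(edits$position < 1L | edits$position > genome$length))
    stop("edit position out of range")
  if (anyDuplicated(edits$position)) stop("edits must not overlap")
  edits <- edits[order(edits$position, decreasing = TRUE), , drop = FALSE]
  seq_chars <- strsplit(genome$sequence, "")[[1]]
  feats <- genome$features
  for (i in seq_len(nrow(edits))) {
    p <- edits$position[i]
    if (edits$op[i] == "sub") {
      seq_chars[p] <- edits$base[i]
    } else {
      seq_chars <- append(seq_chars, edits$base[i], after = p)
      grow <- feats$start <= p & feats$end > p
      feats$end[grow] <- feats$end[grow] + 1L
      shift <- feats$start > p
      feats$start[shift] <- feats$start[shift] + 1L
      feats$end[shift & !grow] <- feats$end[shift & !grow] + 1L
    }
  }
  mt_genome(paste(seq_chars, collapse = ""), feats, name = genome$name)
}

#' Read a genome from FASTA plus a feature TSV
#'
#' @param fasta Path to a single-record FASTA file.
#' @param feature_tsv Path to a tab-separated feature table with columns
#'   `kind`, `name`, `start`, `end`, `strand`.
#' @param name Optional genome name (defaults to the FASTA record name).
#' @return An [mt_genome].
#' @export
read_mt_genome <- function(fasta, feature_tsv, name = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) stop("expected a single-record FASTA")
  features <- utils::read.delim(feature_tsv, stringsAsFactors = FALSE)
  mt_genome(as.character(seqs[[1]]), features,
            name = if (is.null(name)) names(seqs)[1] else name)
}

#' Parse features from a GenBank flat file
#'
#' Minimal parser for the FEATURES block of a GenBank record: extracts
#' `D-loop`, `CDS`, `tRNA` and `rRNA` keys with simple or `complement(a..b)`
#' locations and a `/gene` or `/product` qualifier as the name.  Joined or
#' fuzzy locations are skipped with a warning.
#'
#' @param path Path to a GenBank flat file.
#' @return Feature `data.frame` suitable for [mt_genome()].
#' @export
read_genbank_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keymap <- c("D-loop" = "D-loop", "CDS" = "protein-coding",
              "tRNA" = "tRNA", "rRNA" = "rRNA", "misc_feature" = "noncoding")
  idx <- grep("^ {5}\\S", lines)
  out <- list()
  for (k in seq_along(idx)) {
    ln <- lines[idx[k]]
    key <- sub("^ {5}(\\S+).*", "\\1", ln)
    if (!key %in% names(keymap)) next
    loc <- sub("^ {5}\\S+\\s+", "", ln)
    strand <- if (grepl("^complement", loc)) "H" else "L"
    m <- regmatches(loc, regexec("(\\d+)\\.\\.(\\d+)", loc))[[1]]
    if (length(m) != 3L) {
      warning("skipping feature with unsupported location: ", loc)
      next
    }
    to <- if (k < length(idx)) idx[k + 1] - 1L else length(lines)
    block <- lines[idx[k]:to]
    nm <- grep('/(gene|product)="', block, value = TRUE)
    nm <- if (length(nm)) sub('.*="([^"]*)".*', "\\1", nm[1]) else key
    out[[length(out) + 1L]] <- data.frame(
      kind = keymap[[key]], name = nm,
      start = as.integer(m[2]), end = as.integer(m[3]),
      strand = strand, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# ---- packaged synthetic reference -----------------------------------------

# Feature layout of the synthetic mouse-like mtDNA reference (16,299 bp before
# the pedigree insertion).  Compartment totals match the study genome:
# D-loop 877, protein-coding 11,331, rRNA 2,536, other noncoding 57, and tRNA
# 1,498 growing to 1,499 once the A insertion inside TrnR is applied.
synthetic_mt_layout <- function() {
  L <- function(kind, name, len, strand = "L")
    data.frame(kind = kind, name = name, len = len, strand = strand,
               stringsAsFactors = FALSE)
  rbind(
    L("tRNA", "TrnF", 68), L("rRNA", "Rnr1", 955), L("tRNA", "TrnV", 69),
    L("rRNA", "Rnr2", 1581), L("tRNA", "TrnL1", 68),
    L("protein-coding", "ND1", 957),
    L("tRNA", "TrnI", 68), L("tRNA", "TrnQ", 68, "H"), L("tRNA", "TrnM", 68),
    L("protein-coding", "ND2", 1044),
    L("tRNA", "TrnW", 68), L("tRNA", "TrnA", 68, "H"), L("tRNA", "TrnN", 68, "H"),
    L("noncoding", "OriL", 57),
    L("tRNA", "TrnC", 68, "H"), L("tRNA", "TrnY", 68, "H"),
    L("protein-coding", "COX1", 1545),
    L("tRNA", "TrnS1", 68, "H"), L("tRNA", "TrnD", 68),
    L("protein-coding", "COX2", 684),
    L("tRNA", "TrnK", 68),
    L("protein-coding", "ATP8", 201), L("protein-coding", "ATP6", 681),
    L("protein-coding", "COX3", 732),
    L("tRNA", "TrnG", 68),
    L("protein-coding", "ND3", 345),
    L("tRNA", "TrnR", 68),
    L("protein-coding", "ND4L", 297), L("protein-coding", "ND4", 1428),
    L("tRNA", "TrnH", 68), L("tRNA", "TrnS2", 68), L("tRNA", "TrnL2", 69),
    L("protein-coding", "ND5", 1746),
    L("protein-coding", "ND6", 528, "H"),
    L("tRNA", "TrnE", 68, "H"),
    L("protein-coding", "CYTB", 1143),
    L("tRNA", "TrnT", 68), L("tRNA", "TrnP", 68, "H"),
    L("D-loop", "D-loop", 877))
}

#' Synthetic mouse-like mtDNA reference genome
#'
#' Deterministically generates a synthetic 16,299-bp circular genome whose
#' functional layout mirrors the mouse mtDNA compartment structure (13
#' protein-coding genes, 22 tRNAs, 2 rRNAs, one short noncoding origin and the
#' control region at the end of the sequence), with compartment totals
#' matching the study genome annotation exactly.  Coding regions are generated
#' codon-wise under the vertebrate mitochondrial code with a start codon, a
#' terminal stop and no internal stops on the coding strand.  The sequence is
#' synthetic: it is not the RefSeq mouse sequence.
#'
#' @param seed Integer seed for the sequence generator.
#' @param apply_edits If `TRUE` (default) the pedigree edits of
#'   [synthetic_pedigree_edits()] are applied, giving a 16,300-bp genome with
#'   the extra A inside TrnR.
#' @return An [mt_genome].
#' @export
synthetic_mt_genome <- function(seed = 20200715, apply_edits = TRUE) {
  layout <- synthetic_mt_layout()
  ends <- cumsum(layout$len)
  features <- data.frame(kind = layout$kind, name = layout$name,
                         start = ends - layout$len + 1L, end = ends,
                         strand = layout$strand, stringsAsFactors = FALSE)
  len <- ends[length(ends)]
  rng <- local_rng(seed)
  # L-strand base composition is cytosine-rich relative to guanine, as in
  # vertebrate mtDNA light strands.
  bases <- c("A", "C", "G", "T")
  seq_chars <- sample(bases, len, replace = TRUE,
                      prob = c(0.35, 0.24, 0.12, 0.29))
  stops <- c("TAA", "TAG", "AGA", "AGG")
  codon_pool <- setdiff(all_codons(), stops)
  cds <- features[features$kind == "protein-coding", ]
  for (i in seq_len(nrow(cds))) {
    n_codon <- (cds$end[i] - cds$start[i] + 1L) %/% 3L
    codons <- c("ATG", sample(codon_pool, n_codon - 2L, replace = TRUE), "TAA")
    s <- paste(codons, collapse = "")
    if (cds$strand[i] == "H") s <- revcomp(s)
    seq_chars[cds$start[i]:cds$end[i]] <- strsplit(s, "")[[1]]
  }
  rng()  # restore RNG state
  g <- mt_genome(paste(seq_chars, collapse = ""), features,
                 name = "synthetic-mmu-mtDNA")
  if (apply_edits) g <- apply_pedigree_edits(g, synthetic_pedigree_edits())
  g
}

#' Pedigree edits of the synthetic reference
#'
#' The A insertion after position 9,821 (inside TrnR) shared by both study
#' pedigrees, which brings the genome to 16,300 bp, and the T>C substitution
#' at position 9,461 (inside ND3).
#'
#' @return Edits `data.frame` for [apply_pedigree_edits()].
#' @export
synthetic_pedigree_edits <- function() {
  data.frame(position = c(9821L, 9461L), op = c("ins", "sub"),
             base = c("A", "C"), stringsAsFactors = FALSE)
}

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# Run code under a seeded RNG and return a restorer; used so constructors do
# not disturb the caller's RNG stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}

#' Write a genome to FASTA and a feature TSV
#'
#' @param genome An [mt_genome].
#' @param fasta,feature_tsv Output paths.
#' @return Invisibly, the paths.
#' @export
write_mt_genome <- function(genome, fasta, feature_tsv) {
  dna <- Biostrings::DNAStringSet(genome$sequence)
  names(dna) <- genome$name
  Biostrings::writeXStringSet(dna, fasta)
  utils::write.table(genome$features, feature_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fasta, feature_tsv))
}
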