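# Shared fixtures: small genomes and configs built in code at test time.

# Small circular genome (1,200 bp) with all five compartments; coding
# regions are codon-clean under the vertebrate mitochondrial code.
toy_genome <- function(seed = 42) {
  set.seed(seed)
  len <- 1200L
  features <- data.frame(
    kind = c("tRNA", "rRNA", "protein-coding", "tRNA", "protein-coding",
             "noncoding", "D-loop"),
    name = c("tA", "rS", "geneA", "tB", "geneB", "nc", "D-loop"),
    start = c(1L, 61L, 261L, 561L, 621L, 921L, 1051L),
    end = c(60L, 260L, 560L, 620L, 920L, 950L, 1200L),
    strand = c("L", "L", "L", "H", "H", "L", "L"),
    stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  seq_chars <- sample(bases, len, replace = TRUE,
                      prob = c(0.35, 0.24, 0.12, 0.29))
  stops <- c("TAA", "TAG", "AGA", "AGG")
  pool <- setdiff(mtduplex:::all_codons(), stops)
  cds <- features[features$kind == "protein-coding", ]
  for (i in seq_len(nrow(cds))) {
    n_codon <- (cds$end[i] - cds$start[i] + 1L) %/% 3L
    s <- paste(c("ATG", sample(pool, n_codon - 2L, TRUE), "TAA"),
               collapse = "")
    if (cds$strand[i] == "H") s <- revcomp(s)
    seq_chars[cds$start[i]:cds$end[i]] <- strsplit(s, "")[[1]]
  }
  mt_genome(paste(seq_chars, collapse = ""), features, name = "toy")
}

# tiny read-pair table with given tags (helper for consensus tests)
make_pairs <- function(tags1, tags2, frag1, frag2, spacer = "TGACT") {
  data.frame(id = sprintf("r%d", seq_along(tags1)),
             seq1 = paste0(tags1, spacer, frag1),
             seq2 = paste0(tags2, spacer, frag2),
             stringsAsFactors = FALSE)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# minimal sample metadata table
make_samples <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (is.null(df$fragmentation)) df$fragmentation <- "covaris"
  if (is.null(df$mean_dcs_depth)) df$mean_dcs_depth <- 1000
  df
}
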