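# Nonsynonymous/synonymous rate ratio (hN/hS) with Nei-Gojobori site
# counting and a bootstrap neutrality test.  All codon logic uses the
# vertebrate mitochondrial genetic code (translation table 2).

mito_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("2")
    code
  }
})

translate_codon <- function(codon) unname(mito_code()[codon])

MITO_START_CODONS <- c("ATG", "ATA")

#' Nei-Gojobori synonymous and nonsynonymous site counts
#'
#' For each codon, the synonymous site count of a position is the fraction
#' of its three possible substitutions that preserve the amino acid (stop
#' codons count as distinct "amino acids"); nonsynonymous sites are the
#' complement, so each codon contributes exactly 3 sites in total.
#'
#' @param cds Coding sequence (character string, length divisible by 3,
#'   coding strand).
#' @param warn_internal_stops Warn when internal stop codons are present.
#' @return List with `syn_sites`, `nonsyn_sites`, `n_codons`.
#' @export
ng_sites <- function(cds, warn_internal_stops = TRUE) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length must be divisible by 3")
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aa <- translate_codon(codons)
  if (warn_internal_stops && any(aa[-length(aa)] == "*"))
    warning("internal stop codon(s) in CDS")
  syn <- sum(vapply(codons, codon_syn_sites, numeric(1)))
  list(syn_sites = syn, nonsyn_sites = 3 * length(codons) - syn,
       n_codons = length(codons))
}

codon_syn_sites <- local({
  cache <- NULL
  function(codon) {
    if (is.null(cache)) {
      code <- mito_code()
      cc <- names(code)
      s <- stats::setNames(numeric(length(cc)), cc)
      for (cd in cc) {
        aa <- code[[cd]]
        syn <- 0L
        for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                         substr(cd, p, p))) {
          alt <- cd
          substr(alt, p, p) <- b
          if (code[[alt]] == aa) syn <- syn + 1L
        }
        s[cd] <- syn / 3
      }
      cache <<- s
    }
    cache[[codon]]
  }
})

# Coding-region index: one row per (coding position, alt) with the L-strand
# ref/alt, the mutation type on the reference strand, and the coding effect.
coding_effect_table <- function(genome) {
  cds <- genome$features[genome$features$kind == "protein-coding", ,
                         drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cds))) {
    span <- cds$start[i]:cds$end[i]
    # positions whose compartment label is overridden (precedence) are not
    # part of the analysed coding sequence
    span <- span[genome$compartment[span] == "protein-coding"]
    if (!length(span)) next
    fwd <- cds$strand[i] == "L"
    seq_l <- substr(genome$sequence, cds$start[i], cds$end[i])
    coding <- if (fwd) seq_l else revcomp(seq_l)
    clen <- nchar(coding)
    for (pos in span) {
      idx <- if (fwd) pos - cds$start[i] + 1L else cds$end[i] - pos + 1L
      ci <- (idx - 1L) %/% 3L
      cp <- idx - 3L * ci
      codon <- substr(coding, 3L * ci + 1L, 3L * ci + 3L)
      aa <- translate_codon(codon)
      ref_l <- substr(genome$sequence, pos, pos)
      for (alt_l in setdiff(c("A", "C", "G", "T"), ref_l)) {
        alt_c <- if (fwd) alt_l else comp_base(alt_l)
        new_codon <- codon
        substr(new_codon, cp, cp) <- alt_c
        new_aa <- translate_codon(new_codon)
        effect <-
          if (ci == 0L && codon %in% MITO_START_CODONS &&
              !new_codon %in% MITO_START_CODONS) "start_lost"
          else if (aa != "*" && new_aa == "*") "stop_gained"
          else if (aa == "*" && new_aa != "*") "stop_lost"
          else if (aa == new_aa) "synonymous"
          else "nonsynonymous"
        rows[[length(rows) + 1L]] <- c(pos = pos, gene = cds$name[i],
                                       ref = ref_l, alt = alt_l,
                                       effect = effect)
      }
    }
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  out$pos <- as.integer(out$pos)
  out$type <- paste0(out$ref, ">", out$alt)
  out$syn <- out$effect == "synonymous"
  out
}

# cached per-genome effect tables (keyed by genome name + length)
.effect_cache <- new.env(parent = emptyenv())

get_effect_table <- function(genome) {
  key <- paste0(genome$name, "#", genome$length)
  if (is.null(.effect_cache[[key]]))
    .effect_cache[[key]] <- coding_effect_table(genome)
  .effect_cache[[key]]
}

#' Coding effect of a substitution
#'
#' @param genome An [mt_genome].
#' @param site Position inside a protein-coding feature.
#' @param alt Alternate base on the reference strand.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"stop_gained"`,
#'   `"stop_lost"`, `"start_lost"`.
#' @export
classify_coding_mutation <- function(genome, site, alt) {
  et <- get_effect_table(genome)
  hit <- et$effect[et$pos == site & et$alt == alt]
  if (!length(hit))
    stop("site ", site, " / alt ", alt, " is not a coding substitution")
  hit[1]
}

#' Nei-Gojobori site totals over all protein-coding regions
#'
#' @param genome An [mt_genome].
#' @return List with `syn_sites` and `nonsyn_sites` summed over CDS.
#' @export
ng_sites_genome <- function(genome) {
  cds <- genome$features[genome$features$kind == "protein-coding", ,
                         drop = FALSE]
  tot <- list(syn_sites = 0, nonsyn_sites = 0)
  for (i in seq_len(nrow(cds))) {
    s <- substr(genome$sequence, cds$start[i], cds$end[i])
    if (cds$strand[i] == "H") s <- revcomp(s)
    ng <- ng_sites(s, warn_internal_stops = FALSE)
    tot$syn_sites <- tot$syn_sites + ng$syn_sites
    tot$nonsyn_sites <- tot$nonsyn_sites + ng$nonsyn_sites
  }
  tot
}

#' hN/hS ratio with a bootstrap neutrality test
#'
#' hN is the number of nonsynonymous mutations per nonsynonymous site and hS
#' the number of synonymous mutations per synonymous site (Nei-Gojobori site
#' counts); under neutrality the ratio is expected to equal 1.  The neutral
#' null distribution is generated by bootstrap: each replicate places the
#' same number of mutations on coding sites at random, drawing types from
#' the observed 12-type spectrum and sites uniformly among coding positions
#' offering that type; the empirical two-sided p-value compares the observed
#' ratio with the replicates (add-one correction).  Stop and start changes
#' count as nonsynonymous.  Duplicate records (same sample, site, alt) are
#' collapsed before counting.
#'
#' @param records Mutation records in coding regions (`pos`, `ref`, `alt`,
#'   optionally `sample_id`).
#' @param genome An [mt_genome].
#' @param n_boot Number of bootstrap replicates (default 100).
#' @return List with `hn`, `hs`, `ratio`, `n_nonsyn`, `n_syn`, `sites`,
#'   `p`, `null_ratios`; `ratio` and `p` are `NA` when hS is undefined
#'   (no synonymous mutations observed or no synonymous sites).
#' @export
hn_hs <- function(records, genome, n_boot = 100L) {
  et <- get_effect_table(genome)
  if (!is.null(records$sample_id)) {
    records <- records[!duplicated(paste(records$sample_id, records$pos,
                                         records$alt)), , drop = FALSE]
  } else {
    records <- records[!duplicated(paste(records$pos, records$alt)), ,
                       drop = FALSE]
  }
  hit <- match(paste(records$pos, records$alt),
               paste(et$pos, et$alt))
  if (anyNA(hit))
    stop(sum(is.na(hit)), " record(s) are not coding substitutions")
  eff <- et$effect[hit]
  n_syn <- sum(eff == "synonymous")
  n_nonsyn <- sum(eff != "synonymous")
  sites <- ng_sites_genome(genome)
  hn <- n_nonsyn / sites$nonsyn_sites
  hs <- if (sites$syn_sites > 0) n_syn / sites$syn_sites else NA_real_
  out <- list(hn = hn, hs = hs, n_nonsyn = n_nonsyn, n_syn = n_syn,
              sites = sites)
  if (is.na(hs) || hs == 0) {
    out$ratio <- NA_real_; out$p <- NA_real_; out$null_ratios <- numeric(0)
    return(out)
  }
  out$ratio <- hn / hs
  n <- n_syn + n_nonsyn
  types <- et$type[hit]
  spec <- table(types) / n
  # per-type synonymous probability under uniform placement among coding
  # sites offering the type; placing and classifying each mutation is then
  # a Bernoulli draw, so replicate syn counts are binomial sums
  p_syn <- vapply(names(spec), function(t) mean(et$syn[et$type == t]),
                  numeric(1))
  null_ratios <- vapply(seq_len(n_boot), function(b) {
    n_t <- stats::rmultinom(1, n, spec)[, 1]
    s <- sum(stats::rbinom(length(n_t), n_t, p_syn))
    if (s == 0) return(Inf)
    ((n - s) / sites$nonsyn_sites) / (s / sites$syn_sites)
  }, numeric(1))
  lo <- sum(null_ratios <= out$ratio)
  hi <- sum(null_ratios >= out$ratio)
  out$p <- min(1, 2 * min(lo + 1, hi + 1) / (n_boot + 1))
  out$null_ratios <- null_ratios
  out
}
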