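# Mutation-frequency computation and the statistical battery: Poisson
# intervals, Fisher comparisons, observed-vs-expected binomial tests,
# permutation tests on medians, strand bias, spectra, FDR control.

#' Mutation frequency per sequenced base pair
#'
#' `n / (region_length_bp * mean_dcs_depth)`.  For aggregates across
#' samples, pass the *sum* of mean DCS depths (denominators are summed,
#' never averaged); alternatively supply the precomputed `denominator`
#' directly.
#'
#' @param n_mutations Mutation count.
#' @param region_length_bp Region length (bp).
#' @param mean_dcs_depth Mean DCS depth (or sum of per-sample means).
#' @param denominator Optional explicit denominator in sequenced bp,
#'   overriding `region_length_bp * mean_dcs_depth`.
#' @return Frequency per bp.
#' @export
mutation_frequency <- function(n_mutations, region_length_bp = NULL,
                               mean_dcs_depth = NULL, denominator = NULL) {
  if (is.null(denominator)) {
    stopifnot(!is.null(region_length_bp), !is.null(mean_dcs_depth))
    denominator <- region_length_bp * mean_dcs_depth
  }
  stopifnot(all(denominator > 0), all(n_mutations >= 0))
  n_mutations / denominator
}

#' Exact Poisson confidence interval for a frequency
#'
#' Garwood interval on the count (chi-squared inversion of the Poisson CDF),
#' divided by the denominator; the lower bound is 0 at count 0.
#'
#' @param count Observed count (vectorised).
#' @param denominator Sequenced bp.
#' @param level Confidence level (default 0.95).
#' @return `data.frame` with `estimate`, `lower`, `upper` (per bp).
#' @export
poisson_ci <- function(count, denominator = 1, level = 0.95) {
  a <- (1 - level) / 2
  lower <- ifelse(count == 0, 0, stats::qchisq(a, 2 * count) / 2)
  upper <- stats::qchisq(1 - a, 2 * (count + 1)) / 2
  data.frame(estimate = count / denominator, lower = lower / denominator,
             upper = upper / denominator)
}

#' Fisher's exact comparison of two mutation frequencies
#'
#' Builds the 2x2 table {mutated, unmutated} x {group 1, group 2} and runs
#' the two-sided exact test; the frequency fold change `(n1/d1)/(n2/d2)` is
#' reported alongside.
#'
#' @param n1,d1 Count and denominator (sequenced bp) of group 1.
#' @param n2,d2 Count and denominator of group 2.
#' @return List with `fold`, `odds_ratio`, `p`, `table`.
#' @export
fisher_compare <- function(n1, d1, n2, d2) {
  stopifnot(n1 <= d1, n2 <= d2)
  tab <- matrix(round(c(n1, d1 - n1, n2, d2 - n2)), nrow = 2, byrow = TRUE,
                dimnames = list(c("group1", "group2"),
                                c("mutated", "unmutated")))
  ft <- stats::fisher.test(tab)
  list(fold = (n1 / d1) / (n2 / d2),
       odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}

#' Observed-versus-expected binomial test for a region
#'
#' Tests whether the number of mutations observed in a region deviates from
#' the expectation under uniform placement, with success probability
#' `region_length / genome_length`.
#'
#' @param observed_in_region Mutations observed in the region.
#' @param total_mutations Total mutations observed.
#' @param region_length,genome_length Lengths in bp.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return List with `p`, `observed`, `expected`, `ratio`.
#' @export
observed_expected_binomial <- function(observed_in_region, total_mutations,
                                       region_length, genome_length,
                                       alternative = "greater") {
  stopifnot(region_length <= genome_length,
            observed_in_region <= total_mutations)
  pr <- region_length / genome_length
  expected <- total_mutations * pr
  p <- if (total_mutations == 0) 1 else
    stats::binom.test(observed_in_region, total_mutations, pr,
                      alternative = alternative)$p.value
  list(p = p, observed = observed_in_region, expected = expected,
       ratio = if (expected > 0) observed_in_region / expected else NA_real_)
}

#' One-sided permutation test on group medians
#'
#' Statistic: `median(a) - median(b)`.  Group labels are permuted; the
#' Monte-Carlo p-value uses the add-one estimator
#' `(#{perm >= obs} + 1) / (n_perm + 1)` (never exactly 0).  When the number
#' of distinct label arrangements is at most `n_perm`, all arrangements are
#' enumerated and the exact tail fraction is returned instead.
#'
#' @param a,b Numeric vectors of per-sample values.
#' @param n_perm Number of random permutations (default 1e5).
#' @param alternative `"a_greater"` (default) or `"b_greater"`.
#' @return List with `p`, `statistic`, `method` (`"exhaustive"` or
#'   `"monte-carlo"`), `n_perm`.
#' @export
permutation_median_test <- function(a, b, n_perm = 1e5,
                                    alternative = c("a_greater", "b_greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) >= 1, length(b) >= 1)
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  sgn <- if (alternative == "a_greater") 1 else -1
  obs <- sgn * (stats::median(a) - stats::median(b))
  n_arrangements <- choose(n, na)
  if (is.finite(n_arrangements) && n_arrangements <= n_perm) {
    idx <- utils::combn(n, na)
    stats <- apply(idx, 2, function(i)
      sgn * (stats::median(pool[i]) - stats::median(pool[-i])))
    list(p = mean(stats >= obs - 1e-12), statistic = sgn * obs,
         method = "exhaustive", n_perm = ncol(idx))
  } else {
    hits <- 0L
    for (r in seq_len(n_perm)) {
      i <- sample.int(n, na)
      if (sgn * (stats::median(pool[i]) - stats::median(pool[-i])) >=
          obs - 1e-12) hits <- hits + 1L
    }
    list(p = (hits + 1) / (n_perm + 1), statistic = sgn * obs,
         method = "monte-carlo", n_perm = n_perm)
  }
}

#' Benjamini-Hochberg(-Yekutieli) FDR adjustment
#'
#' Step-up false-discovery-rate adjustment; `"BY"` (default) applies the
#' Benjamini-Yekutieli correction valid under arbitrary dependence, `"BH"`
#' the plain Benjamini-Hochberg procedure.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param method `"BY"` or `"BH"`.
#' @return Adjusted p-values.
#' @export
adjust_fdr <- function(p_values, method = c("BY", "BH")) {
  method <- match.arg(method)
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = method)
}

#' Fold change between two frequencies with study-style rounding
#'
#' @param f_numerator,f_denominator Frequencies.
#' @param digits Decimal places for the reported fold (default 1).
#' @return Rounded fold change.
#' @export
fold_change <- function(f_numerator, f_denominator, digits = 1) {
  round(f_numerator / f_denominator, digits)
}

# ---- denominators ----------------------------------------------------------

#' Sequenced nucleotides per reference base for a sample group
#'
#' The number of sequenced nucleotides "that can effectively lead to" a
#' mutation type X>Y is the number of sequenced X bases: genome base content
#' (optionally within one compartment, or inside/outside the D-loop) times
#' the summed mean DCS depth of the samples.
#'
#' @param genome An [mt_genome].
#' @param depth_sum Sum of mean DCS depths over the samples in the group.
#' @param compartment Optional compartment label, or `"non-D-loop"` for the
#'   complement of the D-loop.
#' @return Named numeric vector of sequenced bp per base A, C, G, T.
#' @export
sequenced_nt_by_base <- function(genome, depth_sum, compartment = NULL) {
  chars <- strsplit(genome$sequence, "")[[1]]
  keep <- if (is.null(compartment)) rep(TRUE, genome$length)
  else if (identical(compartment, "non-D-loop")) genome$compartment != "D-loop"
  else genome$compartment == compartment
  tab <- table(factor(chars[keep], levels = c("A", "C", "G", "T")))
  stats::setNames(as.numeric(tab) * depth_sum, names(tab))
}

#' Per-sample mutation frequencies
#'
#' @param records Retained de novo mutation records.
#' @param samples Sample metadata with `mean_dcs_depth`.
#' @param genome_length Genome length in bp.
#' @return `samples` with `n_mutations`, `denominator`, `frequency` columns.
#' @export
per_sample_frequency <- function(records, samples, genome_length) {
  n <- table(factor(records$sample_id, levels = samples$sample_id))
  samples$n_mutations <- as.integer(n)
  samples$denominator <- genome_length * samples$mean_dcs_depth
  samples$frequency <- samples$n_mutations / samples$denominator
  samples
}

#' Aggregated frequency table over sample strata
#'
#' Aggregation sums mutation counts and denominators within each stratum
#' (never averages frequencies) and attaches exact Poisson intervals.
#'
#' @param records Retained de novo records (optionally pre-filtered to a
#'   compartment or type).
#' @param samples Sample metadata with `mean_dcs_depth` and the grouping
#'   columns.
#' @param region_length Region length used in the denominator (bp).
#' @param by Character vector of grouping columns in `samples`.
#' @return `data.frame` per stratum: counts, denominator, frequency, CI.
#' @export
frequency_table <- function(records, samples, region_length,
                            by = c("age_group", "tissue")) {
  grp <- interaction(samples[by], drop = FALSE, sep = "|")
  n_by_sample <- table(factor(records$sample_id, levels = samples$sample_id))
  out <- do.call(rbind, lapply(levels(grp), function(g) {
    sel <- grp == g
    if (!any(sel)) return(NULL)
    n <- sum(n_by_sample[sel])
    denom <- region_length * sum(samples$mean_dcs_depth[sel])
    grp_cols <- stats::setNames(as.data.frame(t(strsplit(g, "|",
                                                         fixed = TRUE)[[1]]),
                                              stringsAsFactors = FALSE), by)
    cbind(grp_cols,
          data.frame(n_samples = sum(sel), n_mutations = n,
                     denominator = denom, frequency = n / denom,
                     poisson_ci(n, denom)[c("lower", "upper")]))
  }))
  rownames(out) <- NULL
  out
}

# ---- strand bias and spectra ----------------------------------------------

RECIPROCAL_PAIRS <- list(c("G>A", "C>T"), c("T>C", "A>G"),
                         c("G>T", "C>A"), c("T>A", "A>T"),
                         c("T>G", "A>C"), c("G>C", "C>G"))

#' Strand-bias table for reciprocal mutation-type pairs
#'
#' For each reciprocal pair (e.g. G>A vs C>T as read on the reference
#' strand), computes type-specific frequencies using as denominator the
#' number of sequenced bases of the type's reference base, and compares the
#' two with Fisher's exact test.
#'
#' @param records Retained de novo records with `type`.
#' @param nt_by_base Sequenced bp per base (see [sequenced_nt_by_base()]).
#' @return `data.frame` with one row per pair: counts, denominators,
#'   frequencies, fold, odds ratio and p.
#' @export
strand_bias_table <- function(records, nt_by_base) {
  do.call(rbind, lapply(RECIPROCAL_PAIRS, function(pair) {
    n1 <- sum(records$type == pair[1])
    n2 <- sum(records$type == pair[2])
    d1 <- nt_by_base[[substr(pair[1], 1, 1)]]
    d2 <- nt_by_base[[substr(pair[2], 1, 1)]]
    fc <- fisher_compare(n1, d1, n2, d2)
    data.frame(type1 = pair[1], type2 = pair[2], n1 = n1, n2 = n2,
               denom1 = d1, denom2 = d2,
               freq1 = n1 / d1, freq2 = n2 / d2,
               fold = fc$fold, odds_ratio = fc$odds_ratio, p = fc$p,
               stringsAsFactors = FALSE)
  }))
}

#' Mutation spectrum summaries
#'
#' Tabulates the 12 directed substitution types with type-specific
#' frequencies, the 6 pyrimidine-collapsed types, the transition/transversion
#' ratio, the CpG versus non-CpG split of C>T/G>A transitions, and the
#' collapsed trinucleotide-context table.
#'
#' @param records Retained de novo records (annotated).
#' @param nt_by_base Optional sequenced bp per base for frequencies.
#' @return List with `types12`, `types6`, `titv`, `cpg_split`, `contexts`.
#' @export
spectrum_tables <- function(records, nt_by_base = NULL) {
  types12 <- sort(unique(unlist(RECIPROCAL_PAIRS)))
  t12 <- table(factor(records$type, levels = types12))
  tab12 <- data.frame(type = names(t12), n = as.integer(t12),
                      stringsAsFactors = FALSE)
  if (!is.null(nt_by_base)) {
    tab12$denominator <- nt_by_base[substr(tab12$type, 1, 1)]
    tab12$frequency <- tab12$n / tab12$denominator
  }
  types6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  t6 <- table(factor(records$type_collapsed, levels = types6))
  n_ti <- sum(records$transition)
  n_tv <- sum(!records$transition)
  ctga <- records[records$type %in% c("C>T", "G>A"), , drop = FALSE]
  cpg_split <- data.frame(
    context = c("CpG", "non-CpG"),
    n = c(sum(ctga$cpg), sum(!ctga$cpg)))
  contexts <- table(records$type_collapsed, records$context_collapsed)
  list(types12 = tab12,
       types6 = data.frame(type = names(t6), n = as.integer(t6),
                           stringsAsFactors = FALSE),
       titv = if (n_tv > 0) n_ti / n_tv else NA_real_,
       cpg_split = cpg_split, contexts = contexts)
}

#' Monte-Carlo chi-squared comparison of two mutation spectra
#'
#' Pearson's chi-squared test of independence between spectrum and group,
#' with the p-value obtained by Monte-Carlo simulation (the small expected
#' counts typical of mutation spectra violate the asymptotic approximation).
#'
#' @param types_a,types_b Character vectors of (collapsed or directed)
#'   mutation types, or context labels, for the two groups.
#' @param B Number of Monte-Carlo replicates (default 2000).
#' @return List with `p` and the contingency `table`.
#' @export
compare_spectra <- function(types_a, types_b, B = 2000) {
  lev <- sort(unique(c(types_a, types_b)))
  tab <- rbind(a = table(factor(types_a, levels = lev)),
               b = table(factor(types_b, levels = lev)))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L || any(rowSums(tab) == 0))
    return(list(p = 1, table = tab))
  ct <- stats::chisq.test(tab, simulate.p.value = TRUE, B = B)
  list(p = ct$p.value, table = tab)
}
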