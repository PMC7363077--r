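# Frequency arithmetic and the statistical battery against independent
# enumeration / CDF-inversion oracles.

test_that("mutation frequency reproduces the worked denominator example", {
  # 465 mutations over 16,300 bp x summed mean depth = 1,061,353,310 bp
  f <- mutation_frequency(465, denominator = 1061353310)
  expect_equal(f, 465 / 1061353310)
  expect_equal(signif(f, 4), 4.381e-07)
  expect_equal(mutation_frequency(0, 16300, 1000), 0)
  # doubling the denominator halves the frequency
  expect_equal(mutation_frequency(10, denominator = 2e6),
               mutation_frequency(10, denominator = 1e6) / 2)
  expect_error(mutation_frequency(5, 0, 0))
})

test_that("median-based fold changes reproduce study-style rounding", {
  expect_equal(fold_change(1.2e-6, 4.7e-7), 2.6)
  expect_equal(fold_change(3.5e-7, 2.4e-7), 1.5)
  expect_equal(fold_change(1.0e-6, 3.9e-7), 2.6)
})

test_that("Poisson intervals match a CDF-inversion root-finding oracle", {
  # oracle: lower solves P(X >= x | mu) = alpha/2, upper solves
  # P(X <= x | mu) = alpha/2, found by uniroot on the Poisson CDF
  oracle <- function(x, level = 0.95) {
    a <- (1 - level) / 2
    lo <- if (x == 0) 0 else
      stats::uniroot(function(mu) 1 - ppois(x - 1, mu) - a,
                     c(1e-12, 10 * x + 10), tol = 1e-10)$root
    hi <- stats::uniroot(function(mu) ppois(x, mu) - a,
                         c(1e-12, 10 * x + 20), tol = 1e-10)$root
    c(lo, hi)
  }
  for (x in c(0L, 1L, 5L, 100L)) {
    ci <- poisson_ci(x, 1)
    ex <- oracle(x)
    expect_equal(ci$lower, ex[1], tolerance = 1e-6)
    expect_equal(ci$upper, ex[2], tolerance = 1e-6)
    expect_true(ci$lower <= x && x <= ci$upper)
  }
  # width shrinks with the count at fixed frequency
  w <- function(x, d) { ci <- poisson_ci(x, d); ci$upper - ci$lower }
  expect_gt(w(10, 1e4), w(100, 1e5))
  expect_gt(w(100, 1e5), w(1000, 1e6))
})

test_that("Fisher comparison equals hypergeometric enumeration on small tables", {
  # oracle: sum the probabilities of all tables (fixed margins) no more
  # likely than the observed one
  oracle_p <- function(n1, d1, n2, d2) {
    k <- n1 + n2
    support <- max(0, k - d2):min(k, d1)
    probs <- dhyper(support, d1, d2, k)
    sum(probs[probs <= dhyper(n1, d1, d2, k) * (1 + 1e-7)])
  }
  set.seed(9)
  for (i in 1:50) {
    d1 <- sample(5:30, 1); d2 <- sample(5:30, 1)
    n1 <- sample(0:d1, 1); n2 <- sample(0:d2, 1)
    fc <- fisher_compare(n1, d1, n2, d2)
    expect_equal(fc$p, oracle_p(n1, d1, n2, d2), tolerance = 1e-10,
                 label = sprintf("table %d/%d vs %d/%d", n1, d1, n2, d2))
  }
  sym <- fisher_compare(5, 10, 5, 10)
  expect_equal(sym$p, 1)
  expect_equal(fisher_compare(10, 100, 5, 100)$fold, 2)
})

test_that("observed-vs-expected binomial test matches direct tail summation", {
  p <- 877 / 16300
  direct <- sum(dbinom(10:50, 50, p))
  out <- observed_expected_binomial(10, 50, 877, 16300, "greater")
  expect_equal(out$p, direct, tolerance = 1e-12)
  expect_equal(out$expected, 50 * p)
  expect_equal(observed_expected_binomial(0, 50, 877, 16300, "greater")$p, 1)
  even <- observed_expected_binomial(5, 10, 8150, 16300, "two.sided")
  expect_gt(even$p, 0.95)
})

test_that("permutation test enumerates exhaustively and saturates correctly", {
  # two singleton groups: both arrangements give stat >= observed (-1)
  out <- permutation_median_test(1, 2, alternative = "a_greater")
  expect_identical(out$method, "exhaustive")
  expect_equal(out$p, 1)
  expect_equal(permutation_median_test(1, 2, alternative = "b_greater")$p, 0.5)
  # identical groups: upper tail saturates
  expect_gt(permutation_median_test(rep(2, 4), rep(2, 4))$p, 0.99)
  # exhaustive and Monte-Carlo agree within 3 MC standard errors
  set.seed(10)
  a <- rnorm(5, 1); b <- rnorm(5)
  ex <- permutation_median_test(a, b, n_perm = 1e6)   # 252 arrangements
  expect_identical(ex$method, "exhaustive")
  mc <- permutation_median_test(a, b, n_perm = 200)
  expect_identical(mc$method, "monte-carlo")
  se <- sqrt(ex$p * (1 - ex$p) / 200)
  expect_lt(abs(mc$p - ex$p), 3 * se + 1 / 200)
})

test_that("FDR adjustment follows the Benjamini-Yekutieli step-up rule", {
  # m = 3, c(3) = 1 + 1/2 + 1/3 = 11/6; all three adjust to 0.055
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03), "BY"),
               rep(0.055, 3), tolerance = 1e-12)
  expect_equal(adjust_fdr(0.42, "BH"), 0.42)
  set.seed(11)
  p <- runif(20)
  adj <- adjust_fdr(p, "BY")
  # step-up adjusted values are monotone in the sorted order
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p))
})

test_that("aggregation sums numerators and denominators, never frequencies", {
  samples <- make_samples(
    sample_id = c("a", "b"), individual = c("a", "b"), pedigree = "G",
    generation = "pup", tissue = "brain", mean_dcs_depth = c(100, 300))
  records <- data.frame(sample_id = c("a", "a", "b"), pos = 1:3, ref = "A",
                        alt = "G", stringsAsFactors = FALSE)
  tab <- frequency_table(records, samples, region_length = 1000,
                         by = c("generation", "tissue"))
  expect_equal(tab$n_mutations, 3)
  expect_equal(tab$denominator, 1000 * 400)
  expect_equal(tab$frequency, 3 / 4e5)
  # invariant to sample processing order
  tab2 <- frequency_table(records[c(3, 1, 2), ], samples[2:1, ], 1000,
                          by = c("generation", "tissue"))
  expect_equal(tab2$frequency, tab$frequency)
})

test_that("strand bias uses type-specific denominators and recovers planted excess", {
  # equal base content, 5x G>A excess over C>T
  nt <- c(A = 1e6, C = 1e6, G = 1e6, T = 1e6)
  records <- data.frame(
    type = c(rep("G>A", 500), rep("C>T", 100)), stringsAsFactors = FALSE)
  tab <- strand_bias_table(records, nt)
  ga <- tab[tab$type1 == "G>A", ]
  expect_equal(ga$fold, 5)
  expect_equal(ga$odds_ratio, 5, tolerance = 0.15)
  expect_lt(ga$p, 1e-10)
  expect_equal(ga$denom1, 1e6)
  # unequal base content changes the denominators, not the counts
  nt2 <- c(A = 1e6, C = 2e6, G = 5e5, T = 1e6)
  tab2 <- strand_bias_table(records, nt2)
  expect_equal(tab2[tab2$type1 == "G>A", "denom1"], 5e5)
  expect_equal(tab2[tab2$type1 == "G>A", "denom2"], 2e6)
})

test_that("spectrum summaries tally types, Ti/Tv and strand-collapsed contexts", {
  records <- data.frame(
    ref     = c(rep("G", 5), rep("C", 3), "A", "T"),
    alt     = c(rep("A", 5), rep("T", 3), "C", "A"),
    stringsAsFactors = FALSE)
  records$type <- paste0(records$ref, ">", records$alt)
  ti <- c("A>G", "G>A", "C>T", "T>C")
  records$transition <- records$type %in% ti
  records$cpg <- FALSE
  coll <- collapse_substitution(records$ref, records$alt,
                                rep("TGT", nrow(records)))
  records$type_collapsed <- coll$type
  records$context_collapsed <- coll$context
  sp <- spectrum_tables(records)
  expect_equal(sp$titv, 8 / 2)
  # G>A collapses onto C>T
  expect_equal(sp$types6$n[sp$types6$type == "C>T"], 8L)
  # G>T at TGT is tallied as C>A at ACA
  one <- collapse_substitution("G", "T", "TGT")
  expect_equal(one$type, "C>A"); expect_equal(one$context, "ACA")
  # identical spectra: Monte-Carlo chi-squared p is ~1
  set.seed(12)
  types <- sample(c("C>T", "T>C", "C>A"), 60, TRUE)
  expect_gt(compare_spectra(types, types)$p, 0.5)
})

test_that("sequenced-nt denominators follow base content and compartment", {
  g <- toy_genome()
  nt <- sequenced_nt_by_base(g, depth_sum = 100)
  chars <- strsplit(g$sequence, "")[[1]]
  expect_equal(unname(nt["C"]), sum(chars == "C") * 100)
  expect_equal(sum(nt), g$length * 100)
  ntd <- sequenced_nt_by_base(g, 100, "D-loop")
  ntn <- sequenced_nt_by_base(g, 100, "non-D-loop")
  expect_equal(sum(ntd) + sum(ntn), g$length * 100)
  expect_equal(sum(ntd), 150 * 100)  # toy D-loop is 150 bp
})
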