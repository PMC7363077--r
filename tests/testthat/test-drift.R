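# Heteroplasmy drift: sharing categories, correlations, normalized variance
# and the bottleneck estimator.

test_that("normalized variance follows the hand-computed definition", {
  expect_equal(normalized_variance(c(0.1, 0.3), p = 0.2), 0.0625)
  expect_equal(normalized_variance(c(0.2, 0.2, 0.2), p = 0.2), 0)
  expect_error(normalized_variance(c(0.1), p = 0.1))
  expect_error(normalized_variance(c(0.1, 0.2), p = 0))
})

test_that("MAF correlation matches the covariance formula and is symmetric", {
  x <- c(0.01, 0.05, 0.20, 0.32)
  y <- c(0.02, 0.04, 0.18, 0.35)
  byhand <- (sum((x - mean(x)) * (y - mean(y))) /
               sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  expect_equal(maf_correlation(x, y), byhand)
  expect_equal(maf_correlation(x, y), maf_correlation(y, x))
  expect_equal(maf_correlation(x, x), 1)
  set.seed(31)
  big <- runif(2000); noise <- runif(2000)
  expect_lt(maf_correlation(big, noise), 0.01)
})

test_that("N_ij and the point estimate follow the estimator formula", {
  # p = 0.5, offspring {0.4, 0.6}: sigma2 = 0.01, N_ij = 0.25/0.01 = 25
  e1 <- data.frame(individual = "i1", site = 1L, p_parent = 0.5,
                   p_offspring = c(0.4, 0.6))
  # engineered second entry with N_ij = 75
  dev <- sqrt(0.25 / 75)
  e2 <- data.frame(individual = "i2", site = 1L, p_parent = 0.5,
                   p_offspring = c(0.5 - dev, 0.5 + dev))
  res <- bottleneck_estimate(rbind(e1, e2), n_boot = 100)
  expect_equal(sort(res$entries$n_ij), c(25, 75), tolerance = 1e-9)
  expect_equal(res$n, 50, tolerance = 1e-9)
  expect_true(res$ci[1] <= res$ci[2])
})

test_that("degenerate entries are excluded with a warning, not divided by", {
  ok <- data.frame(individual = "a", site = 1L, p_parent = 0.5,
                   p_offspring = c(0.4, 0.6))
  zero_var <- data.frame(individual = "b", site = 1L, p_parent = 0.5,
                         p_offspring = c(0.5, 0.5))
  boundary <- data.frame(individual = "c", site = 1L, p_parent = 0,
                         p_offspring = c(0, 0.1))
  expect_warning(res <- bottleneck_estimate(rbind(ok, zero_var, boundary),
                                            n_boot = 50), "excluded")
  expect_equal(res$n_entries, 1L)
  expect_equal(res$n_excluded, 2L)
  expect_equal(res$n, 25)
})

test_that("sharing categories reflect pedigree presence patterns", {
  samples <- make_samples(
    sample_id = c("m1.brain", "m2.brain", "p1.brain", "p2.brain"),
    individual = c("m1", "m2", "p1", "p2"), pedigree = "G1",
    generation = c("mother", "mother", "pup", "pup"), tissue = "brain")
  calls <- data.frame(
    sample_id = c("p1.brain",
                  "m1.brain", "p1.brain",
                  "m1.brain", "m2.brain", "p1.brain", "p2.brain"),
    pos = c(10L, 20L, 20L, 30L, 30L, 30L, 30L),
    ref = "A", alt = "G", dcs_count = 10L, dcs_depth = 1000L,
    sscs_count = 30L, sscs_depth = 3000L, stringsAsFactors = FALSE)
  het <- heteroplasmy_table(calls, samples, sites = c(10L, 20L, 30L))
  out <- categorize_sharing(het)
  cat_of <- function(s) out$sites$category[out$sites$site == s]
  expect_identical(cat_of(10L), "pup_only")
  expect_identical(cat_of(20L), "mother_and_pups")
  expect_identical(cat_of(30L), "several_mothers")
})

test_that("the heteroplasmy table picks the right MAF source per sample", {
  samples <- make_samples(sample_id = "s1", individual = "i1",
                          pedigree = "G", generation = "pup",
                          tissue = "brain")
  calls <- data.frame(sample_id = "s1", pos = c(5L, 6L), ref = "A",
                      alt = "G", dcs_count = c(12L, 3L),
                      dcs_depth = 1000L, sscs_count = c(36L, 10L),
                      sscs_depth = 3000L, stringsAsFactors = FALSE)
  het <- heteroplasmy_table(calls, samples, sites = c(5L, 6L, 7L))
  expect_equal(het$maf[het$site == 5], 12 / 1000)
  expect_identical(het$source[het$site == 5], "DCS")
  expect_equal(het$maf[het$site == 6], 10 / 3000)  # DCS minor depth 3 < 5
  expect_identical(het$source[het$site == 6], "SSCS")
  expect_equal(het$maf[het$site == 7], 0)          # uncalled -> 0
})

test_that("bottleneck estimates order correctly across simulated N", {
  set.seed(33)
  sim_entries <- function(N, nsites = 120, noff = 6) {
    do.call(rbind, lapply(seq_len(nsites), function(i) {
      p <- runif(1, 0.2, 0.8)
      data.frame(individual = paste0("i", i), site = i, p_parent = p,
                 p_offspring = simulate_transmission(p, N, noff))
    }))
  }
  est <- vapply(c(10L, 50L, 200L), function(N)
    suppressWarnings(bottleneck_estimate(sim_entries(N), n_boot = 50)$n),
    numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("normalized variance of binomial drift estimates 1/N at large n", {
  set.seed(34)
  N <- 50L
  nv <- replicate(400, {
    p <- runif(1, 0.25, 0.75)
    normalized_variance(simulate_transmission(p, N, 50), p = p)
  })
  expect_equal(mean(nv), 1 / N, tolerance = 0.1)
})

test_that("drift correlations weaken through the germline bottleneck", {
  g <- synthetic_mt_genome()
  cfg <- sim_config(g, seed = 35, bottleneck_n = 40L,
                    founder_maf_range = c(0.05, 0.3))
  truth <- simulate_pedigree(cfg)
  calls <- simulate_variant_calls(truth)
  het <- heteroplasmy_table(calls, truth$samples, truth$het_sites$site)
  corr <- drift_correlations(het)
  som <- corr$r_squared[corr$comparison == "brain_vs_muscle"]
  oo <- corr$r_squared[corr$comparison == "oocytes_vs_somatic"]
  # somatic tissues track each other tightly; oocytes drift away
  expect_true(all(som > 0.9))
  expect_true(all(oo < som[match(corr$generation[corr$comparison ==
    "oocytes_vs_somatic"], corr$generation[corr$comparison ==
    "brain_vs_muscle"])]))
})

test_that("maternal turnover rounds increase oocyte drift in mothers", {
  g <- synthetic_mt_genome()
  cfg <- sim_config(g, seed = 36, bottleneck_n = 60L,
                    mother_turnover_rounds = 3L,
                    founder_maf_range = c(0.05, 0.3))
  truth <- simulate_pedigree(cfg)
  calls <- simulate_variant_calls(truth)
  het <- heteroplasmy_table(calls, truth$samples, truth$het_sites$site)
  nv <- normalized_variance_table(het, "oocytes")
  med <- tapply(nv$normalized_variance, nv$generation, median)
  expect_gt(med[["mother"]], med[["pup"]])
})
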