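# Nei-Gojobori site counting, coding-effect classification and the hN/hS
# bootstrap neutrality test.

test_that("per-codon site fractions match enumeration under the mito code", {
  # TTT (Phe): only the third-position T>C change is synonymous -> 1/3
  expect_equal(ng_sites("TTT")$syn_sites, 1 / 3, tolerance = 1e-12)
  expect_equal(ng_sites("TTT")$nonsyn_sites, 8 / 3, tolerance = 1e-12)
  # conservation: every codon contributes exactly 3 sites
  for (cd in mtduplex:::all_codons()) {
    ng <- suppressWarnings(ng_sites(cd, warn_internal_stops = FALSE))
    expect_equal(ng$syn_sites + ng$nonsyn_sites, 3, tolerance = 1e-12)
  }
  expect_error(ng_sites("TTTA"), "divisible")
})

test_that("CDS site totals match a brute-force per-substitution oracle", {
  set.seed(21)
  code <- Biostrings::getGeneticCode("2")
  # independent oracle: count synonymous single-base substitutions over the
  # whole CDS, one ninth of a codon's substitutions per site fraction
  oracle <- function(cds) {
    syn <- 0
    for (i in seq(1, nchar(cds), 3)) {
      cd <- substr(cds, i, i + 2)
      for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                       substr(cd, p, p))) {
        alt <- cd; substr(alt, p, p) <- b
        if (code[[alt]] == code[[cd]]) syn <- syn + 1
      }
    }
    syn / 3
  }
  for (rep in 1:5) {
    pool <- setdiff(mtduplex:::all_codons(), c("TAA", "TAG", "AGA", "AGG"))
    cds <- paste(sample(pool, 30, TRUE), collapse = "")
    expect_equal(ng_sites(cds)$syn_sites, oracle(cds), tolerance = 1e-9)
  }
})

test_that("coding mutations are classified by before/after translation", {
  g <- toy_genome()
  cds <- g$features[g$features$name == "geneA", ]
  # geneA starts with ATG on the L strand: disrupt the start codon
  expect_identical(classify_coding_mutation(g, cds$start, "C"), "start_lost")
  # the terminal TAA stop: first position T>C gives CAA (Gln) -> stop_lost
  expect_identical(classify_coding_mutation(g, cds$end - 2L, "C"),
                   "stop_lost")
  # exhaustive cross-check of the effect table against direct translation
  et <- mtduplex:::get_effect_table(g)
  code <- Biostrings::getGeneticCode("2")
  set.seed(22)
  idx <- sample(nrow(et), 200)
  for (i in idx) {
    if (!et$gene[i] %in% c("geneA", "geneB")) next
    f <- g$features[g$features$name == et$gene[i], ]
    fwd <- f$strand == "L"
    coding <- substr(g$sequence, f$start, f$end)
    if (!fwd) coding <- revcomp(coding)
    k <- if (fwd) et$pos[i] - f$start + 1L else f$end - et$pos[i] + 1L
    mutated <- coding
    substr(mutated, k, k) <- if (fwd) et$alt[i] else
      chartr("ACGT", "TGCA", et$alt[i])
    ci <- (k - 1L) %/% 3L
    aa0 <- code[[substr(coding, 3 * ci + 1, 3 * ci + 3)]]
    aa1 <- code[[substr(mutated, 3 * ci + 1, 3 * ci + 3)]]
    expected <- if (ci == 0L && substr(coding, 1, 3) %in% c("ATG", "ATA") &&
                    !substr(mutated, 1, 3) %in% c("ATG", "ATA")) "start_lost"
    else if (aa0 != "*" && aa1 == "*") "stop_gained"
    else if (aa0 == "*" && aa1 != "*") "stop_lost"
    else if (aa0 == aa1) "synonymous" else "nonsynonymous"
    expect_identical(et$effect[i], expected,
                     label = paste("pos", et$pos[i], "alt", et$alt[i]))
  }
})

test_that("hN/hS handles degenerate inputs and ignores record order", {
  g <- toy_genome()
  et <- mtduplex:::get_effect_table(g)
  syn <- et[et$effect == "synonymous", ][1:6, ]
  res <- hn_hs(data.frame(pos = syn$pos, ref = syn$ref, alt = syn$alt),
               g, n_boot = 50)
  expect_equal(res$hn, 0)
  expect_equal(res$ratio, 0)
  # order invariance and duplicate-site collapse
  set.seed(23)
  mix <- et[sample(nrow(et), 40), ]
  rec <- data.frame(pos = mix$pos, ref = mix$ref, alt = mix$alt)
  set.seed(1); r1 <- hn_hs(rec, g, n_boot = 20)
  set.seed(1); r2 <- hn_hs(rec[rev(seq_len(nrow(rec))), ], g, n_boot = 20)
  set.seed(1); r3 <- hn_hs(rbind(rec, rec[1:5, ]), g, n_boot = 20)
  expect_equal(r1$ratio, r2$ratio)
  expect_equal(r1$ratio, r3$ratio)
  # a non-coding record is rejected
  dloop_pos <- which(g$compartment == "D-loop")[1]
  expect_error(hn_hs(data.frame(pos = dloop_pos, ref = "A", alt = "G"), g),
               "not coding")
})

test_that("uniform neutral placement is centred on ratio 1", {
  # Nei-Gojobori site counts assume every coding substitution is equally
  # likely; drawing mutations uniformly over (site, alt) pairs is therefore
  # the process under which hN/hS has neutral expectation exactly 1.  (A
  # biased spectrum shifts the neutral ratio away from 1, which is why the
  # bootstrap null is generated from the observed spectrum instead.)
  g <- synthetic_mt_genome()
  et <- mtduplex:::get_effect_table(g)
  set.seed(24)
  draw_uniform <- function(n) {
    idx <- sample.int(nrow(et), n, replace = TRUE)
    data.frame(pos = et$pos[idx], ref = et$ref[idx], alt = et$alt[idx])
  }
  ratios <- replicate(60, hn_hs(draw_uniform(250), g, n_boot = 2)$ratio)
  expect_equal(mean(ratios), 1, tolerance = 0.08)
})

test_that("transition-biased spectra depress the naive neutral ratio below 1", {
  # sanity check of the rationale above: under the study-like transition-
  # heavy spectrum, neutral placement gives hN/hS well below 1, so the
  # spectrum-matched bootstrap null (not the constant 1) is the correct
  # reference
  g <- synthetic_mt_genome()
  et <- mtduplex:::get_effect_table(g)
  spec <- default_spectrum()
  set.seed(25)
  draw_spec <- function(n) {
    types <- sample(names(spec), n, TRUE, prob = spec)
    idx <- vapply(types, function(t) {
      cand <- which(et$type == t)
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    data.frame(pos = et$pos[idx], ref = et$ref[idx], alt = et$alt[idx])
  }
  ratios <- replicate(30, hn_hs(draw_spec(250), g, n_boot = 2)$ratio)
  expect_lt(mean(ratios), 0.9)
  null_mean <- mean(hn_hs(draw_spec(250), g, n_boot = 200)$null_ratios)
  expect_equal(null_mean, mean(ratios), tolerance = 0.12)
})
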