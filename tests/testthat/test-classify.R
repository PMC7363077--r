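# Classification of variants into de novo / early somatic / inherited and
# the exclusion filters.

fixture_samples <- function() {
  make_samples(
    sample_id = c("m1.brain", "m1.muscle", "m1.oo1", "m1.pool",
                  "p1.brain", "p1.muscle", "p1.oo1",
                  "p2.brain", "p2.muscle"),
    individual = c("m1", "m1", "m1", "m1", "p1", "p1", "p1", "p2", "p2"),
    pedigree = "G1",
    generation = c(rep("mother", 4), rep("pup", 3), "pup", "pup"),
    tissue = c("brain", "muscle", "single_oocyte", "oocyte_pool",
               "brain", "muscle", "single_oocyte", "brain", "muscle"),
    fragmentation = c("covaris", "covaris", "enzymatic", "covaris",
                      "covaris", "covaris", "enzymatic", "covaris",
                      "covaris"))
}

mk_calls <- function(sample_id, pos, ref = "A", alt = "G", dcs = 1L) {
  data.frame(sample_id = sample_id, pos = pos, ref = ref, alt = alt,
             dcs_count = dcs, dcs_depth = 1000L, sscs_count = dcs * 3L,
             sscs_depth = 3000L, stringsAsFactors = FALSE)
}

test_that("presence patterns map to the documented classes", {
  samples <- fixture_samples()
  calls <- rbind(
    # pup p1: brain+muscle+oocyte, absent from mother -> inherited
    mk_calls(c("p1.brain", "p1.muscle", "p1.oo1"), 100L),
    # p2: both somatic tissues only, but p2 has no germline samples ->
    # stays a de novo candidate (early somatic requires assayed oocytes)
    mk_calls(c("p2.brain", "p2.muscle"), 200L),
    # m1: both somatic tissues, oocytes assayed and clean -> early somatic
    mk_calls(c("m1.brain", "m1.muscle"), 300L),
    # single tissue -> de novo candidate
    mk_calls("p1.brain", 400L),
    # two generations of the pedigree -> inherited
    mk_calls(c("m1.brain", "p1.brain"), 500L))
  out <- classify_variants(calls, samples)
  cls <- function(p) unique(out$class[out$pos == p])
  expect_identical(cls(100L), "inherited")
  expect_identical(cls(200L), "de_novo_tissue_specific")
  expect_identical(cls(300L), "early_somatic")
  expect_identical(cls(400L), "de_novo_tissue_specific")
  expect_identical(cls(500L), "inherited")
  # every call got exactly one class
  expect_equal(nrow(out), nrow(calls))
  expect_false(any(is.na(out$class)))
})

test_that("a sample without metadata is a hard error", {
  samples <- fixture_samples()
  expect_error(classify_variants(mk_calls("ghost.brain", 1L), samples),
               "without metadata")
})

test_that("recurrence is keyed on site and allele with the >3 rule", {
  # unrelated single-tissue pup samples, so no inheritance or early-somatic
  # pattern interferes with the recurrence rule
  samples <- make_samples(
    sample_id = paste0("p", 1:5, ".brain"),
    individual = paste0("p", 1:5), pedigree = rep(c("G1", "G2"), c(3, 2)),
    generation = "pup", tissue = "brain")
  four <- mk_calls(paste0("p", 1:4, ".brain"), 50L)
  three <- mk_calls(paste0("p", 1:3, ".brain"), 60L)
  # same site, different allele: independent events
  other_alt <- mk_calls("p5.brain", 50L, alt = "T")
  out <- classify_variants(rbind(four, three, other_alt), samples)
  out$type <- paste0(out$ref, ">", out$alt)
  out <- filter_recurrent(out)
  expect_true(all(out$class[out$pos == 50L & out$alt == "G"] ==
                    "excluded_recurrent"))
  expect_true(all(out$class[out$pos == 60L] == "de_novo_tissue_specific"))
  expect_identical(out$class[out$pos == 50L & out$alt == "T"],
                   "de_novo_tissue_specific")
})

test_that("multi-molecule observations collapse to single events", {
  samples <- fixture_samples()
  calls <- rbind(mk_calls("p1.brain", 10L, dcs = 5L),
                 mk_calls("p1.brain", 20L, dcs = 1L),
                 mk_calls("p1.brain", 30L, alt = "C"),
                 mk_calls("p1.brain", 30L, alt = "T"))
  out <- collapse_multimolecule(classify_variants(calls, samples))
  expect_equal(out$event_count, rep(1L, 4))
  expect_equal(out$n_supporting_dcs[out$pos == 10L], 5L)
  # two different alts at one site are two events
  expect_equal(sum(out$pos == 30L), 2L)
})

test_that("fragmentation artifacts are excluded only in enzymatic samples", {
  samples <- fixture_samples()
  calls <- rbind(mk_calls("m1.oo1", 10L, ref = "T", alt = "A"),
                 mk_calls("m1.muscle", 20L, ref = "T", alt = "A"),
                 mk_calls("m1.oo1", 30L, ref = "G", alt = "A"))
  out <- classify_variants(calls, samples)
  out$type <- paste0(out$ref, ">", out$alt)
  out <- filter_artifacts(out, samples, exclusion_sites = 30L)
  expect_identical(out$class[out$pos == 10L],
                   "excluded_fragmentation_artifact")
  expect_identical(out$class[out$pos == 20L], "de_novo_tissue_specific")
  expect_identical(out$class[out$pos == 30L], "excluded_listed")
})

test_that("classification partitions the calls and ignores input order", {
  g <- toy_genome()
  cfg <- sim_config(g, seed = 77)
  truth <- simulate_pedigree(cfg)
  calls <- simulate_variant_calls(truth)
  rec1 <- classify_mutations(calls, truth$samples, g)
  shuffled <- calls[sample(nrow(calls)), ]
  rec2 <- classify_mutations(shuffled, truth$samples, g)
  expect_equal(nrow(rec1), nrow(rec2))
  key <- function(r) paste(r$sample_id, r$pos, r$alt)
  expect_setequal(key(rec1), key(rec2))
  m <- match(key(rec1), key(rec2))
  expect_identical(rec1$class, rec2$class[m])
  # partition: one class per call key, all classes valid
  expect_true(all(rec1$class %in% mtduplex:::MUTATION_CLASSES))
  expect_false(anyDuplicated(key(rec1)) > 0)
})

test_that("planted truth is recovered by classification on simulated calls", {
  g <- synthetic_mt_genome()
  cfg <- sim_config(g, seed = 88, artifact_rate = 0)
  truth <- simulate_pedigree(cfg)
  calls <- simulate_variant_calls(truth)
  rec <- classify_mutations(calls, truth$samples, g)
  planted <- paste(truth$denovo$sample_id, truth$denovo$site,
                   truth$denovo$alt)
  got <- paste(rec$sample_id, rec$pos, rec$alt)
  found <- match(planted, got)
  expect_true(all(!is.na(found)))
  cls <- rec$class[found]
  # planted tissue-specific events overwhelmingly classified as such; the
  # remainder are chance recurrence collisions plus true A>T/T>A events in
  # enzymatically fragmented oocytes, which the artifact rule deliberately
  # sacrifices
  expect_gt(mean(cls == "de_novo_tissue_specific"), 0.9)
  expect_true(all(cls %in% c("de_novo_tissue_specific",
                             "excluded_recurrent", "early_somatic",
                             "inherited",
                             "excluded_fragmentation_artifact")))
  at <- cls == "excluded_fragmentation_artifact"
  if (any(at)) {
    t_at <- paste0(truth$denovo$ref, ">", truth$denovo$alt)[at]
    expect_true(all(t_at %in% c("A>T", "T>A")))
  }
  # planted heteroplasmies end up inherited, not de novo
  het <- rec[rec$pos %in% truth$het_sites$site, ]
  expect_gt(mean(het$class == "inherited"), 0.95)
})
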