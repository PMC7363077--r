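# End-to-end orchestration: simulate -> call -> classify -> statistics /
# selection / drift / mixed model, with optional TSV outputs.

#' Run the full analysis on a simulated study
#'
#' Executes the consensus-level pipeline: simulates the pedigrees and
#' planted events, generates per-sample variant calls, classifies them,
#' and runs the frequency, spectrum, selection, drift and mixed-model
#' analyses.  Single-oocyte data are combined per individual in all
#' frequency summaries.  Every stage's result is returned in one report
#' list; with `output_dir` the main tables are also written as TSV files
#' together with a manifest of seed and parameters.
#'
#' @param config A [sim_config()].
#' @param n_perm Permutations for the median tests (default 1e4).
#' @param n_boot Bootstrap resamples for the bottleneck CI (default 1000).
#' @param hn_hs_boot Bootstrap replicates for the hN/hS null (default 100).
#' @param include_glmm Fit the mixed-effects model (default TRUE).
#' @param min_het_maf Minimum maximum-across-samples MAF for a site
#'   classified inherited to enter the drift analyses (default 0.002).
#'   Chance co-occurrence of single-molecule de novo calls at one site can
#'   satisfy the presence-based inherited rule at MAFs far below any real
#'   segregating heteroplasmy; such sites would otherwise dominate the
#'   bottleneck mean through near-zero parent frequencies.
#' @param min_het_samples Minimum number of carrying samples for a drift
#'   site (default 3).
#' @param output_dir Optional directory for TSV outputs.
#' @return A `mt_report` list (see Details in the vignette).
#' @export
run_all <- function(config, n_perm = 1e4, n_boot = 1000L, hn_hs_boot = 100L,
                    include_glmm = TRUE, min_het_maf = 0.002,
                    min_het_samples = 3L, output_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genome <- config$genome
  truth <- simulate_pedigree(config)
  calls <- simulate_variant_calls(truth)
  records <- classify_mutations(calls, truth$samples, genome)
  retained <- records[records$class == "de_novo_tissue_specific", ,
                      drop = FALSE]
  samples <- truth$samples

  freq_units <- analysis_unit_frequencies(retained, samples, genome$length)
  folds <- age_fold_table(freq_units, n_perm = n_perm)
  regions <- region_analysis(retained, samples, genome)
  nt_all <- sequenced_nt_by_base(genome, sum(samples$mean_dcs_depth))
  spectrum <- list(
    mothers = spectrum_tables(
      retained[retained$generation == "mother", , drop = FALSE]),
    pups = spectrum_tables(
      retained[retained$generation == "pup", , drop = FALSE]),
    all = spectrum_tables(retained, nt_all))
  strand_bias <- strand_bias_table(retained, nt_all)

  coding <- retained[retained$compartment == "protein-coding", , drop = FALSE]
  selection <- lapply(stats::setNames(c("mother", "pup"), c("mother", "pup")),
                      function(g) {
    rec <- coding[coding$generation == g, , drop = FALSE]
    if (nrow(rec) < 5L) return(NULL)
    hn_hs(rec, genome, n_boot = hn_hs_boot)
  })

  het_sites <- sort(unique(records$pos[records$class == "inherited"]))
  drift <- NULL
  if (length(het_sites) >= 3L) {
    het <- heteroplasmy_table(calls, samples, het_sites)
    keep <- vapply(split(het$maf, het$site), function(m)
      max(m) >= min_het_maf && sum(m > 0) >= min_het_samples, logical(1))
    het_sites <- as.integer(names(keep)[keep])
    het <- het[het$site %in% het_sites, , drop = FALSE]
  }
  if (length(het_sites) >= 3L) {
    nv_oo <- normalized_variance_table(het, "oocytes")
    nv_som <- normalized_variance_table(het, "somatic")
    nv_test <- function(nv) {
      if (is.null(nv)) return(NULL)
      a <- nv$normalized_variance[nv$generation == "mother"]
      b <- nv$normalized_variance[nv$generation == "pup"]
      if (length(a) < 2L || length(b) < 2L) return(NULL)
      permutation_median_test(a, b, n_perm = n_perm)
    }
    bn <- function(entries) {
      if (is.null(entries) || nrow(entries) < 3L) return(NULL)
      ok <- entries$p_parent > 0 & entries$p_parent < 1
      if (sum(ok) < 3L) return(NULL)
      suppressWarnings(bottleneck_estimate(entries[ok, , drop = FALSE],
                                           n_boot = n_boot))
    }
    drift <- list(
      sharing = categorize_sharing(het),
      correlations = drift_correlations(het),
      normalized_variance = list(
        oocytes = nv_oo, somatic = nv_som,
        test_oocytes = nv_test(nv_oo), test_somatic = nv_test(nv_som)),
      bottleneck = list(
        pup_somatic_vs_oocytes = bn(bottleneck_entries(
          het, comparison = "somatic_vs_oocytes", generation = "pup")),
        mother_somatic_vs_oocytes = bn(bottleneck_entries(
          het, comparison = "somatic_vs_oocytes", generation = "mother")),
        mother_vs_pups = bn(bottleneck_entries(
          het, pedigree = config$pedigree, comparison = "mother_vs_pups"))))
  }

  glmm <- NULL
  if (include_glmm) {
    cells <- build_cells(retained, samples, genome)
    glmm <- fit_glmm(cells)
  }

  report <- structure(
    list(truth = truth, calls = calls, records = records,
         retained = retained, frequencies = freq_units, folds = folds,
         regions = regions, spectrum = spectrum, strand_bias = strand_bias,
         selection = selection, drift = drift, glmm = glmm,
         funnel = classification_funnel(records),
         manifest = list(seed = config$seed, genome = genome$name,
                         genome_length = genome$length,
                         n_samples = nrow(samples), n_perm = n_perm,
                         n_boot = n_boot, timestamp = NULL)),
    class = "mt_report")
  if (!is.null(output_dir)) write_report_tsvs(report, output_dir)
  report
}

# per-analysis-unit frequencies: somatic tissues and oocyte pools per
# sample, single oocytes combined per individual
analysis_unit_frequencies <- function(retained, samples, genome_length) {
  ps <- per_sample_frequency(retained, samples, genome_length)
  ps$unit <- ifelse(ps$tissue == "single_oocyte",
                    paste0(ps$individual, ".single_oocyte"), ps$sample_id)
  agg <- do.call(rbind, lapply(split(ps, ps$unit), function(d)
    data.frame(unit = d$unit[1], individual = d$individual[1],
               generation = d$generation[1], tissue = d$tissue[1],
               n_mutations = sum(d$n_mutations),
               denominator = sum(d$denominator),
               frequency = sum(d$n_mutations) / sum(d$denominator),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg
}

# mother-vs-pup fold changes per tissue: median-based fold with permutation
# p, and aggregate fold (summed counts/denominators) with Fisher p
age_fold_table <- function(freq_units, n_perm = 1e4) {
  out <- lapply(unique(freq_units$tissue), function(tis) {
    d <- freq_units[freq_units$tissue == tis, ]
    fm <- d$frequency[d$generation == "mother"]
    fp <- d$frequency[d$generation == "pup"]
    if (!length(fm) || !length(fp)) return(NULL)
    perm <- permutation_median_test(fm, fp, n_perm = n_perm)
    nm <- sum(d$n_mutations[d$generation == "mother"])
    dm <- sum(d$denominator[d$generation == "mother"])
    np <- sum(d$n_mutations[d$generation == "pup"])
    dp <- sum(d$denominator[d$generation == "pup"])
    fish <- fisher_compare(nm, dm, np, dp)
    data.frame(tissue = tis,
               median_freq_mother = stats::median(fm),
               median_freq_pup = stats::median(fp),
               fold_median = fold_change(stats::median(fm),
                                         stats::median(fp)),
               perm_p = perm$p,
               fold_aggregate = fish$fold, fisher_p = fish$p,
               n_mother = length(fm), n_pup = length(fp),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  tab$perm_p_adj <- adjust_fdr(tab$perm_p, "BY")
  tab$fisher_p_adj <- adjust_fdr(tab$fisher_p, "BY")
  tab
}

# compartment frequency table plus observed-vs-expected binomial tests for
# the D-loop and the coding complement, per age group
region_analysis <- function(retained, samples, genome) {
  sizes <- compartment_sizes(genome)
  out <- list()
  for (g in c("mother", "pup")) {
    rec <- retained[retained$generation == g, , drop = FALSE]
    n_tot <- nrow(rec)
    n_dloop <- sum(rec$compartment == "D-loop")
    coding_comps <- c("protein-coding", "tRNA", "rRNA")
    n_coding <- sum(rec$compartment %in% coding_comps)
    freq <- do.call(rbind, lapply(names(sizes), function(comp)
      data.frame(age_group = g, compartment = comp,
                 length_bp = sizes[[comp]],
                 n_mutations = sum(rec$compartment == comp),
                 frequency = mutation_frequency(
                   sum(rec$compartment == comp), sizes[[comp]],
                   sum(samples$mean_dcs_depth[samples$generation == g])),
                 stringsAsFactors = FALSE)))
    out[[g]] <- list(
      frequencies = freq,
      dloop_test = observed_expected_binomial(
        n_dloop, n_tot, sizes[["D-loop"]], genome$length, "greater"),
      coding_test = observed_expected_binomial(
        n_coding, n_tot, sum(sizes[coding_comps]), genome$length, "less"))
  }
  out
}

# filter funnel: counts per class, the machine-readable account of what was
# removed at each rule
classification_funnel <- function(records) {
  tab <- table(factor(records$class, levels = MUTATION_CLASSES))
  data.frame(class = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' @export
print.mt_report <- function(x, ...) {
  cat("mtduplex report -", x$manifest$n_samples, "samples, genome",
      x$manifest$genome_length, "bp\n\nClassification funnel:\n")
  print(x$funnel, row.names = FALSE)
  cat("\nMother vs pup fold changes:\n")
  print(x$folds[c("tissue", "fold_median", "perm_p_adj", "fold_aggregate",
                  "fisher_p_adj")], row.names = FALSE, digits = 3)
  for (g in names(x$selection)) if (!is.null(x$selection[[g]]))
    cat(sprintf("\nhN/hS (%s): %.2f (p = %.2g)", g, x$selection[[g]]$ratio,
                x$selection[[g]]$p))
  cat("\n")
  if (!is.null(x$drift)) {
    cat("\nHeteroplasmy drift:\n")
    print(x$drift$correlations, row.names = FALSE, digits = 3)
    for (cmp in names(x$drift$bottleneck)) {
      bn <- x$drift$bottleneck[[cmp]]
      if (!is.null(bn)) { cat(sprintf("%-28s", cmp)); print(bn) }
    }
  }
  if (!is.null(x$glmm)) { cat("\n"); print(x$glmm) }
  invisible(x)
}

#' Write the main report tables as TSV files
#'
#' @param report An `mt_report` from [run_all()].
#' @param output_dir Directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_report_tsvs <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    path <- file.path(output_dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  paths <- c(
    wr(report$records, "mutations_classified"),
    wr(report$frequencies, "frequencies_per_unit"),
    wr(report$folds, "age_fold_changes"),
    wr(report$strand_bias, "strand_bias"),
    wr(report$funnel, "filter_funnel"))
  if (!is.null(report$drift)) {
    paths <- c(paths, wr(report$drift$sharing$sites, "heteroplasmy_sharing"),
               wr(report$drift$correlations, "drift_correlations"))
  }
  if (!is.null(report$glmm)) {
    paths <- c(paths, wr(report$glmm$coefficients, "glmm_coefficients"))
    if (!is.null(report$glmm$partial))
      paths <- c(paths, wr(report$glmm$partial, "glmm_partial_r2"))
  }
  manifest <- report$manifest
  manifest_path <- file.path(output_dir, "manifest.txt")
  writeLines(paste(names(manifest),
                   vapply(manifest, function(v)
                     paste(format(v), collapse = " "), character(1)),
                   sep = "\t"), manifest_path)
  invisible(c(paths, manifest_path))
}

#' Build a simulation configuration from a YAML file
#'
#' Reads scalar and list parameters for [sim_config()] from YAML (requires
#' the `yaml` package); the genome is supplied separately.  Unknown keys are
#' an error so typos in config files fail fast.
#'
#' @param path YAML file of `sim_config` parameters.
#' @param genome An [mt_genome].
#' @return A `sim_config`.
#' @export
sim_config_from_yaml <- function(path, genome) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("YAML configuration requires the yaml package")
  pars <- yaml::read_yaml(path)
  known <- setdiff(names(formals(sim_config)), "genome")
  bad <- setdiff(names(pars), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  defaults <- formals(sim_config)
  if (!is.null(pars$mu)) {
    mu <- eval(defaults$mu)
    mu[names(pars$mu)] <- lapply(pars$mu, unlist)
    pars$mu <- mu
  }
  if (!is.null(pars$depth)) {
    depth <- eval(defaults$depth)
    depth[names(pars$depth)] <- unlist(pars$depth)
    pars$depth <- depth
  }
  if (!is.null(pars$spectrum)) pars$spectrum <- unlist(pars$spectrum)
  do.call(sim_config, c(list(genome = genome), pars))
}

#' Run the read-level demonstration pipeline on one sample
#'
#' Emits duplex read families for a sample, runs tag correction, consensus
#' calling and head trimming, places the consensus reads using the sidecar,
#' clips mate overlaps, filters, piles up and calls variants.  Intended for
#' small genomes/depths (the consensus-level path of [run_all()] covers
#' study-scale analyses).
#'
#' @param truth An `mt_truth` from [simulate_pedigree()].
#' @param sample_id One sample to process.
#' @param depth Emission depth override (see [emit_read_families()]).
#' @return List with `consensus`, `alignments`, `site_counts`, `calls`,
#'   `summary`.
#' @export
run_read_pipeline <- function(truth, sample_id, depth = NULL) {
  config <- truth$config
  em <- emit_read_families(truth, sample_id, depth = depth)
  fams <- correct_tags(em$reads[c("id", "seq1", "seq2")],
                       tag_length = config$tag_length,
                       spacer_length = config$spacer_length)
  cons <- call_consensus(fams$families)
  trimmed <- trim_head(cons)
  chunk <- config$read_length - config$tag_length - config$spacer_length
  aln <- align_consensus(trimmed$consensus, em$sidecar, read_chunk = chunk)
  aln <- filter_alignments(clip_overlaps(aln))
  counts <- pileup(aln, truth$genome)
  calls <- call_variants(counts, sample_id = sample_id)
  list(consensus = trimmed$consensus, alignments = aln,
       site_counts = counts, calls = calls,
       summary = family_summary(fams$families, cons))
}
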