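# Synthetic-data generator: two-generation pedigrees, inherited heteroplasmies
# transmitted through a germline bottleneck, age- and tissue-dependent de novo
# mutations, and barcoded duplex read families.
#
# Randomness contract: every simulate_* entry point seeds base R's RNG from
# config$seed (a single documented stream); per-sample substreams for read
# emission are derived as (seed + 104729 * sample_index) mod 2^31 - 1, so a
# single sample can be re-emitted without replaying the others.

#' Default two-pedigree specification
#'
#' Emulates the study design: two independent two-generation pedigrees with
#' four mothers each (one without pups) and 28 pups in total; mothers aged
#' about 10 months, pups about 20 days.  Every animal contributes brain and
#' muscle; mothers contribute 6 single oocytes and an oocyte pool, female
#' pups 2 single oocytes and an oocyte pool.
#'
#' @return `data.frame` with columns `id`, `pedigree`, `generation`
#'   (`"mother"`/`"pup"`), `sex`, `mother_id`, `age_group`,
#'   `n_single_oocytes`, `oocyte_pool_size`.
#' @export
pedigree_spec_default <- function() {
  mk <- function(ped, mothers, pups_per_mother) {
    mo <- data.frame(id = sprintf("%s_M%d", ped, seq_len(mothers)),
                     pedigree = ped, generation = "mother", sex = "F",
                     mother_id = NA_character_, stringsAsFactors = FALSE)
    pu <- do.call(rbind, lapply(seq_along(pups_per_mother), function(i) {
      n <- pups_per_mother[i]
      if (n == 0L) return(NULL)
      data.frame(id = sprintf("%s_M%d_P%d", ped, i, seq_len(n)),
                 pedigree = ped, generation = "pup",
                 sex = rep_len(c("F", "M", "F"), n),
                 mother_id = sprintf("%s_M%d", ped, i),
                 stringsAsFactors = FALSE)
    }))
    rbind(mo, pu)
  }
  ind <- rbind(mk("G126", 4L, c(0L, 4L, 4L, 3L)),
               mk("G129", 4L, c(4L, 4L, 4L, 5L)))
  ind$age_group <- ifelse(ind$generation == "mother", "10mo", "20d")
  female <- ind$sex == "F"
  # females contribute 1-6 single oocytes (deterministic cycle, study-like
  # spread); mothers contribute 6 each
  pup_counts <- rep_len(c(2L, 3L, 1L, 4L, 2L, 3L), sum(female &
                                                         ind$generation == "pup"))
  ind$n_single_oocytes <- 0L
  ind$n_single_oocytes[ind$generation == "mother"] <- 6L
  ind$n_single_oocytes[female & ind$generation == "pup"] <- pup_counts
  ind$oocyte_pool_size <- ifelse(ind$generation == "mother", 20L,
                                 ifelse(female, 8L, 0L))
  ind
}

#' Default 12-type mutation spectrum weights
#'
#' Directed substitution weights relative to the reference (light) strand:
#' transition-dominated, with the G>A over C>T and T>C over A>G strand biases
#' characteristic of mtDNA.  Weights sum to 1.
#' @return Named numeric vector over the 12 directed substitution types.
#' @export
default_spectrum <- function() {
  c("G>A" = 0.31, "T>C" = 0.22, "C>T" = 0.10, "A>G" = 0.08,
    "G>T" = 0.05, "C>A" = 0.04, "A>T" = 0.04, "T>A" = 0.04,
    "A>C" = 0.035, "T>G" = 0.035, "C>G" = 0.025, "G>C" = 0.025)
}

#' Build a simulation configuration
#'
#' Defaults reproduce the study conditions: per-tissue mutation rates equal
#' to the reported median frequencies (mothers' brain 1.2e-6/bp vs pups'
#' 4.7e-7/bp, and so on), median DCS depths of 2,050x, 1,986x, 133x and 932x
#' for brain, muscle, single oocytes and oocyte pools, a 3-fold D-loop rate
#' multiplier, 28 inherited heteroplasmies with founder minor allele
#' frequencies between 0.3% and 30%, a germline bottleneck of 85 segregating
#' units, 12-nt duplex tags with a 5-nt spacer, and tag-family sizes in the
#' 6-12 range.
#'
#' @param genome An [mt_genome].
#' @param seed Integer seed.
#' @param pedigree Pedigree specification (see [pedigree_spec_default()]).
#' @param bottleneck_n Effective number of segregating germline units.
#' @param mother_turnover_rounds Extra binomial drift rounds applied to
#'   oocytes of mothers (mtDNA turnover during meiotic arrest); default 0.
#' @param n_heteroplasmies Number of inherited heteroplasmic sites.
#' @param founder_maf_range Range of founder minor allele frequencies
#'   (log-uniform draw).
#' @param mu Named list of per-tissue mutation rates (per bp), each a vector
#'   `c(mother = , pup = )`.
#' @param depth Named vector of median DCS depths per tissue.
#' @param depth_cv Lognormal coefficient of variation of per-sample depth.
#' @param sscs_depth_factor SSCS depth as a multiple of DCS depth.
#' @param dloop_multiplier D-loop mutation-rate multiplier.
#' @param spectrum 12-type spectrum weights (sum 1).
#' @param individual_rate_sd Log-scale standard deviation of a per-
#'   individual mutation-rate multiplier (lognormal, mean 1), emulating the
#'   minor but real between-animal heterogeneity of mutation loads; 0
#'   disables it.
#' @param multi_molecule_rate Poisson mean of extra supporting molecules per
#'   de novo event (most events are single-molecule).
#' @param early_somatic_rate Poisson mean of early somatic mutations per
#'   individual.
#' @param artifact_rate Per-bp rate of A>T/T>A fragmentation artifacts in
#'   enzymatically fragmented samples.
#' @param tag_length,spacer_length Duplex tag geometry (nt).
#' @param family_size_mean Mean tag-family size per strand.
#' @param read_length Read length (nt) for read emission.
#' @param fragment_mean,fragment_sd Fragment length distribution (nt).
#' @param error_rate Per-base read error rate.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome,
                       seed = 1L,
                       pedigree = pedigree_spec_default(),
                       bottleneck_n = 85L,
                       mother_turnover_rounds = 0L,
                       n_heteroplasmies = 28L,
                       founder_maf_range = c(0.003, 0.30),
                       mu = list(brain = c(mother = 1.2e-6, pup = 4.7e-7),
                                 muscle = c(mother = 1.2e-6, pup = 4.5e-7),
                                 single_oocyte = c(mother = 1.0e-6, pup = 3.9e-7),
                                 oocyte_pool = c(mother = 3.5e-7, pup = 2.4e-7)),
                       depth = c(brain = 2050, muscle = 1986,
                                 single_oocyte = 133, oocyte_pool = 932),
                       depth_cv = 0.15,
                       sscs_depth_factor = 3,
                       dloop_multiplier = 3,
                       individual_rate_sd = 0.15,
                       spectrum = default_spectrum(),
                       multi_molecule_rate = 0.07,
                       early_somatic_rate = 1.5,
                       artifact_rate = 1e-7,
                       tag_length = 12L,
                       spacer_length = 5L,
                       family_size_mean = 8,
                       read_length = 250L,
                       fragment_mean = 300,
                       fragment_sd = 30,
                       error_rate = 0.002) {
  stopifnot(inherits(genome, "mt_genome"),
            bottleneck_n >= 1L,
            all(unlist(mu) >= 0), all(depth > 0),
            abs(sum(spectrum) - 1) < 1e-8, all(spectrum >= 0),
            family_size_mean >= 1,
            error_rate >= 0, artifact_rate >= 0)
  chunk <- read_length - tag_length - spacer_length
  if (chunk < 1L) stop("read_length must exceed tag + spacer length")
  if (fragment_mean >= genome$length)
    stop("fragment length must be below the genome length")
  structure(as.list(environment()), class = "sim_config")
}

#' Binomial bottleneck transmission of a heteroplasmy
#'
#' Each offspring allele frequency is drawn as
#' `Binomial(bottleneck_n, founder_maf) / bottleneck_n`, the single-draw
#' drift model whose across-offspring variance is
#' `founder_maf * (1 - founder_maf) / bottleneck_n`.
#'
#' @param founder_maf Founder allele frequency in `[0, 1]`.
#' @param bottleneck_n Number of segregating units (>= 1).
#' @param n_offspring Number of offspring frequencies to draw.
#' @param rounds Number of successive binomial rounds (default 1; extra
#'   rounds model mtDNA turnover).
#' @return Numeric vector of offspring frequencies (uses the current RNG
#'   stream).
#' @export
simulate_transmission <- function(founder_maf, bottleneck_n, n_offspring,
                                  rounds = 1L) {
  if (founder_maf < 0 || founder_maf > 1) stop("founder_maf must be in [0, 1]")
  stopifnot(bottleneck_n >= 1L, rounds >= 1L)
  f <- rep(founder_maf, n_offspring)
  for (r in seq_len(rounds))
    f <- stats::rbinom(n_offspring, bottleneck_n, f) / bottleneck_n
  f
}

#' Simulate a study: pedigree, heteroplasmies and de novo mutations
#'
#' Places inherited heteroplasmies on founders and transmits them
#' mother-to-pup and individual-to-oocyte through the configured binomial
#' bottleneck (heteroplasmies originate in a pedigree founder, in a single
#' mother, or in a mother's germline only, mirroring the sharing categories
#' observed in two-generation pedigrees).  De novo mutations are drawn per
#' sample as Poisson with mean `mu[tissue, age] * genome length * depth`,
#' positions with the D-loop multiplier and types from the spectrum.  Early
#' somatic mutations (both somatic tissues, absent from the germline) are
#' planted per individual.
#'
#' @param config A [sim_config()].
#' @return A `mt_truth` list: `samples` (sample metadata incl. true mean DCS
#'   depth and fragmentation method), `denovo` (planted tissue-specific
#'   events incl. molecule counts), `early` (planted early somatic events),
#'   `het_sites` (site-level heteroplasmy table) and `het_maf` (per-sample
#'   true minor allele frequencies), plus `genome` and `config`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genome <- config$genome
  ped <- config$pedigree
  samples <- build_samples(config)
  # per-individual mutation-rate multiplier (lognormal, unit mean)
  s <- config$individual_rate_sd
  mult <- stats::setNames(exp(stats::rnorm(nrow(ped), -s^2 / 2, s)), ped$id)
  samples$rate_multiplier <- unname(mult[samples$individual])
  het <- simulate_heteroplasmies(config, ped, samples)
  denovo <- simulate_denovo(config, samples, het$sites$site)
  early <- simulate_early_somatic(config, ped, samples,
                                  c(het$sites$site, denovo$site))
  structure(list(samples = samples, denovo = denovo, early = early,
                 het_sites = het$sites, het_maf = het$maf,
                 genome = genome, config = config),
            class = "mt_truth")
}

build_samples <- function(config) {
  ped <- config$pedigree
  rows <- list()
  add <- function(ind, tissue, idx = NA_integer_) {
    frag <- if (tissue == "single_oocyte") "enzymatic" else "covaris"
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = if (is.na(idx)) paste(ind$id, tissue, sep = ".")
                  else sprintf("%s.%s%d", ind$id, tissue, idx),
      individual = ind$id, pedigree = ind$pedigree,
      generation = ind$generation, age_group = ind$age_group,
      tissue = tissue, oocyte_index = idx, fragmentation = frag,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(ped))) {
    ind <- ped[i, ]
    add(ind, "brain"); add(ind, "muscle")
    if (ind$n_single_oocytes > 0L)
      for (k in seq_len(ind$n_single_oocytes)) add(ind, "single_oocyte", k)
    if (ind$oocyte_pool_size > 0L) add(ind, "oocyte_pool")
  }
  samples <- do.call(rbind, rows)
  med <- config$depth[samples$tissue]
  samples$mean_dcs_depth <-
    round(med * exp(stats::rnorm(nrow(samples), 0, config$depth_cv)))
  samples$mean_sscs_depth <- round(samples$mean_dcs_depth *
                                     config$sscs_depth_factor)
  rownames(samples) <- NULL
  samples
}

# Inherited heteroplasmies: site table plus per-sample true MAF matrix.
simulate_heteroplasmies <- function(config, ped, samples) {
  genome <- config$genome
  n <- config$n_heteroplasmies
  # sharing-origin mix mirrors the observed 17/7/4 split (pup-only /
  # mother-and-pups / several-mothers)
  origin <- sample(rep(c("mother_germline", "mother", "founder"),
                       round(n * c(17, 7, 4) / 28))[seq_len(n)])
  sites <- sample(genome$length, n)
  ref <- genome_base(genome, sites)
  alt <- vapply(ref, function(r) sample(setdiff(c("A","C","G","T"), r), 1),
                character(1), USE.NAMES = FALSE)
  lo <- log(config$founder_maf_range)
  f0 <- exp(stats::runif(n, lo[1], lo[2]))
  mothers <- ped[ped$generation == "mother", ]
  # individual-level frequencies: somatic (fs) and germline (fg)
  fs <- fg <- matrix(0, nrow(ped), n, dimnames = list(ped$id, NULL))
  for (j in seq_len(n)) {
    host <- sample(mothers$id, 1)
    host_ped <- mothers$pedigree[mothers$id == host]
    if (origin[j] == "founder") {
      sibs <- mothers$id[mothers$pedigree == host_ped]
      fs[sibs, j] <- simulate_transmission(f0[j], config$bottleneck_n,
                                           length(sibs))
      fg[sibs, j] <- fs[sibs, j]
    } else if (origin[j] == "mother") {
      fs[host, j] <- fg[host, j] <- f0[j]
    } else {  # germline of the mother only: low-frequency, somatic-absent
      fg[host, j] <- stats::runif(1, 0.002, 0.05)
    }
    pups <- ped$id[!is.na(ped$mother_id) & ped$mother_id == host |
                     (origin[j] == "founder" & !is.na(ped$mother_id) &
                        ped$mother_id %in% rownames(fg)[fg[, j] > 0])]
    for (p in unique(pups)) {
      src <- fg[ped$mother_id[ped$id == p], j]
      f <- simulate_transmission(src, config$bottleneck_n, 1L)
      fs[p, j] <- fg[p, j] <- f
    }
  }
  # per-sample true MAF: somatic tissues fluctuate tightly around the
  # individual somatic frequency; oocytes pass the bottleneck (mothers with
  # optional extra turnover rounds); pools average their oocytes
  maf <- matrix(0, nrow(samples), n, dimnames = list(samples$sample_id, NULL))
  for (i in seq_len(nrow(samples))) {
    ind <- samples$individual[i]
    gen <- samples$generation[i]
    rounds <- 1L + if (gen == "mother") config$mother_turnover_rounds else 0L
    for (j in seq_len(n)) {
      if (samples$tissue[i] %in% c("brain", "muscle")) {
        f <- fs[ind, j]
        maf[i, j] <- if (f > 0) stats::rbinom(1, 5000L, f) / 5000 else 0
      } else if (samples$tissue[i] == "single_oocyte") {
        f <- fg[ind, j]
        maf[i, j] <- if (f > 0)
          simulate_transmission(f, config$bottleneck_n, 1L, rounds) else 0
      } else {  # oocyte pool
        f <- fg[ind, j]
        k <- max(1L, config$pedigree$oocyte_pool_size[
          config$pedigree$id == ind])
        maf[i, j] <- if (f > 0)
          mean(simulate_transmission(f, config$bottleneck_n, k, rounds)) else 0
      }
    }
  }
  list(sites = data.frame(site = sites, ref = ref, alt = alt,
                          origin = origin, founder_maf = f0,
                          stringsAsFactors = FALSE),
       maf = maf)
}

# Position/type sampling machinery shared by de novo and null placements:
# draw a directed type from the spectrum, then a site whose reference base
# matches the type, weighted by the D-loop multiplier.
position_sampler <- function(genome, dloop_multiplier) {
  chars <- strsplit(genome$sequence, "")[[1]]
  w <- ifelse(genome$compartment == "D-loop", dloop_multiplier, 1)
  by_base <- lapply(c(A = "A", C = "C", G = "G", T = "T"), function(b) {
    idx <- which(chars == b)
    list(idx = idx, w = w[idx])
  })
  function(types) {
    refs <- substr(types, 1L, 1L)
    vapply(refs, function(b) {
      bb <- by_base[[b]]
      bb$idx[sample.int(length(bb$idx), 1L, prob = bb$w)]
    }, integer(1), USE.NAMES = FALSE)
  }
}

simulate_denovo <- function(config, samples, reserved_sites) {
  genome <- config$genome
  draw_pos <- position_sampler(genome, config$dloop_multiplier)
  out <- list()
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    rate <- config$mu[[s$tissue]][[if (s$generation == "mother") "mother"
                                   else "pup"]] * s$rate_multiplier
    n <- stats::rpois(1, rate * genome$length * s$mean_dcs_depth)
    n_art <- if (s$fragmentation == "enzymatic")
      stats::rpois(1, config$artifact_rate * genome$length * s$mean_dcs_depth)
    else 0L
    if (n + n_art == 0L) next
    types <- character(0)
    if (n > 0L)
      types <- sample(names(config$spectrum), n, replace = TRUE,
                      prob = config$spectrum)
    if (n_art > 0L)
      types <- c(types, sample(c("A>T", "T>A"), n_art, replace = TRUE))
    pos <- draw_pos(types)
    keep <- !pos %in% reserved_sites
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      sample_id = s$sample_id, site = pos[keep],
      ref = substr(types[keep], 1L, 1L), alt = substr(types[keep], 3L, 3L),
      n_molecules = 1L + stats::rpois(sum(keep), config$multi_molecule_rate),
      artifact = c(rep(FALSE, n), rep(TRUE, n_art))[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(sample_id = character(), site = integer(),
                      ref = character(), alt = character(),
                      n_molecules = integer(), artifact = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

simulate_early_somatic <- function(config, ped, samples, reserved_sites) {
  genome <- config$genome
  out <- list()
  for (id in ped$id) {
    n <- stats::rpois(1, config$early_somatic_rate)
    if (n == 0L) next
    repeat {
      sites <- sample(genome$length, n)
      if (!any(sites %in% reserved_sites)) break
    }
    ref <- genome_base(genome, sites)
    alt <- vapply(ref, function(r) sample(setdiff(c("A","C","G","T"), r), 1),
                  character(1), USE.NAMES = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      individual = id, site = sites, ref = ref, alt = alt,
      maf = stats::runif(n, 0.001, 0.01), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(individual = character(), site = integer(),
                      ref = character(), alt = character(), maf = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Consensus-level variant calls from a simulated truth set
#'
#' Generates the per-sample variant table a duplex pipeline would produce at
#' study scale without emitting individual reads: planted de novo events
#' appear with their molecule counts at the sample's DCS depth, and
#' heteroplasmies and early somatic mutations yield binomially sampled DCS
#' and SSCS allele counts at each sample's depths.
#'
#' @param truth An `mt_truth` from [simulate_pedigree()].
#' @return Variant `data.frame` (sample_id, pos, ref, alt, dcs_count,
#'   dcs_depth, sscs_count, sscs_depth).
#' @export
simulate_variant_calls <- function(truth) {
  config <- truth$config
  set.seed((config$seed + 104729L) %% .Machine$integer.max)
  samples <- truth$samples
  rows <- list()
  push <- function(sample_id, pos, ref, alt, dcs, dcs_depth, sscs, sscs_depth) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sample_id, pos = pos, ref = ref, alt = alt,
      dcs_count = dcs, dcs_depth = dcs_depth,
      sscs_count = sscs, sscs_depth = sscs_depth, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    dD <- s$mean_dcs_depth; dS <- s$mean_sscs_depth
    dn <- truth$denovo[truth$denovo$sample_id == s$sample_id, , drop = FALSE]
    if (nrow(dn))
      push(s$sample_id, dn$site, dn$ref, dn$alt,
           pmin(dn$n_molecules, dD), dD,
           pmin(dn$n_molecules * truth$config$sscs_depth_factor, dS), dS)
    hm <- truth$het_maf[s$sample_id, ]
    hot <- which(hm > 0)
    if (length(hot)) {
      dcs <- stats::rbinom(length(hot), dD, hm[hot])
      sscs <- stats::rbinom(length(hot), dS, hm[hot])
      keep <- dcs > 0L | sscs > 0L
      if (any(keep)) {
        ht <- truth$het_sites[hot[keep], ]
        push(s$sample_id, ht$site, ht$ref, ht$alt, dcs[keep], dD,
             sscs[keep], dS)
      }
    }
    if (s$tissue %in% c("brain", "muscle")) {
      ea <- truth$early[truth$early$individual == s$individual, , drop = FALSE]
      if (nrow(ea)) {
        dcs <- stats::rbinom(nrow(ea), dD, ea$maf)
        sscs <- stats::rbinom(nrow(ea), dS, ea$maf)
        keep <- dcs > 0L
        if (any(keep))
          push(s$sample_id, ea$site[keep], ea$ref[keep], ea$alt[keep],
               dcs[keep], dD, sscs[keep], dS)
      }
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows)
  else data.frame(sample_id = character(), pos = integer(), ref = character(),
                  alt = character(), dcs_count = integer(),
                  dcs_depth = integer(), sscs_count = integer(),
                  sscs_depth = integer(), stringsAsFactors = FALSE)
  calls[calls$dcs_count > 0L | calls$sscs_count > 0L, , drop = FALSE]
}

# ---- read-family emission --------------------------------------------------

random_tags <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A","C","G","T"), len, replace = TRUE), collapse = ""),
    character(1))
}

add_read_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A","C","G","T"), b), 1), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Emit barcoded duplex read families for selected samples
#'
#' For each simulated template molecule, emits paired reads for both template
#' strands: each read is a random tag, the invariant spacer, then fragment
#' sequence with per-base errors.  Family sizes are drawn per strand around
#' the configured mean.  A sidecar table records the true template origin
#' (duplex tag key, start, fragment length) for alignment-free downstream
#' processing.  Planted variants of the sample are embedded in the templates;
#' enzymatically fragmented samples additionally receive template-level
#' (strand-consistent) A>T/T>A artifact molecules.
#'
#' @param truth An `mt_truth` from [simulate_pedigree()].
#' @param sample_ids Samples to emit (default: all).
#' @param depth Mean DCS depth used for template counts; defaults to each
#'   sample's metadata depth (override with a small value for demonstration
#'   runs).
#' @param out_dir Optional directory; when given, paired FASTQ files and the
#'   sidecar TSV are written there.
#' @return List with `reads` (`data.frame`: id, sample_id, seq1, seq2),
#'   `sidecar` (`data.frame`: duplex_key, template_id, sample_id, start,
#'   frag_len) and, if written, `files`.
#' @export
emit_read_families <- function(truth, sample_ids = NULL, depth = NULL,
                               out_dir = NULL) {
  config <- truth$config
  genome <- truth$genome
  samples <- truth$samples
  if (is.null(sample_ids)) sample_ids <- samples$sample_id
  chunk <- config$read_length - config$tag_length - config$spacer_length
  spacer <- paste(rep_len(c("T","G","A","C","T"), config$spacer_length),
                  collapse = "")
  seq2x <- paste0(genome$sequence, genome$sequence)  # circular extraction
  all_reads <- list(); all_sidecar <- list()
  for (sid in sample_ids) {
    i <- match(sid, samples$sample_id)
    if (is.na(i)) stop("unknown sample: ", sid)
    set.seed((config$seed + 104729L * i) %% .Machine$integer.max)
    s <- samples[i, ]
    d <- if (is.null(depth)) s$mean_dcs_depth else depth
    cov_per_template <- min(2L * (chunk - 12L), config$fragment_mean)
    n_templates <- max(1L, round(d * genome$length / cov_per_template))
    start <- sample.int(genome$length, n_templates, replace = TRUE)
    frag_len <- pmax(chunk, pmin(genome$length - 1L,
      round(stats::rnorm(n_templates, config$fragment_mean,
                         config$fragment_sd))))
    frags <- substring(seq2x, start, start + frag_len - 1L)
    # carriers: heteroplasmies by per-template Bernoulli, de novo events on
    # k dedicated covering templates
    hm <- truth$het_maf[sid, ]
    for (j in which(hm > 0)) {
      site <- truth$het_sites$site[j]
      off <- template_offset(site, start, frag_len, genome$length)
      cov <- which(!is.na(off))
      carry <- cov[stats::runif(length(cov)) < hm[j]]
      substr(frags[carry], off[carry], off[carry]) <- truth$het_sites$alt[j]
    }
    dn <- truth$denovo[truth$denovo$sample_id == sid, , drop = FALSE]
    if (s$tissue %in% c("brain", "muscle")) {
      ea <- truth$early[truth$early$individual == s$individual, , drop = FALSE]
      if (nrow(ea)) {
        # early somatic events behave like low-frequency heteroplasmies
        for (r in seq_len(nrow(ea))) {
          off <- template_offset(ea$site[r], start, frag_len, genome$length)
          cov <- which(!is.na(off))
          carry <- cov[stats::runif(length(cov)) < ea$maf[r]]
          substr(frags[carry], off[carry], off[carry]) <- ea$alt[r]
        }
      }
    }
    if (nrow(dn)) {
      trim <- 12L  # planted events must stay visible after head trimming
      for (r in seq_len(nrow(dn))) {
        off <- template_offset(dn$site[r], start, frag_len, genome$length)
        cov <- which(!is.na(off) & off > trim & off <= chunk)
        k <- min(dn$n_molecules[r], length(cov))
        if (k < dn$n_molecules[r]) {
          # add dedicated templates covering the site in the visible window
          extra <- dn$n_molecules[r] - k
          es <- wrap_pos(dn$site[r] - (sample.int(chunk - trim - 1L, extra,
                                                  replace = TRUE) + trim - 1L),
                         genome$length)
          el <- rep(round(config$fragment_mean), extra)
          start <- c(start, es); frag_len <- c(frag_len, el)
          frags <- c(frags, substring(seq2x, es, es + el - 1L))
          off <- template_offset(dn$site[r], start, frag_len, genome$length)
          cov <- which(!is.na(off) & off > trim & off <= chunk)
          k <- dn$n_molecules[r]
        }
        carry <- cov[sample.int(length(cov), k)]
        substr(frags[carry], off[carry], off[carry]) <- dn$alt[r]
      }
    }
    n_templates <- length(start)
    tagA <- random_tags(n_templates, config$tag_length)
    tagB <- random_tags(n_templates, config$tag_length)
    fragL <- substr(frags, 1L, chunk)
    fragR <- substr(revcomp(frags), 1L, chunk)
    reads <- list(); sidecar <- list()
    for (t in seq_len(n_templates)) {
      n_ab <- 1L + stats::rpois(1, config$family_size_mean - 1)
      n_ba <- 1L + stats::rpois(1, config$family_size_mean - 1)
      s1 <- c(paste0(tagA[t], spacer,
                     add_read_errors(rep(fragL[t], n_ab), config$error_rate)),
              paste0(tagB[t], spacer,
                     add_read_errors(rep(fragR[t], n_ba), config$error_rate)))
      s2 <- c(paste0(tagB[t], spacer,
                     add_read_errors(rep(fragR[t], n_ab), config$error_rate)),
              paste0(tagA[t], spacer,
                     add_read_errors(rep(fragL[t], n_ba), config$error_rate)))
      reads[[t]] <- data.frame(
        id = sprintf("%s:t%d:%d", sid, t, seq_len(n_ab + n_ba)),
        sample_id = sid, seq1 = s1, seq2 = s2, stringsAsFactors = FALSE)
      key <- if (tagA[t] <= tagB[t]) paste0(tagA[t], tagB[t])
             else paste0(tagB[t], tagA[t])
      sidecar[[t]] <- data.frame(
        duplex_key = key, template_id = sprintf("%s:t%d", sid, t),
        sample_id = sid, start = start[t], frag_len = frag_len[t],
        tag_top = paste0(tagA[t], tagB[t]), stringsAsFactors = FALSE)
    }
    all_reads[[sid]] <- do.call(rbind, reads)
    all_sidecar[[sid]] <- do.call(rbind, sidecar)
  }
  out <- list(reads = do.call(rbind, all_reads),
              sidecar = do.call(rbind, all_sidecar))
  rownames(out$reads) <- rownames(out$sidecar) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(out_dir, "reads_1.fastq")
    f2 <- file.path(out_dir, "reads_2.fastq")
    fs <- file.path(out_dir, "sidecar.tsv")
    write_fastq(out$reads$id, out$reads$seq1, f1)
    write_fastq(out$reads$id, out$reads$seq2, f2)
    utils::write.table(out$sidecar, fs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$files <- c(fastq1 = f1, fastq2 = f2, sidecar = fs)
  }
  out
}

# 1-based offset of a circular genome site within a template fragment, or NA
# when the fragment does not cover it.
template_offset <- function(site, start, frag_len, genome_len) {
  delta <- (site - start) %% genome_len
  ifelse(delta < frag_len, delta + 1L, NA_integer_)
}

#' Simulate model cells for the mixed-effects frequency model
#'
#' Generates per-individual binomial observations from known fixed-effect
#' log-odds and a normal random intercept, in the cell layout used by
#' [fit_glmm()] (tissue x compartment x mutation-type within individual).
#'
#' @param n_individuals Number of individuals (half assigned to each age
#'   group).
#' @param beta Named list of effect log-odds:
#'   `intercept`, `age_pup`, `tissue` (vector over muscle/single_oocyte/
#'   oocyte_pool), `compartment_non_dloop`, `type` (vector over the two
#'   transition classes).
#' @param re_sd Random-intercept standard deviation.
#' @param nt_total Nucleotide weight per cell (scalar or vector recycled).
#' @return `data.frame` of model cells with true parameters as attributes.
#' @export
simulate_model_cells <- function(n_individuals = 36L,
                                 beta = list(intercept = -13.5,
                                             age_pup = -1.0,
                                             tissue = c(muscle = 0,
                                                        single_oocyte = -0.3,
                                                        oocyte_pool = -0.4),
                                             compartment_non_dloop = -1.0,
                                             type = c("A>G/T>C" = 0.3,
                                                      "C>T/G>A" = 1.0)),
                                 re_sd = 0.3,
                                 nt_total = 2e6) {
  ids <- sprintf("I%02d", seq_len(n_individuals))
  age <- rep(c("mother", "pup"), length.out = n_individuals)
  u <- stats::rnorm(n_individuals, 0, re_sd)
  grid <- expand.grid(individual = ids,
                      tissue = c("brain", "muscle", "single_oocyte",
                                 "oocyte_pool"),
                      compartment = c("D-loop", "non-D-loop"),
                      type = c("transversion", "A>G/T>C", "C>T/G>A"),
                      stringsAsFactors = FALSE)
  grid$age_group <- age[match(grid$individual, ids)]
  eta <- beta$intercept +
    ifelse(grid$age_group == "pup", beta$age_pup, 0) +
    ifelse(grid$tissue == "brain", 0, beta$tissue[grid$tissue]) +
    ifelse(grid$compartment == "non-D-loop", beta$compartment_non_dloop, 0) +
    ifelse(grid$type == "transversion", 0, beta$type[grid$type]) +
    u[match(grid$individual, ids)]
  grid$nt_total <- rep_len(nt_total, nrow(grid))
  grid$n_mutations <- stats::rbinom(nrow(grid), grid$nt_total,
                                    stats::plogis(eta))
  attr(grid, "beta") <- beta
  attr(grid, "re_sd") <- re_sd
  grid
}

#' Write sequences as FASTQ
#'
#' @param ids,seqs Character vectors of record ids and sequences.
#' @param path Output path.
#' @param qual_char Constant base-quality character (default `"I"`, Q40).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(ids, seqs, path, qual_char = "I") {
  quals <- vapply(nchar(seqs), function(n)
    paste(rep(qual_char, n), collapse = ""), character(1))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  invisible(path)
}

#' Read a FASTQ file into read-pair form
#'
#' Reads two mate FASTQ files written by [emit_read_families()] (or any
#' plain 4-line FASTQ pair with matching record order) into the pair table
#' consumed by [correct_tags()].
#'
#' @param fastq1,fastq2 Paths to the two mate files.
#' @return `data.frame` with `id`, `seq1`, `seq2`.
#' @export
read_fastq_pairs <- function(fastq1, fastq2) {
  r1 <- readLines(fastq1); r2 <- readLines(fastq2)
  stopifnot(length(r1) %% 4L == 0L, length(r1) == length(r2))
  idx <- seq(1L, length(r1), by = 4L)
  ids1 <- sub("^@", "", r1[idx])
  ids2 <- sub("^@", "", r2[idx])
  stopifnot(identical(ids1, ids2))
  data.frame(id = ids1, seq1 = r1[idx + 1L], seq2 = r2[idx + 1L],
             stringsAsFactors = FALSE)
}
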