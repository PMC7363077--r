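# Inherited-heteroplasmy analyses: pedigree sharing categories, allele
# frequency correlations, normalized variance, and the effective germline
# bottleneck estimator with bootstrap confidence interval.

#' Long-format heteroplasmy MAF table
#'
#' For a set of inherited heteroplasmic sites, extracts each sample's minor
#' allele frequency with its measurement source: the DCS-level frequency, or
#' the SSCS-level frequency when the DCS minor-allele depth is below 5.
#' Samples without a call at a site get MAF 0.
#'
#' @param calls Variant table (see [call_variants()] /
#'   [simulate_variant_calls()]).
#' @param samples Sample metadata.
#' @param sites Integer vector of heteroplasmic positions.
#' @return `data.frame`: `site`, `sample_id`, `individual`, `generation`,
#'   `pedigree`, `tissue`, `maf`, `source`.
#' @export
heteroplasmy_table <- function(calls, samples, sites) {
  grid <- expand.grid(site = sites, sample_id = samples$sample_id,
                      stringsAsFactors = FALSE)
  idx <- match(paste(grid$sample_id, grid$site),
               paste(calls$sample_id, calls$pos))
  dcs_count <- ifelse(is.na(idx), 0L, calls$dcs_count[idx])
  dcs_depth <- ifelse(is.na(idx), NA, calls$dcs_depth[idx])
  sscs <- ifelse(is.na(idx), NA, calls$sscs_count[idx] / calls$sscs_depth[idx])
  dcs_maf <- ifelse(is.na(idx) | dcs_depth == 0, 0, dcs_count / dcs_depth)
  src <- select_maf_source(dcs_count, dcs_maf, sscs)
  grid$maf <- as_minor_af(ifelse(is.na(idx), 0, src$maf))
  grid$source <- ifelse(is.na(idx), "DCS", src$source)
  si <- match(grid$sample_id, samples$sample_id)
  grid$individual <- samples$individual[si]
  grid$generation <- samples$generation[si]
  grid$pedigree <- samples$pedigree[si]
  grid$tissue <- samples$tissue[si]
  grid
}

#' Pedigree sharing category of heteroplasmic sites
#'
#' Labels each site by its presence pattern: `several_mothers` when two or
#' more mothers of a pedigree carry it, `mother_and_pups` when a mother and
#' at least one pup carry it, and `pup_only` when it is confined to pups.
#' Per-category median MAFs (over carrying samples) are reported.
#'
#' @param het Long MAF table from [heteroplasmy_table()].
#' @param presence_min MAF above which a sample counts as carrying the site
#'   (default 0, i.e. any positive measurement).
#' @return List with `sites` (per-site category) and `category_summary`.
#' @export
categorize_sharing <- function(het, presence_min = 0) {
  per_site <- lapply(split(het, het$site), function(d) {
    carrier <- d$maf > presence_min
    ind <- unique(d$individual[carrier])
    gen <- unique(d$generation[carrier])
    mothers <- unique(d$individual[carrier & d$generation == "mother"])
    cat <- if (length(mothers) >= 2L) "several_mothers"
    else if (length(mothers) == 1L && "pup" %in% gen) "mother_and_pups"
    else "pup_only"
    data.frame(site = d$site[1], category = cat,
               n_individuals = length(ind),
               median_maf = stats::median(d$maf[carrier]),
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, per_site)
  rownames(sites) <- NULL
  summ <- do.call(rbind, lapply(split(sites, sites$category), function(d)
    data.frame(category = d$category[1], n_sites = nrow(d),
               median_maf = stats::median(d$median_maf),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(sites = sites, category_summary = summ)
}

#' Squared Pearson correlation of paired allele frequencies
#'
#' @param x,y Paired MAF vectors (untransformed).
#' @return R-squared.
#' @export
maf_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  stats::cor(x, y)^2
}

#' Normalized variance of allele frequencies
#'
#' Population variance (divide by n) of the values around their mean,
#' normalized by `p * (1 - p)` where `p` is the average allele frequency of
#' the unit (e.g. among single oocytes of a mouse, or between its somatic
#' tissues).  Under pure binomial drift through a bottleneck of N units the
#' expectation is 1/N.
#'
#' @param values Allele frequencies (n >= 2).
#' @param p Average allele frequency in `(0, 1)` (default: `mean(values)`).
#' @return Normalized variance.
#' @export
normalized_variance <- function(values, p = mean(values)) {
  stopifnot(length(values) >= 2, p > 0, p < 1)
  mean((values - mean(values))^2) / (p * (1 - p))
}

#' Effective germline bottleneck size with bootstrap CI
#'
#' For each (individual, site) entry, `N_ij = p_ij (1 - p_ij) / sigma2_ij`
#' where `p_ij` is the parent reference frequency (mean across brain and
#' muscle) and `sigma2_ij` the mean squared deviation of the `n_ij`
#' offspring frequencies (oocytes or pups) from `p_ij` (divide by n).  The
#' point estimate N is the arithmetic mean of the `N_ij`; the confidence
#' interval resamples the `N_ij` values with replacement.  Entries with
#' `p_ij` outside (0, 1) or `sigma2_ij = 0` are excluded and counted.
#'
#' @param entries `data.frame` with columns `individual`, `site`,
#'   `p_parent` and `p_offspring` (one row per offspring measurement).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @return A `bottleneck_result` list: `n` (point estimate), `ci`,
#'   `n_entries`, `n_excluded`, `entries` (per-entry `N_ij` table).
#' @export
bottleneck_estimate <- function(entries, n_boot = 1000L, level = 0.95) {
  per <- lapply(split(entries, paste(entries$individual, entries$site,
                                     sep = "\r")), function(d) {
    p <- d$p_parent[1]
    s2 <- mean((d$p_offspring - p)^2)
    data.frame(individual = d$individual[1], site = d$site[1], p_parent = p,
               n_offspring = nrow(d), sigma2 = s2,
               n_ij = if (p > 0 && p < 1 && s2 > 0)
                 p * (1 - p) / s2 else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  ok <- !is.na(per$n_ij)
  n_excluded <- sum(!ok)
  if (n_excluded)
    warning(n_excluded, " entr(y/ies) excluded (boundary p or zero variance)")
  nij <- per$n_ij[ok]
  if (!length(nij)) stop("no usable entries for the bottleneck estimate")
  boots <- vapply(seq_len(n_boot), function(b)
    mean(sample(nij, replace = TRUE)), numeric(1))
  a <- (1 - level) / 2
  structure(list(n = mean(nij),
                 ci = unname(stats::quantile(boots, c(a, 1 - a))),
                 level = level, n_entries = length(nij),
                 n_excluded = n_excluded, entries = per),
            class = "bottleneck_result")
}

#' @export
print.bottleneck_result <- function(x, ...) {
  cat(sprintf(
    "Effective bottleneck: %.1f segregating units (%d%% CI %.3g-%.3g; %d entries, %d excluded)\n",
    x$n, round(100 * x$level), x$ci[1], x$ci[2], x$n_entries, x$n_excluded))
  invisible(x)
}

#' Build bottleneck comparison entries from a heteroplasmy table
#'
#' Supported comparisons: parent = an individual's somatic mean (brain and
#' muscle), offspring = its single oocytes (`"somatic_vs_oocytes"`, within
#' `generation`); or parent = a mother's somatic mean, offspring = her pups'
#' somatic means (`"mother_vs_pups"`).
#'
#' @param het Long MAF table from [heteroplasmy_table()].
#' @param pedigree Pedigree table (`id`, `mother_id`) for
#'   `"mother_vs_pups"`.
#' @param comparison One of `"somatic_vs_oocytes"`, `"mother_vs_pups"`.
#' @param generation For `"somatic_vs_oocytes"`: `"pup"` or `"mother"`.
#' @return Entries `data.frame` for [bottleneck_estimate()].
#' @export
bottleneck_entries <- function(het, pedigree = NULL,
                               comparison = c("somatic_vs_oocytes",
                                              "mother_vs_pups"),
                               generation = "pup") {
  comparison <- match.arg(comparison)
  som <- het[het$tissue %in% SOMATIC_TISSUES, ]
  som_mean <- stats::aggregate(maf ~ individual + site, som, mean)
  names(som_mean)[3] <- "somatic_mean"
  if (comparison == "somatic_vs_oocytes") {
    oo <- het[het$tissue == "single_oocyte" & het$generation == generation, ]
    m <- merge(oo, som_mean, by = c("individual", "site"))
    data.frame(individual = m$individual, site = m$site,
               p_parent = m$somatic_mean, p_offspring = m$maf,
               stringsAsFactors = FALSE)
  } else {
    stopifnot(!is.null(pedigree))
    pup_mean <- som_mean[som_mean$individual %in%
                           pedigree$id[!is.na(pedigree$mother_id)], ]
    pup_mean$mother <- pedigree$mother_id[match(pup_mean$individual,
                                                pedigree$id)]
    mo_mean <- som_mean
    m <- merge(pup_mean, mo_mean, by.x = c("mother", "site"),
               by.y = c("individual", "site"),
               suffixes = c("_pup", "_mother"))
    data.frame(individual = m$mother, site = m$site,
               p_parent = m$somatic_mean_mother,
               p_offspring = m$somatic_mean_pup, stringsAsFactors = FALSE)
  }
}

#' Somatic and germline MAF correlations by age group
#'
#' Computes, per generation, the R-squared between brain and muscle MAFs
#' across (individual, site) pairs, and between the single-oocyte mean and
#' the somatic mean.  Only (individual, site) pairs where at least one
#' member of the compared pair is positive enter the correlation, and an
#' oocyte restriction (`min_oocytes`) mirrors subsetting to animals with
#' enough oocytes.
#'
#' @param het Long MAF table from [heteroplasmy_table()].
#' @param min_oocytes Minimum single oocytes per individual for the
#'   oocyte-somatic correlation (default 1).
#' @return `data.frame` with `generation`, `comparison`, `r_squared`, `n`.
#' @export
drift_correlations <- function(het, min_oocytes = 1L) {
  out <- list()
  for (gen in c("pup", "mother")) {
    d <- het[het$generation == gen, ]
    br <- d[d$tissue == "brain", c("individual", "site", "maf")]
    mu <- d[d$tissue == "muscle", c("individual", "site", "maf")]
    m <- merge(br, mu, by = c("individual", "site"),
               suffixes = c("_brain", "_muscle"))
    m <- m[m$maf_brain > 0 | m$maf_muscle > 0, ]
    if (nrow(m) >= 3)
      out[[length(out) + 1L]] <- data.frame(
        generation = gen, comparison = "brain_vs_muscle",
        r_squared = maf_correlation(m$maf_brain, m$maf_muscle), n = nrow(m),
        stringsAsFactors = FALSE)
    oo <- d[d$tissue == "single_oocyte", ]
    n_oo <- tapply(oo$sample_id, oo$individual,
                   function(s) length(unique(s)))
    keep_ind <- names(n_oo)[n_oo >= min_oocytes]
    oo_mean <- stats::aggregate(maf ~ individual + site,
                                oo[oo$individual %in% keep_ind, ], mean)
    som <- d[d$tissue %in% SOMATIC_TISSUES, ]
    som_mean <- stats::aggregate(maf ~ individual + site, som, mean)
    m2 <- merge(oo_mean, som_mean, by = c("individual", "site"),
                suffixes = c("_oocyte", "_somatic"))
    m2 <- m2[m2$maf_oocyte > 0 | m2$maf_somatic > 0, ]
    if (nrow(m2) >= 3)
      out[[length(out) + 1L]] <- data.frame(
        generation = gen, comparison = "oocytes_vs_somatic",
        r_squared = maf_correlation(m2$maf_oocyte, m2$maf_somatic),
        n = nrow(m2), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Normalized MAF variance per individual, for drift comparisons
#'
#' For each individual and heteroplasmic site, the normalized variance of
#' the MAF among its single oocytes (`unit = "oocytes"`) or between its two
#' somatic tissues (`unit = "somatic"`), for comparing drift between age
#' groups with a permutation test.
#'
#' @param het Long MAF table.
#' @param unit `"oocytes"` or `"somatic"`.
#' @return `data.frame`: `individual`, `generation`, `site`,
#'   `normalized_variance`.
#' @export
normalized_variance_table <- function(het, unit = c("oocytes", "somatic")) {
  unit <- match.arg(unit)
  d <- if (unit == "oocytes") het[het$tissue == "single_oocyte", ]
  else het[het$tissue %in% SOMATIC_TISSUES, ]
  per <- lapply(split(d, paste(d$individual, d$site, sep = "\r")), function(g) {
    if (nrow(g) < 2L || !any(g$maf > 0)) return(NULL)
    p <- mean(g$maf)
    if (p <= 0 || p >= 1) return(NULL)
    data.frame(individual = g$individual[1], generation = g$generation[1],
               site = g$site[1],
               normalized_variance = normalized_variance(g$maf, p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  if (!is.null(out)) rownames(out) <- NULL
  out
}
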