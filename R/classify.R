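# Classification of variant calls across tissues and pedigree members into
# putative tissue-specific de novo mutations, early somatic mutations and
# inherited heteroplasmies, with the recurrence, fragmentation-artifact and
# exclusion-list filters.

SOMATIC_TISSUES <- c("brain", "muscle")
GERMLINE_TISSUES <- c("single_oocyte", "oocyte_pool")

MUTATION_CLASSES <- c("de_novo_tissue_specific", "early_somatic", "inherited",
                      "excluded_recurrent", "excluded_fragmentation_artifact",
                      "excluded_listed")

#' Classify variant calls by tissue and pedigree presence
#'
#' A variant (site, alt) is *inherited* when it is present in both somatic
#' and germline tissues of one individual, or in two generations (a mother
#' and a pup) of one pedigree.  A non-inherited variant is *early somatic*
#' in an individual where it is present in both somatic tissues, the
#' individual has germline samples, and it is absent from all of them.  All
#' remaining calls are putative tissue-specific de novo candidates.  Presence
#' in oocytes means presence in any single oocyte or the oocyte pool.
#'
#' @param calls Variant `data.frame` (`sample_id`, `pos`, `ref`, `alt`, DCS/
#'   SSCS counts; see [call_variants()] / [simulate_variant_calls()]).
#' @param samples Sample metadata (`sample_id`, `individual`, `pedigree`,
#'   `generation`, `tissue`, `fragmentation`, `mean_dcs_depth`).
#' @param pedigree Pedigree table (`id`, `mother_id`); currently used for
#'   validation only, generation membership comes from `samples`.
#' @return The calls with columns `class`, `individual`, `tissue` added; one
#'   row per input call, each with exactly one class.
#' @export
classify_variants <- function(calls, samples, pedigree = NULL) {
  miss <- setdiff(calls$sample_id, samples$sample_id)
  if (length(miss))
    stop("calls reference sample(s) without metadata: ",
         paste(utils::head(miss, 5), collapse = ", "))
  idx <- match(calls$sample_id, samples$sample_id)
  calls$individual <- samples$individual[idx]
  calls$tissue <- samples$tissue[idx]
  calls$generation <- samples$generation[idx]
  calls$pedigree <- samples$pedigree[idx]
  key <- paste(calls$pos, calls$alt, sep = ":")
  somatic <- calls$tissue %in% SOMATIC_TISSUES
  germline <- calls$tissue %in% GERMLINE_TISSUES

  # variant-level inheritance
  inh_keys <- unique(unlist(lapply(split(seq_len(nrow(calls)), key), function(i) {
    k <- key[i[1]]
    ind <- calls$individual[i]
    both_in_ind <- any(vapply(unique(ind), function(id) {
      any(somatic[i][ind == id]) && any(germline[i][ind == id])
    }, logical(1)))
    two_gen <- any(vapply(unique(calls$pedigree[i]), function(p) {
      g <- calls$generation[i][calls$pedigree[i] == p]
      all(c("mother", "pup") %in% g)
    }, logical(1)))
    if (both_in_ind || two_gen) k else NULL
  })))

  # individual-level early-somatic pattern (both somatic tissues carry it,
  # germline assayed and clean)
  has_germline <- tapply(samples$tissue %in% GERMLINE_TISSUES,
                         samples$individual, any)
  ikey <- paste(key, calls$individual, sep = "@")
  early_keys <- unique(unlist(lapply(split(seq_len(nrow(calls)), ikey),
                                     function(i) {
    k <- ikey[i[1]]
    id <- calls$individual[i[1]]
    tis <- calls$tissue[i]
    if (all(SOMATIC_TISSUES %in% tis) && !any(tis %in% GERMLINE_TISSUES) &&
        isTRUE(has_germline[[id]])) k else NULL
  })))

  calls$class <- "de_novo_tissue_specific"
  calls$class[ikey %in% early_keys] <- "early_somatic"
  calls$class[key %in% inh_keys] <- "inherited"
  calls
}

#' Annotate mutation records with type, compartment and context
#'
#' Adds the directed substitution type on the reference strand, the
#' transition flag, the functional compartment, the L-strand trinucleotide
#' context with CpG status, and the pyrimidine-collapsed type and context
#' used for spectrum reporting.
#'
#' @param records Classified calls (needs `pos`, `ref`, `alt`).
#' @param genome An [mt_genome].
#' @return `records` with columns `type`, `transition`, `compartment`,
#'   `context`, `cpg`, `type_collapsed`, `context_collapsed`.
#' @export
annotate_mutations <- function(records, genome) {
  if (nrow(records) == 0L) {
    records[c("type", "compartment", "context", "type_collapsed",
              "context_collapsed")] <- character(0)
    records$transition <- logical(0); records$cpg <- logical(0)
    return(records)
  }
  records$type <- paste0(records$ref, ">", records$alt)
  ti <- c("A>G", "G>A", "C>T", "T>C")
  records$transition <- records$type %in% ti
  records$compartment <- compartment_of(genome, records$pos)
  ctx <- context_of(genome, records$pos)
  records$context <- ctx$context
  records$cpg <- ctx$cpg
  coll <- collapse_substitution(records$ref, records$alt, records$context)
  records$type_collapsed <- coll$type
  records$context_collapsed <- coll$context
  records
}

#' Flag recurrent de novo candidates
#'
#' A (site, alt) combination observed as a de novo candidate in more than
#' `max_samples` samples across the whole dataset (both pedigrees jointly)
#' is either a mutational hot spot or a low-frequency segregating variant;
#' all its candidate records are reclassified `excluded_recurrent`.
#' Occurrence in up to `max_samples` samples is retained (low-frequency de
#' novo mutations are expected to recur by chance).
#'
#' @param records Classified mutation records.
#' @param max_samples Maximum number of samples sharing a candidate
#'   (default 3; strictly more are excluded).
#' @return Records with recurrent candidates reclassified.
#' @export
filter_recurrent <- function(records, max_samples = 3L) {
  cand <- records$class == "de_novo_tissue_specific"
  key <- paste(records$pos, records$alt, sep = ":")
  n_samples <- tapply(records$sample_id[cand], key[cand],
                      function(s) length(unique(s)))
  bad <- names(n_samples)[n_samples > max_samples]
  records$class[cand & key %in% bad] <- "excluded_recurrent"
  records
}

#' Collapse multi-molecule observations to single mutation events
#'
#' Mutations measured in more than one molecule of a sample are counted as a
#' single mutation event (assumed to stem from one mutation occurrence); the
#' supporting DCS count is retained for reporting.
#'
#' @param records Mutation records (one or more rows per sample/site/alt).
#' @return Records with one row per (sample, site, alt), an `event_count`
#'   column fixed at 1 and `n_supporting_dcs` carrying the summed DCS
#'   support.
#' @export
collapse_multimolecule <- function(records) {
  if (nrow(records) == 0L) {
    records$n_supporting_dcs <- integer(0)
    records$event_count <- integer(0)
    return(records)
  }
  key <- paste(records$sample_id, records$pos, records$alt, sep = "\r")
  support <- tapply(records$dcs_count, key, sum)
  first <- !duplicated(key)
  out <- records[first, , drop = FALSE]
  out$n_supporting_dcs <- as.integer(support[key[first]])
  out$event_count <- 1L
  rownames(out) <- NULL
  out
}

#' Flag fragmentation artifacts and listed sites
#'
#' A>T and T>A candidates in enzymatically fragmented samples are flagged as
#' fragmentation artifacts (end-repair introduces strand-consistent A/T
#' substitutions that survive duplex consensus).  Candidates at sites on a
#' user-supplied exclusion list (e.g. Numt homology or known contamination)
#' are flagged `excluded_listed`.
#'
#' @param records Classified mutation records (with `type`).
#' @param samples Sample metadata with `fragmentation`.
#' @param exclusion_sites Optional integer vector of positions to exclude.
#' @return Records with artifact classes assigned.
#' @export
filter_artifacts <- function(records, samples, exclusion_sites = NULL) {
  frag <- samples$fragmentation[match(records$sample_id, samples$sample_id)]
  cand <- records$class == "de_novo_tissue_specific"
  at <- records$type %in% c("A>T", "T>A")
  records$class[cand & at & frag == "enzymatic"] <-
    "excluded_fragmentation_artifact"
  if (length(exclusion_sites)) {
    cand <- records$class == "de_novo_tissue_specific"
    records$class[cand & records$pos %in% exclusion_sites] <- "excluded_listed"
  }
  records
}

#' Full classification pipeline
#'
#' Runs [classify_variants()], [annotate_mutations()],
#' [collapse_multimolecule()], [filter_recurrent()] and [filter_artifacts()]
#' in order, after sorting the calls so the result is independent of input
#' record order.
#'
#' @inheritParams classify_variants
#' @param genome An [mt_genome].
#' @param exclusion_sites Optional positions for [filter_artifacts()].
#' @param max_recurrent Passed to [filter_recurrent()].
#' @return Fully classified and annotated mutation records.
#' @export
classify_mutations <- function(calls, samples, genome, pedigree = NULL,
                               exclusion_sites = NULL, max_recurrent = 3L) {
  ord <- order(calls$sample_id, calls$pos, calls$alt)
  records <- classify_variants(calls[ord, , drop = FALSE], samples, pedigree)
  records <- annotate_mutations(records, genome)
  records <- collapse_multimolecule(records)
  records <- filter_recurrent(records, max_recurrent)
  records <- filter_artifacts(records, samples, exclusion_sites)
  records
}
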