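# Binomial mixed-effects logistic regression of mutation frequency with
# nucleotide-count weights, marginal/conditional/partial pseudo-R2 and
# likelihood-ratio tests.

GLMM_TYPE_CLASSES <- c("transversion", "A>G/T>C", "C>T/G>A")

type_class_of <- function(type) {
  ifelse(type %in% c("A>G", "T>C"), "A>G/T>C",
         ifelse(type %in% c("C>T", "G>A"), "C>T/G>A", "transversion"))
}

# bases whose mutation can produce the class
type_class_bases <- list("transversion" = c("A", "C", "G", "T"),
                         "A>G/T>C" = c("A", "T"),
                         "C>T/G>A" = c("C", "G"))

#' Build model cells for the mixed-effects frequency model
#'
#' One observation per individual x tissue x mtDNA compartment (D-loop vs
#' outside) x mutation-type class (transversions, A>G/T>C, C>T/G>A): the
#' mutation count of that class and the number of sequenced nucleotides able
#' to produce it (depth times the compartment content of the class's
#' reference bases).  Single oocytes are combined per individual; cells
#' below `min_nt` sequenced nucleotides are discarded (low-depth bias).
#'
#' @param records Retained de novo mutation records (annotated).
#' @param samples Sample metadata with `mean_dcs_depth`.
#' @param genome An [mt_genome].
#' @param min_nt Minimum sequenced nucleotides per cell (default 200000).
#' @return `data.frame` of cells; the number of dropped cells is attached as
#'   attribute `"n_dropped"`.
#' @export
build_cells <- function(records, samples, genome, min_nt = 2e5) {
  base_content <- lapply(
    stats::setNames(c("D-loop", "non-D-loop"), c("D-loop", "non-D-loop")),
    function(comp) sequenced_nt_by_base(genome, 1, comp))
  samples$unit <- ifelse(samples$tissue == "single_oocyte",
                         paste0(samples$individual, ".single_oocyte"),
                         samples$sample_id)
  rec_unit <- samples$unit[match(records$sample_id, samples$sample_id)]
  rec_comp <- ifelse(records$compartment == "D-loop", "D-loop", "non-D-loop")
  rec_class <- type_class_of(records$type)
  rows <- list()
  for (u in unique(samples$unit)) {
    su <- samples[samples$unit == u, , drop = FALSE]
    depth <- sum(su$mean_dcs_depth)
    in_u <- !is.na(rec_unit) & rec_unit == u
    for (comp in c("D-loop", "non-D-loop")) {
      for (cls in GLMM_TYPE_CLASSES) {
        nt <- sum(base_content[[comp]][type_class_bases[[cls]]]) * depth
        n <- sum(in_u & rec_comp == comp & rec_class == cls)
        rows[[length(rows) + 1L]] <- data.frame(
          individual = su$individual[1], age_group = su$generation[1],
          tissue = su$tissue[1], compartment = comp, type = cls,
          n_mutations = n, nt_total = nt, stringsAsFactors = FALSE)
      }
    }
  }
  cells <- do.call(rbind, rows)
  keep <- cells$nt_total >= min_nt
  out <- cells[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

cell_factors <- function(cells) {
  cells$age_group <- factor(cells$age_group, levels = c("mother", "pup"))
  cells$tissue <- factor(cells$tissue,
                         levels = intersect(c("brain", "muscle",
                                              "single_oocyte", "oocyte_pool"),
                                            unique(cells$tissue)))
  cells$compartment <- factor(cells$compartment,
                              levels = c("D-loop", "non-D-loop"))
  cells$type <- factor(cells$type, levels = GLMM_TYPE_CLASSES)
  cells
}

glmm_formula <- function(interactions = FALSE) {
  if (interactions)
    cbind(n_mutations, nt_total - n_mutations) ~ age_group + tissue +
      compartment + type + type:age_group + type:tissue + type:compartment +
      (1 | individual)
  else
    cbind(n_mutations, nt_total - n_mutations) ~ age_group + tissue +
      compartment + type + (1 | individual)
}

#' Fit the binomial mixed-effects mutation-frequency model
#'
#' Binomial family with logit link; the mutation count out of the cell's
#' nucleotide total is the response (equivalent to modelling the frequency
#' weighted by the total), with age group, tissue, compartment and mutation
#' type as fixed categorical predictors (baselines: mother, brain, D-loop,
#' transversion) and a random intercept per individual.  Reports Wald tests
#' per coefficient, likelihood-ratio tests per variable (full vs reduced
#' refit) and for the random effect (mixed vs fixed-only), and marginal,
#' conditional and partial pseudo-R-squared.
#'
#' @param cells Model cells from [build_cells()] or
#'   [simulate_model_cells()].
#' @param interactions Include the mutation-type two-way interactions.
#' @param compute_lrt Compute per-variable likelihood-ratio tests and
#'   partial pseudo-R2 (requires one refit per variable).
#' @return A `glmm_fit` list: `fit`, `coefficients` (with odds ratios),
#'   `r2` (marginal, conditional), `partial` (per-variable partial
#'   pseudo-R2 and LRT p), `ranef_test`, `converged`, `n_cells`.
#' @export
fit_glmm <- function(cells, interactions = FALSE, compute_lrt = TRUE) {
  cells <- cell_factors(cells)
  for (v in c("age_group", "tissue", "compartment", "type")) {
    if (nlevels(droplevels(cells[[v]])) < 2L)
      stop("fixed-effect variable '", v, "' has a single level (rank-deficient design)")
  }
  if (length(unique(cells$individual)) < 2L)
    stop("at least two individuals are required for a random intercept")
  fit <- lme4::glmer(glmm_formula(interactions), data = cells,
                     family = stats::binomial(),
                     control = lme4::glmerControl(optimizer = "bobyqa"))
  msgs <- unlist(fit@optinfo$conv$lme4)
  singular <- any(grepl("boundary \\(singular\\)", msgs))
  conv <- length(msgs) == 0L || all(grepl("boundary \\(singular\\)", msgs))
  co <- summary(fit)$coefficients
  coefficients <- data.frame(term = rownames(co), estimate = co[, 1],
                             std_error = co[, 2],
                             odds_ratio = exp(co[, 1]), wald_p = co[, 4],
                             stringsAsFactors = FALSE)
  rownames(coefficients) <- NULL
  r2 <- pseudo_r2_components(fit)
  # random-effect LRT against the fixed-only binomial GLM (naive chi-squared
  # reference; conservative at the boundary)
  glm_fit <- stats::glm(lme4::nobars(glmm_formula(interactions)),
                        data = cells, family = stats::binomial())
  lr <- as.numeric(2 * (stats::logLik(fit) - stats::logLik(glm_fit)))
  ranef_test <- list(lr = lr, df = 1,
                     p = stats::pchisq(max(lr, 0), 1, lower.tail = FALSE))
  out <- list(fit = fit, cells = cells, interactions = interactions,
              coefficients = coefficients,
              r2 = r2[c("marginal", "conditional")],
              ranef_test = ranef_test, converged = conv,
              singular = singular, n_cells = nrow(cells))
  if (compute_lrt) out$partial <- partial_pseudo_r2(fit, cells, interactions)
  class(out) <- "glmm_fit"
  out
}

#' Marginal and conditional pseudo-R-squared of a binomial-logit mixed model
#'
#' Latent-scale variance decomposition: the marginal pseudo-R2 is the fixed-
#' effect linear-predictor variance over the total latent variance (fixed +
#' random-intercept + distribution-specific pi^2/3 for the logit link); the
#' conditional pseudo-R2 adds the random-intercept variance to the
#' numerator.
#'
#' @param fit A fitted `glmerMod` binomial model.
#' @return List with `marginal`, `conditional`, `var_fixed`, `var_random`.
#' @export
pseudo_r2_components <- function(fit) {
  eta_fixed <- as.vector(lme4::getME(fit, "X") %*% lme4::fixef(fit))
  var_f <- stats::var(eta_fixed)
  var_r <- sum(vapply(lme4::VarCorr(fit), function(m) sum(diag(m)),
                      numeric(1)))
  var_d <- pi^2 / 3
  tot <- var_f + var_r + var_d
  list(marginal = var_f / tot, conditional = (var_f + var_r) / tot,
       var_fixed = var_f, var_random = var_r)
}

#' Partial pseudo-R-squared from full- and reduced-model marginal values
#'
#' `((1 - R2_red) - (1 - R2_full)) / (1 - R2_red)`, the share of the
#' unexplained variability of the reduced model that the variable recovers.
#'
#' @param r2_full,r2_reduced Marginal pseudo-R2 of the full and reduced
#'   models.
#' @return Partial pseudo-R2.
#' @export
partial_r2_formula <- function(r2_full, r2_reduced) {
  ((1 - r2_reduced) - (1 - r2_full)) / (1 - r2_reduced)
}

# per-variable reduced refits: partial pseudo-R2 + LRT
partial_pseudo_r2 <- function(fit, cells, interactions) {
  full_r2 <- pseudo_r2_components(fit)$marginal
  full_ll <- stats::logLik(fit)
  vars <- c("age_group", "tissue", "compartment", "type")
  out <- lapply(vars, function(v) {
    keep <- setdiff(vars, v)
    if (interactions && v != "type") {
      inter <- setdiff(c("type:age_group", "type:tissue", "type:compartment"),
                       paste0("type:", v))
      rhs <- paste(c(keep, inter, "(1 | individual)"), collapse = " + ")
    } else if (interactions && v == "type") {
      rhs <- paste(c(keep, "(1 | individual)"), collapse = " + ")
    } else {
      rhs <- paste(c(keep, "(1 | individual)"), collapse = " + ")
    }
    red <- lme4::glmer(
      stats::as.formula(paste(
        "cbind(n_mutations, nt_total - n_mutations) ~", rhs)),
      data = cells, family = stats::binomial(),
      control = lme4::glmerControl(optimizer = "bobyqa"))
    lr <- as.numeric(2 * (full_ll - stats::logLik(red)))
    df <- attr(full_ll, "df") - attr(stats::logLik(red), "df")
    data.frame(variable = v,
               partial_r2 = partial_r2_formula(
                 full_r2, pseudo_r2_components(red)$marginal),
               lrt_stat = lr, lrt_df = df,
               lrt_p = stats::pchisq(max(lr, 0), df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit the model with mutation-type interactions
#'
#' Adds the two-way interactions between mutation type and each of age
#' group, tissue and compartment, and tests the interaction block with a
#' likelihood-ratio test against the main-effects model.
#'
#' @inheritParams fit_glmm
#' @return A `glmm_fit` with an `interaction_test` element.
#' @export
fit_glmm_interactions <- function(cells, compute_lrt = TRUE) {
  main <- fit_glmm(cells, interactions = FALSE, compute_lrt = FALSE)
  full <- fit_glmm(cells, interactions = TRUE, compute_lrt = compute_lrt)
  lr <- as.numeric(2 * (stats::logLik(full$fit) - stats::logLik(main$fit)))
  df <- attr(stats::logLik(full$fit), "df") -
    attr(stats::logLik(main$fit), "df")
  full$interaction_test <- list(lr = lr, df = df,
                                p = stats::pchisq(max(lr, 0), df,
                                                  lower.tail = FALSE))
  full$main_fit <- main
  full
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf(
    "Binomial mixed-effects frequency model (%d cells%s)\n",
    x$n_cells, if (x$interactions) ", with type interactions" else ""))
  cat(sprintf("Marginal pseudo-R2: %.2f%%  Conditional pseudo-R2: %.2f%%\n",
              100 * x$r2$marginal, 100 * x$r2$conditional))
  if (!is.null(x$partial)) {
    cat("Partial pseudo-R2 (%):\n")
    p <- x$partial
    for (i in seq_len(nrow(p)))
      cat(sprintf("  %-12s %6.2f  (LRT p = %.3g)\n", p$variable[i],
                  100 * p$partial_r2[i], p$lrt_p[i]))
  }
  cat(sprintf("Random intercept (individual): LRT p = %.3g%s\n",
              x$ranef_test$p,
              if (isTRUE(x$singular)) " (variance estimated at zero)" else ""))
  if (!x$converged) cat("WARNING: fit did not converge cleanly\n")
  invisible(x)
}
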