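#' The study's model suite
#'
#' Declarative constructors for the analysis models fitted to the
#' emergence-test data, all thin wrappers around [ammc()] that encode each
#' model's fixed terms, random structure, response family and residual
#' structure. All expect a loaded study object from [load_study()] (or
#' [as_study()] on simulator output), which carries the common scaling of the
#' boldness score (computed over all records before any sex subsetting, so
#' male and female fits share a scale).
#'
#' @name model_suite
NULL

study_subset_ <- function(study, sex = NULL, time_points = NULL) {
  d <- study$data
  if (!is.null(sex) && !identical(sex, "both")) {
    sex <- match.arg(sex, c("F", "M"))
    d <- d[d$sex == sex, , drop = FALSE]
    if (!nrow(d)) stop("sex subset '", sex, "' is empty")
  }
  if (!is.null(time_points)) d <- d[d$time_point %in% time_points, , drop = FALSE]
  droplevels(d)
}

#' Cross-context correlation model (Model 1)
#'
#' Trivariate character-state model of the time-point 2 and 3 trials, one
#' trait per context (standard / with female / with object): per-context
#' fixed Sex + Age + Generation, a 3 x 3 unstructured among-individual
#' covariance, context-specific residual variances with cross-context
#' residual covariances fixed at zero (contexts are never co-measured within
#' a trial), censored-Gaussian response.
#'
#' @param study a loaded study; @param control,prior,seed see [ammc()].
#' @return an [ammc()] fit; among-individual correlations via
#'   [genetic_correlations()] with `term = "id"`.
#' @export
fit_model1 <- function(study, control = chain_control(), prior = list(),
                       seed = 1L) {
  d <- study_subset_(study, time_points = 2:3)
  for (ctx in c("S", "F", "O"))
    if (!any(d$context == ctx)) stop("no observations in context ", ctx)
  ammc(bold ~ 0 + context + context:(sex + age_class + generation),
       data = d, random = list(id = us("context", px = TRUE)),
       resid = resid_classes("context"),
       family = "cengaussian", bound = study$scaling$bound_scaled,
       control = control, prior = prior, seed = seed)
}

#' Short- and long-term repeatability models (Models 2a, 2b)
#'
#' Single-sex censored-Gaussian models with fixed Age + Generation + Trial +
#' Context and age-heterogeneous residuals. Variant `a` carries an
#' age-specific individual effect (4 x 4 unstructured); variant `b` adds an
#' overall (cross-age) individual effect with a single variance.
#'
#' @param study loaded study; @param sex `"F"` or `"M"`;
#' @param variant `"a"` or `"b"`; @param control,prior,seed see [ammc()].
#' @seealso [repeatability()]
#' @export
fit_model2 <- function(study, sex, variant = c("a", "b"),
                       control = chain_control(), prior = list(), seed = 1L) {
  variant <- match.arg(variant)
  d <- study_subset_(study, sex)
  random <- list(id = us("age_class", px = TRUE))
  if (variant == "b") random$id_overall <- us(NULL, group = "id", px = TRUE)
  ammc(bold ~ age_class + generation + trial_f + context, data = d,
       random = random, resid = resid_classes("age_class"),
       family = "cengaussian", bound = study$scaling$bound_scaled,
       control = control, prior = prior, seed = seed)
}

#' Age-specific animal model (Model 3a)
#'
#' The core variance-partitioning model, fitted per sex: censored-Gaussian
#' boldness with fixed Age + Generation + Trial + Context and three
#' age-specific random terms with 4 x 4 unstructured covariance matrices -
#' among-individual identity, additive genetic (`animal`, covariance
#' proportional to the pedigree A matrix) and maternal identity - plus
#' age-heterogeneous residuals with zero cross-age covariance.
#'
#' @inheritParams fit_model2
#' @seealso [heritability_series()], [genetic_correlations()],
#'   [gxs_gxa_tests()], [age_contrasts()]
#' @export
fit_model3a <- function(study, sex, control = chain_control(),
                        prior = list(), seed = 1L) {
  if (is.null(study$pedigree)) stop("model 3a needs a pedigree")
  d <- study_subset_(study, sex)
  ammc(bold ~ age_class + generation + trial_f + context, data = d,
       random = list(id = us("age_class", px = TRUE),
                     animal = us("age_class", pedigree = TRUE, px = TRUE),
                     mother = us("age_class", px = TRUE)),
       resid = resid_classes("age_class"),
       family = "cengaussian", bound = study$scaling$bound_scaled,
       pedigree = study$pedigree,
       control = control, prior = prior, seed = seed)
}

#' Body-size model (Model 3b)
#'
#' Adds standardized body size as a fixed covariate and simplifies the random
#' structure to a single overall individual effect (homogeneous residual), so
#' the size effect is not confounded with the variance partition of the full
#' animal model. Records with missing size are dropped with a message.
#'
#' @inheritParams fit_model2
#' @export
fit_model3b <- function(study, sex, control = chain_control(),
                        prior = list(), seed = 1L) {
  d <- study_subset_(study, sex)
  if (is.null(d$body_size)) stop("no body_size column")
  miss <- is.na(d$body_size)
  if (any(miss)) {
    message("dropping ", sum(miss), " record(s) with missing body size")
    d <- droplevels(d[!miss, , drop = FALSE])
  }
  if (stats::sd(d$body_size) == 0)
    stop("body size is constant; the size effect is not estimable")
  d$size_std <- (d$body_size - mean(d$body_size)) / stats::sd(d$body_size)
  ammc(bold ~ age_class + generation + trial_f + context + size_std,
       data = d, random = list(id_overall = us(NULL, group = "id", px = TRUE)),
       resid = resid_classes(NULL),
       family = "cengaussian", bound = study$scaling$bound_scaled,
       control = control, prior = prior, seed = seed)
}

#' Within/between-individual age decomposition
#'
#' Adds to a record table the between-individual age component `age_m` (mean
#' of the age classes at which that individual was observed) and the
#' within-individual component `age_wh` (the record's age class minus
#' `age_m`). By construction `age_m + age_wh` reconstructs the age class
#' exactly and `age_wh` sums to zero within each individual.
#'
#' @param data record table with columns `id` and `time_point` (age classes
#'   1-4).
#' @return `data` with columns `age_m`, `age_wh` appended.
#' @export
decompose_age <- function(data) {
  stopifnot(all(data$time_point %in% 1:4))
  agem <- tapply(data$time_point, data$id,
                 function(tp) mean(unique(tp)))
  data$age_m <- as.numeric(agem[as.character(data$id)])
  data$age_wh <- as.numeric(data$time_point - data$age_m)
  data
}

#' Selective-disappearance model (Model 3c)
#'
#' Replaces the age factor by its between-individual (`age_m`) and
#' within-individual (`age_wh`) components (fixed AgeM + AgeWH + Generation +
#' Trial + Context, overall individual effect, homogeneous residual).
#' `age_wh` measures within-individual plasticity across ages; a difference
#' between the `age_m` and `age_wh` slopes indicates selective disappearance
#' (non-random dropout of certain phenotypes). The fit carries a
#' `disappearance` element summarizing both slopes and their contrast.
#'
#' @inheritParams fit_model2
#' @export
fit_model3c <- function(study, sex, control = chain_control(),
                        prior = list(), seed = 1L) {
  d <- decompose_age(study_subset_(study, sex))
  if (stats::var(d$age_m) == 0)
    stop("age_m is constant (no attrition in the data); the ",
         "between-individual age effect is not estimable")
  fit <- ammc(bold ~ age_m + age_wh + generation + trial_f + context,
              data = d, random = list(id_overall = us(NULL, group = "id", px = TRUE)),
              resid = resid_classes(NULL),
              family = "cengaussian", bound = study$scaling$bound_scaled,
              control = control, prior = prior, seed = seed)
  bm <- fit$draws$fixed[, "age_m"]
  bw <- fit$draws$fixed[, "age_wh"]
  fit$disappearance <- rbind(
    cbind(effect = "age_wh (plasticity)", post_est(bw)),
    cbind(effect = "age_m (between-individual)", post_est(bm)),
    cbind(effect = "age_m - age_wh (selective disappearance)",
          post_est(bm - bw)))
  fit
}

#' Bivariate boldness-survival animal model (Model 4)
#'
#' Per-individual bivariate response: mean of the (up to two) time-point-1
#' emergence scores, treating a censored 300 as 300, then standardized
#' (Gaussian); and survival to the final test (binary probit, liability
#' scale). Fixed Generation per trait (plus Sex per trait when both sexes are
#' pooled); additive genetic (`animal`) term with a 2 x 2 unstructured
#' covariance; 2 x 2 unstructured residual with the binary variance fixed
#' at 1. No maternal term.
#'
#' @param study loaded study; @param sex `"F"`, `"M"` or `"both"`;
#' @param control,prior,seed see [ammc()].
#' @seealso [survival_assoc()]
#' @export
fit_model4 <- function(study, sex = "both", control = chain_control(),
                       prior = list(), seed = 1L) {
  if (is.null(study$pedigree)) stop("model 4 needs a pedigree")
  d <- study_subset_(study, sex, time_points = 1)
  if (!nrow(d)) stop("no time-point-1 records")
  agg <- stats::aggregate(raw_seconds ~ id, data = d, FUN = mean)
  info <- d[!duplicated(d$id), c("id", "sex", "generation", "survived_tp4")]
  tab <- merge(info, agg, by = "id")
  if (length(unique(tab$survived_tp4)) < 2)
    warning("binary degeneracy: all individuals have the same survival ",
            "outcome; the liability variance is not identified")
  mu <- mean(tab$raw_seconds); sdv <- stats::sd(tab$raw_seconds)
  long <- rbind(
    data.frame(id = tab$id, sex = tab$sex, generation = tab$generation,
               trait = "bold", value = (tab$raw_seconds - mu) / sdv,
               fam = "gaussian", stringsAsFactors = FALSE),
    data.frame(id = tab$id, sex = tab$sex, generation = tab$generation,
               trait = "surv", value = as.numeric(tab$survived_tp4),
               fam = "probit", stringsAsFactors = FALSE))
  long$trait <- factor(long$trait, levels = c("bold", "surv"))
  long$animal <- long$id
  fixed <- if (identical(sex, "both"))
    value ~ 0 + trait + trait:generation + trait:sex
  else value ~ 0 + trait + trait:generation
  ammc(fixed, data = long,
       random = list(animal = us("trait", pedigree = TRUE, px = TRUE)),
       resid = resid_bivar("id"), family = "fam",
       pedigree = study$pedigree,
       control = control, prior = prior, seed = seed)
}
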