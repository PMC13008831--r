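#' Breeding-design description
#'
#' Describes the paternal half-sib, three-generation design used to produce
#' the phenotyped population: `n_sires_P` parental sires each mated to
#' `dams_per_sire` virgin females (each dam contributing a single brood), the
#' resulting F1 crossed as trios (`n_sires_F1` males x `n_dams_F1` females,
#' two dams per sire) with all three members of a trio drawn from distinct F1
#' full-sib families, and one brood per F1 dam.
#'
#' @param n_sires_P number of parental-generation sires (default 50).
#' @param dams_per_sire dams mated to each P sire (default 2).
#' @param n_sires_F1,n_dams_F1 F1 individuals used as parents of the F2
#'   (defaults 16 and 32; `n_dams_F1` must equal `2 * n_sires_F1` under the
#'   trio mating scheme).
#' @param brood_mean,brood_min brood-size distribution: Poisson with the given
#'   mean, truncated below at `brood_min`. Set `fixed_brood` to a count for
#'   deterministic brood sizes.
#' @param fixed_brood optional fixed brood size overriding the distribution.
#' @param cross_family_trios require the three members of each F2 trio to come
#'   from three different F1 families (default TRUE).
#' @return object of class `breeding_design`.
#' @export
breeding_design <- function(n_sires_P = 50, dams_per_sire = 2,
                            n_sires_F1 = 16, n_dams_F1 = 32,
                            brood_mean = 4, brood_min = 1,
                            fixed_brood = NULL, cross_family_trios = TRUE) {
  stopifnot(n_sires_P >= 1, dams_per_sire >= 1, n_sires_F1 >= 1,
            n_dams_F1 == dams_per_sire * n_sires_F1,
            brood_mean > 0, brood_min >= 1)
  structure(list(n_sires_P = n_sires_P, dams_per_sire = dams_per_sire,
                 n_sires_F1 = n_sires_F1, n_dams_F1 = n_dams_F1,
                 brood_mean = brood_mean, brood_min = brood_min,
                 fixed_brood = fixed_brood,
                 cross_family_trios = cross_family_trios),
            class = "breeding_design")
}

#' Simulation parameters: variance components, fixed effects, censoring,
#' survival
#'
#' Holds the generating values for the synthetic study. Traits live on a
#' standardized latent scale (phenotypic SD about 1); `raw_scale` maps the
#' latent trait to emergence time in seconds, which is right-censored at
#' `censor_bound`. Covariance matrices are 4 x 4 across the four age classes
#' (time points). Defaults reproduce the study conditions used throughout the
#' package's recovery tests: additive variance 0.3 at every age with rank-one
#' cross-age structure (genetic correlations of 1), maternal-identity variance
#' 0.1 expressed at age 2 in females only, among-individual (permanent
#' environment) variance 0.2, and residuals chosen so the latent phenotypic
#' variance is 1 at every age and in both sexes.
#'
#' @param G_A 4x4 additive covariance across ages (PSD).
#' @param G_M 4x4 maternal-identity covariance across ages.
#' @param maternal_sex sex(es) in which the maternal effect is expressed:
#'   `"F"`, `"M"` or `"both"`.
#' @param G_ID 4x4 permanent-environment (among-individual) covariance.
#' @param V_R residual variance per age class; either a length-4 vector
#'   (shared) or `list(F =, M =)`.
#' @param beta fixed effects on the latent scale: list with `intercept`,
#'   `sex_M`, `age` (length 4, first entry the reference 0), `gen_F2`,
#'   `trial` (length 3), `context` (named S/F/O), `size` (sex-specific slope
#'   on standardized body size, named `c(F =, M =)`; default both 0).
#' @param va_scale per-sex multiplier applied to additive genetic values
#'   (variance scale), for genotype-by-sex scenarios; default `c(F=1, M=1)`.
#' @param censor_bound raw-scale censoring threshold in seconds (300).
#' @param raw_scale `c(mean, sd)` affine map from latent units to seconds.
#' @param survival list: `intercept` of the liability, `V_A` additive variance
#'   of the liability, `cov_A` additive covariance between the age-1 boldness
#'   value (emergence time, latent scale) and the liability, and `weights`,
#'   the death-interval allocation probabilities (death after TP1/TP2/TP3),
#'   proportional to the attrition observed in the study (23, 56, 54).
#' @param size list `mean = c(F=, M=)`, `sd` for the body-size covariate.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(G_A = 0.3 * matrix(1, 4, 4),
                       G_M = {
                         m <- matrix(0, 4, 4); m[2, 2] <- 0.1; m
                       },
                       maternal_sex = "F",
                       G_ID = diag(0.2, 4),
                       V_R = list(F = c(0.5, 0.4, 0.5, 0.5),
                                  M = c(0.5, 0.5, 0.5, 0.5)),
                       beta = list(intercept = 0, sex_M = -0.4,
                                   age = c(0, 0.5, 0.5, 0.35), gen_F2 = 0,
                                   trial = c(0, 0.2, 0.25),
                                   context = c(S = 0, F = -0.1, O = -0.1),
                                   size = c(F = 0, M = 0)),
                       va_scale = c(F = 1, M = 1),
                       censor_bound = 300,
                       raw_scale = c(mean = 150, sd = 60),
                       survival = list(intercept = 0.54, V_A = 0.5,
                                       cov_A = 0.4 * sqrt(0.3 * 0.5),
                                       weights = c(23, 56, 54) / 133),
                       size = list(mean = c(F = 0, M = 0), sd = 1)) {
  chk_cov <- function(m, nm) {
    if (!isTRUE(all.equal(m, t(m))) || min(eigen(m, symmetric = TRUE,
                                                 only.values = TRUE)$values) < -1e-8)
      stop(nm, " must be symmetric positive semi-definite")
  }
  chk_cov(G_A, "G_A"); chk_cov(G_M, "G_M"); chk_cov(G_ID, "G_ID")
  if (is.numeric(V_R)) V_R <- list(F = V_R, M = V_R)
  stopifnot(all(unlist(V_R) > 0), censor_bound > 0, raw_scale[["sd"]] > 0)
  maternal_sex <- match.arg(maternal_sex, c("F", "M", "both"))
  if (survival$V_A > 0 && survival$cov_A^2 > survival$V_A * G_A[1, 1] + 1e-12)
    stop("survival cov_A implies a genetic correlation outside [-1, 1]")
  structure(list(G_A = G_A, G_M = G_M, maternal_sex = maternal_sex,
                 G_ID = G_ID, V_R = V_R, beta = beta, va_scale = va_scale,
                 censor_bound = censor_bound, raw_scale = raw_scale,
                 survival = survival, size = size),
            class = "sim_params")
}

# run expr under a local RNG stream; global .Random.seed restored on exit
with_seed_ <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

rbrood_ <- function(n, design) {
  if (!is.null(design$fixed_brood)) return(rep(design$fixed_brood, n))
  out <- integer(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rpois(length(need), design$brood_mean)
    ok <- draw >= design$brood_min
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate the three-generation pedigree
#'
#' P founders (sires and dams), F1 full-sib families nested within paternal
#' half-sib pairs, and F2 broods from cross-family F1 trios. Offspring sexes
#' are independent Bernoulli(0.5).
#'
#' @param design a [breeding_design()].
#' @param seed integer seed (RNG state is restored afterwards).
#' @return A sorted `pedigree` with an extra column `family` (the dam label,
#'   one brood per dam) for non-founders.
#' @export
simulate_pedigree <- function(design = breeding_design(), seed = NULL) {
  with_seed_(seed, {
    ns <- design$n_sires_P; dps <- design$dams_per_sire
    nd <- ns * dps
    sires <- sprintf("PS%03d", seq_len(ns))
    dams <- sprintf("PD%03d", seq_len(nd))
    ped <- data.frame(id = c(sires, dams),
                      sire = NA_character_, dam = NA_character_,
                      sex = c(rep("M", ns), rep("F", nd)),
                      generation = "P", family = NA_character_,
                      stringsAsFactors = FALSE)
    # F1: dam k belongs to sire ceiling(k / dps)
    bro <- rbrood_(nd, design)
    f1 <- data.frame(
      id = sprintf("F1_%04d", seq_len(sum(bro))),
      sire = rep(sires[ceiling(seq_len(nd) / dps)], bro),
      dam = rep(dams, bro),
      sex = sample(c("F", "M"), sum(bro), replace = TRUE),
      generation = "F1", family = rep(dams, bro),
      stringsAsFactors = FALSE)
    # F2 parents: trios of one F1 male and two F1 females, all three from
    # different F1 families
    males <- f1[f1$sex == "M", ]
    females <- f1[f1$sex == "F", ]
    nsf <- design$n_sires_F1; ndf <- design$n_dams_F1
    if (nrow(males) < nsf || nrow(females) < ndf)
      stop("design infeasible: not enough F1 of the required sex")
    pick_trios <- function() {
      ms <- males[sample(nrow(males), nsf), ]
      fs <- females[sample(nrow(females), ndf), ]
      trio_dams <- vector("list", nsf)
      used <- rep(FALSE, ndf)
      for (t in seq_len(nsf)) {
        if (design$cross_family_trios) {
          # dams from families differing from the sire's and from each other
          avail <- which(!used & fs$family != ms$family[t])
          if (!length(avail)) return(NULL)
          d1 <- avail[sample.int(length(avail), 1)]
          avail2 <- which(!used & fs$family != ms$family[t] &
                            fs$family != fs$family[d1])
          avail2 <- setdiff(avail2, d1)
          if (!length(avail2)) return(NULL)
          d2 <- avail2[sample.int(length(avail2), 1)]
        } else {
          avail <- which(!used)
          if (length(avail) < 2) return(NULL)
          dd <- sample(avail, 2)
          d1 <- dd[1]; d2 <- dd[2]
        }
        used[c(d1, d2)] <- TRUE
        trio_dams[[t]] <- c(d1, d2)
      }
      list(ms = ms, fs = fs, trio_dams = trio_dams)
    }
    trios <- NULL
    for (try in 1:50) {
      trios <- pick_trios()
      if (!is.null(trios)) break
    }
    if (is.null(trios))
      stop("design infeasible: not enough distinct F1 families for cross-family trios")
    f2_sire <- character(0); f2_dam <- character(0)
    for (t in seq_len(nsf)) {
      dd <- trios$trio_dams[[t]]
      f2_sire <- c(f2_sire, rep(trios$ms$id[t], 2))
      f2_dam <- c(f2_dam, trios$fs$id[dd])
    }
    bro2 <- rbrood_(length(f2_dam), design)
    f2 <- data.frame(
      id = sprintf("F2_%04d", seq_len(sum(bro2))),
      sire = rep(f2_sire, bro2), dam = rep(f2_dam, bro2),
      sex = sample(c("F", "M"), sum(bro2), replace = TRUE),
      generation = "F2", family = rep(f2_dam, bro2),
      stringsAsFactors = FALSE)
    all <- rbind(ped, f1, f2)
    fam <- all$family
    names(fam) <- all$id
    out <- validate_and_sort(all[, c("id", "sire", "dam", "sex", "generation")])
    out$family <- unname(fam[out$id])
    class(out) <- c("pedigree", "data.frame")
    out
  })
}

# symmetric PSD square root
psd_sqrt_ <- function(G) {
  e <- eigen(G, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}

#' Gene-drop additive genetic values through the pedigree
#'
#' Realizes the animal term: founders are drawn from N(0, G) and each
#' offspring is the parental average plus a Mendelian deviation with
#' covariance `d_i * G`, `d_i = (1 - (F_s + F_d)/2) / 2` (adjusted for unknown
#' parents). The trait vector is 5-dimensional: the four age-class boldness
#' values plus the survival liability, whose additive component is tied to the
#' age-1 boldness value through `survival$cov_A` (regression construction, so
#' the joint covariance stays PSD for any PSD `G_A`).
#'
#' Also draws the maternal brood effect (one value per dam per age class) and
#' the permanent-environment values, and records the generating ("true")
#' heritability, maternal-effect and repeatability ratios implied by the
#' parameters.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param params [sim_params()].
#' @param seed integer seed.
#' @return object of class `true_values`: list with `additive` (n x 5 matrix,
#'   columns `age1..age4, surv`), `maternal` (dams x 4), `pe` (n x 4), and
#'   `true` (named list of generating ratios).
#' @export
simulate_genetic_effects <- function(ped, params = sim_params(), seed = NULL) {
  pp <- .ped_indices(ped)
  ped <- pp$ped; si <- pp$sire; di <- pp$dam
  n <- nrow(ped)
  GA <- params$G_A
  vs <- params$survival
  b <- if (GA[1, 1] > 0) vs$cov_A / GA[1, 1] else 0
  vrem <- vs$V_A - b^2 * GA[1, 1]
  if (vrem < -1e-10) stop("survival additive variance incompatible with cov_A")
  Gfull <- rbind(cbind(GA, GA[, 1] * b),
                 c(GA[1, ] * b, b^2 * GA[1, 1] + max(vrem, 0)))
  sq <- psd_sqrt_(Gfull)
  FF <- inbreeding(ped)
  with_seed_(seed, {
    A <- matrix(0, n, 5, dimnames = list(ped$id, c(paste0("age", 1:4), "surv")))
    Z <- matrix(stats::rnorm(n * 5), n, 5)
    for (i in seq_len(n)) {
      s <- si[i]; d <- di[i]
      mu <- numeric(5)
      dd <- 1
      if (s > 0L && d > 0L) {
        mu <- 0.5 * (A[s, ] + A[d, ])
        dd <- 0.5 * (1 - 0.5 * (FF[s] + FF[d]))
      } else if (s > 0L) {
        mu <- 0.5 * A[s, ]; dd <- 0.75 - 0.25 * FF[s]
      } else if (d > 0L) {
        mu <- 0.5 * A[d, ]; dd <- 0.75 - 0.25 * FF[d]
      }
      A[i, ] <- mu + sqrt(dd) * drop(sq %*% Z[i, ])
    }
    dams <- unique(stats::na.omit(ped$dam))
    Mm <- matrix(stats::rnorm(length(dams) * 4), length(dams), 4) %*%
      psd_sqrt_(params$G_M)
    rownames(Mm) <- dams
    PE <- matrix(stats::rnorm(n * 4), n, 4) %*% psd_sqrt_(params$G_ID)
    rownames(PE) <- ped$id
    truequant <- .true_ratios(params)
    structure(list(additive = A, maternal = Mm, pe = PE, true = truequant,
                   params = params),
              class = "true_values")
  })
}

# generating ratios implied by the parameters (ground truth for recovery)
.true_ratios <- function(params) {
  out <- list()
  for (sx in c("F", "M")) {
    va <- diag(params$G_A) * params$va_scale[[sx]]
    vm <- if (params$maternal_sex %in% c(sx, "both")) diag(params$G_M) else rep(0, 4)
    vid <- diag(params$G_ID)
    vr <- params$V_R[[sx]]
    vp <- va + vm + vid + vr
    out[[sx]] <- list(h2 = va / vp, m2 = vm / vp, R_short = (vid + vm + va) / vp,
                      V_P = vp)
  }
  sva <- params$survival$V_A
  out$survival <- list(h2_liability = sva / (sva + 1),
                       r_A = if (sva > 0 && params$G_A[1, 1] > 0)
                         params$survival$cov_A / sqrt(sva * params$G_A[1, 1]) else 0)
  out
}

#' Simulate the emergence-test phenotype records
#'
#' Applies the study's trial schedule to every non-founder: two standard
#' trials at time point 1, three trials in contexts S/F/O (randomized order
#' per individual) at time points 2 and 3, and two standard trials at time
#' point 4. The latent trait is the sum of fixed effects, additive, maternal
#' (in the sex(es) where expressed) and permanent-environment values plus an
#' age- and sex-specific residual; it is mapped to seconds by `raw_scale` and
#' right-censored at `censor_bound` (records at the bound carry
#' `censored = TRUE`; times are floored at 1 s, i.e. immediate emergence).
#'
#' @param ped pedigree; @param truth from [simulate_genetic_effects()];
#' @param params [sim_params()]; @param seed integer seed.
#' @return Long-format data.frame: `id, sex, generation, time_point, trial,
#'   context, raw_seconds, censored, body_size, survived_tp4` (the last filled
#'   by [apply_survival()]; `TRUE` here).
#' @export
simulate_phenotypes <- function(ped, truth, params = sim_params(), seed = NULL) {
  ped <- if (inherits(ped, "pedigree")) ped else validate_and_sort(ped)
  ph <- ped[ped$generation != "P", , drop = FALSE]
  n <- nrow(ph)
  with_seed_(seed, {
    size <- stats::rnorm(n, params$size$mean[ph$sex], params$size$sd)
    names(size) <- ph$id
    sched <- data.frame(time_point = c(1, 1, 2, 2, 2, 3, 3, 3, 4, 4),
                        trial = c(1, 2, 1, 2, 3, 1, 2, 3, 1, 2))
    ntr <- nrow(sched)
    rec <- data.frame(
      id = rep(ph$id, each = ntr),
      sex = rep(ph$sex, each = ntr),
      generation = rep(ph$generation, each = ntr),
      time_point = rep(sched$time_point, n),
      trial = rep(sched$trial, n),
      stringsAsFactors = FALSE)
    # contexts: S at TP1/TP4; randomized S/F/O order within TP2 and TP3
    ctx <- matrix("S", n, ntr)
    for (i in seq_len(n)) {
      ctx[i, 3:5] <- sample(c("S", "F", "O"))
      ctx[i, 6:8] <- sample(c("S", "F", "O"))
    }
    rec$context <- as.vector(t(ctx))
    be <- params$beta
    tp <- rec$time_point
    lat <- be$intercept + ifelse(rec$sex == "M", be$sex_M, 0) +
      be$age[tp] + ifelse(rec$generation == "F2", be$gen_F2, 0) +
      be$trial[rec$trial] + be$context[rec$context] +
      be$size[rec$sex] * size[rec$id]
    sc <- sqrt(params$va_scale[rec$sex])
    ri <- match(rec$id, rownames(truth$additive))
    lat <- lat + sc * truth$additive[cbind(ri, tp)]
    mat_on <- params$maternal_sex == "both" | rec$sex == params$maternal_sex
    dam_of <- stats::setNames(ped$dam, ped$id)
    mi <- match(dam_of[rec$id], rownames(truth$maternal))
    lat <- lat + ifelse(mat_on, truth$maternal[cbind(mi, tp)], 0)
    lat <- lat + truth$pe[cbind(match(rec$id, rownames(truth$pe)), tp)]
    vr <- mapply(function(sx, t) params$V_R[[sx]][t], rec$sex, tp)
    lat <- lat + stats::rnorm(nrow(rec), 0, sqrt(vr))
    raw <- params$raw_scale[["mean"]] + params$raw_scale[["sd"]] * lat
    cens <- raw >= params$censor_bound
    raw <- pmin(pmax(raw, 1), params$censor_bound)
    rec$raw_seconds <- raw
    rec$censored <- cens
    rec$body_size <- unname(size[rec$id])
    rec$survived_tp4 <- TRUE
    rownames(rec) <- NULL
    rec
  })
}

#' Simulate survival to the final test and death intervals
#'
#' The liability is `intercept + additive survival value + N(0, 1)`; an
#' individual survives to time point 4 if its liability is positive.
#' Non-survivors are allocated a death interval (after TP1, TP2 or TP3) with
#' the configured interval weights.
#'
#' @inheritParams simulate_phenotypes
#' @return data.frame `id, sex, liability, survived, last_tp`.
#' @export
simulate_survival <- function(ped, truth, params = sim_params(), seed = NULL) {
  ped <- if (inherits(ped, "pedigree")) ped else validate_and_sort(ped)
  ph <- ped[ped$generation != "P", , drop = FALSE]
  with_seed_(seed, {
    liab <- params$survival$intercept + truth$additive[ph$id, "surv"] +
      stats::rnorm(nrow(ph))
    survived <- liab > 0
    last_tp <- ifelse(survived, 4L,
                      sample(1:3, nrow(ph), replace = TRUE,
                             prob = params$survival$weights))
    data.frame(id = ph$id, sex = ph$sex, liability = unname(liab),
               survived = unname(survived), last_tp = unname(last_tp),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Remove phenotype records after death and set the survival flag
#'
#' @param pheno phenotype table from [simulate_phenotypes()].
#' @param survival table from [simulate_survival()].
#' @return Filtered phenotype table.
#' @export
apply_survival <- function(pheno, survival) {
  last <- stats::setNames(survival$last_tp, survival$id)
  surv <- stats::setNames(survival$survived, survival$id)
  out <- pheno[pheno$time_point <= last[pheno$id], , drop = FALSE]
  out$survived_tp4 <- unname(surv[out$id])
  rownames(out) <- NULL
  out
}

#' Simulate a complete study
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [simulate_genetic_effects()], [simulate_phenotypes()],
#' [simulate_survival()] and [apply_survival()], with sub-seeds derived from
#' `seed`.
#'
#' @param design [breeding_design()]; @param params [sim_params()];
#' @param seed integer seed.
#' @return list `pedigree`, `phenotypes`, `survival`, `truth`.
#' @export
simulate_study <- function(design = breeding_design(), params = sim_params(),
                           seed = 1) {
  ped <- simulate_pedigree(design, seed = seed)
  truth <- simulate_genetic_effects(ped, params, seed = seed + 1L)
  pheno <- simulate_phenotypes(ped, truth, params, seed = seed + 2L)
  surv <- simulate_survival(ped, truth, params, seed = seed + 3L)
  list(pedigree = ped, phenotypes = apply_survival(pheno, surv),
       survival = surv, truth = truth)
}

#' Fixture dataset matching the study's sample-size table
#'
#' Simulates the default design and reduces it to the study's marginal
#' counts: exactly 399 individuals scored at time point 1 (210 females, 189
#' males), 376 at TP2, 320 at TP3 and 266 at TP4. Scored individuals are a
#' random subset of the phenotyped pool; the required number of deaths per
#' sex and interval is met by removing the individuals with the lowest
#' survival liabilities first (earliest deaths are the most strongly
#' selected), which preserves the simulated boldness-survival association.
#' Deterministic given `seed`.
#'
#' @param seed integer seed.
#' @param params [sim_params()].
#' @return list as [simulate_study()], phenotypes restricted to the fixture.
#' @export
fixture_study <- function(seed = 1, params = sim_params()) {
  target <- list(F = c(210, 200, 180, 156), M = c(189, 176, 140, 110))
  for (attempt in 0:24) {
    succ_seed <- seed + 1000L * attempt
    st <- simulate_study(breeding_design(), params, seed = succ_seed)
    ph_ind <- unique(st$phenotypes$id[st$phenotypes$time_point == 1])
    sx <- stats::setNames(st$pedigree$sex, st$pedigree$id)[ph_ind]
    if (sum(sx == "F") >= target$F[1] && sum(sx == "M") >= target$M[1]) break
    st <- NULL
  }
  if (is.null(st)) stop("could not reach the fixture sample sizes")
  surv <- st$survival
  pheno_all <- simulate_phenotypes(st$pedigree, st$truth, params,
                                   seed = succ_seed + 2L)
  new_last <- integer(0); new_ids <- character(0); new_surv <- logical(0)
  with_seed_(seed + 500L, {
    for (s in c("F", "M")) {
      ids <- ph_ind[sx[ph_ind] == s]
      ids <- sample(ids, target[[s]][1])
      liab <- stats::setNames(surv$liability, surv$id)[ids]
      ord <- ids[order(liab)] # lowest liability dies first
      ndeath <- -diff(c(target[[s]], target[[s]][4]))[1:3]
      last <- rep(4L, length(ids))
      names(last) <- ord
      pos <- 1L
      for (tp in 1:3) {
        if (ndeath[tp] > 0) {
          last[pos:(pos + ndeath[tp] - 1L)] <- tp
          pos <- pos + ndeath[tp]
        }
      }
      new_ids <- c(new_ids, names(last))
      new_last <- c(new_last, unname(last))
      new_surv <- c(new_surv, unname(last) == 4L)
    }
  })
  fsurv <- data.frame(id = new_ids,
                      sex = stats::setNames(st$pedigree$sex, st$pedigree$id)[new_ids],
                      liability = stats::setNames(surv$liability, surv$id)[new_ids],
                      survived = new_surv, last_tp = new_last,
                      stringsAsFactors = FALSE, row.names = NULL)
  pheno <- pheno_all[pheno_all$id %in% new_ids, , drop = FALSE]
  pheno <- apply_survival(pheno, fsurv)
  list(pedigree = st$pedigree, phenotypes = pheno, survival = fsurv,
       truth = st$truth)
}
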