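test_that("simulated pedigree matches the breeding-design arithmetic", {
  ped <- simulate_pedigree(breeding_design(fixed_brood = 4), seed = 1)
  f1 <- ped[ped$generation == "F1", ]
  expect_equal(nrow(f1), 400)
  expect_equal(length(unique(f1$family)), 100)
  # families nested in 50 paternal half-sib pairs
  fam_sire <- unique(f1[, c("family", "sire")])
  expect_equal(nrow(fam_sire), 100)
  expect_equal(length(unique(fam_sire$sire)), 50)
  expect_true(all(table(fam_sire$sire) == 2))
})

test_that("pedigree simulation is deterministic and trios are cross-family", {
  p1 <- simulate_pedigree(seed = 5)
  p2 <- simulate_pedigree(seed = 5)
  expect_identical(p1, p2)
  f2 <- p1[p1$generation == "F2", ]
  fam_of <- stats::setNames(p1$family, p1$id)
  trio_fams <- unique(data.frame(sire = f2$sire, dam = f2$dam))
  by_sire <- split(trio_fams$dam, trio_fams$sire)
  for (s in names(by_sire)) {
    fams <- c(fam_of[s], fam_of[by_sire[[s]]])
    expect_equal(length(unique(fams)), 3)
  }
})

test_that("gene dropping has the right first and second moments", {
  # G_A = 0 gives exactly zero additive values
  ped <- simulate_pedigree(breeding_design(fixed_brood = 2), seed = 2)
  p0 <- sim_params(G_A = matrix(0, 4, 4),
                   survival = list(intercept = 0.5, V_A = 0, cov_A = 0,
                                   weights = c(1, 1, 1) / 3))
  tr0 <- simulate_genetic_effects(ped, p0, seed = 3)
  expect_true(all(tr0$additive[, 1:4] == 0))
  # founder covariance ~ G_A (moment check, 3 MC standard errors)
  big <- validate_and_sort(
    data.frame(id = sprintf("f%04d", 1:4000), sire = NA, dam = NA,
               sex = rep(c("M", "F"), 2000), generation = "P"))
  pars <- sim_params()
  tr <- simulate_genetic_effects(big, pars, seed = 4)
  emp <- stats::cov(tr$additive[, 1:4])
  se <- sqrt((diag(pars$G_A) %o% diag(pars$G_A) +
                pars$G_A^2) / nrow(big)) # var of a sample covariance
  expect_true(all(abs(emp - pars$G_A) < 3 * se + 1e-12))
  # paternal half-sib additive covariance ~ G_A / 4
  ns <- 1200
  hs <- validate_and_sort(data.frame(
    id = c(sprintf("s%04d", 1:ns), sprintf("a%04d", 1:ns), sprintf("b%04d", 1:ns)),
    sire = c(rep(NA, ns), sprintf("s%04d", 1:ns), sprintf("s%04d", 1:ns)),
    dam = NA,
    sex = c(rep("M", ns), rep("F", 2 * ns)),
    generation = c(rep("P", ns), rep("F1", 2 * ns))))
  trh <- simulate_genetic_effects(hs, pars, seed = 5)
  a1 <- trh$additive[sprintf("a%04d", 1:ns), 1]
  b1 <- trh$additive[sprintf("b%04d", 1:ns), 1]
  cv <- stats::cov(a1, b1)
  se_cv <- sqrt((pars$G_A[1, 1]^2 + (pars$G_A[1, 1] / 4)^2) / ns)
  expect_lt(abs(cv - pars$G_A[1, 1] / 4), 3 * se_cv)
})

test_that("phenotype schedule, censoring and invariants", {
  ped <- simulate_pedigree(breeding_design(n_sires_P = 10, dams_per_sire = 2,
                                           n_sires_F1 = 2, n_dams_F1 = 4,
                                           fixed_brood = 4), seed = 1)
  pars <- sim_params()
  tr <- simulate_genetic_effects(ped, pars, seed = 2)
  ph <- simulate_phenotypes(ped, tr, pars, seed = 3)
  # 2 + 3 + 3 + 2 trials per phenotyped individual
  expect_true(all(table(ph$id) == 10))
  sch <- table(ph$time_point) / length(unique(ph$id))
  expect_equal(as.numeric(sch), c(2, 3, 3, 2))
  # contexts: S at TP1/TP4; one each of S, F, O at TP2 and TP3
  expect_true(all(ph$context[ph$time_point %in% c(1, 4)] == "S"))
  ctx23 <- tapply(ph$context[ph$time_point == 2], ph$id[ph$time_point == 2],
                  function(x) paste(sort(x), collapse = ""))
  expect_true(all(ctx23 == "FOS"))
  expect_true(all(ph$raw_seconds > 0 & ph$raw_seconds <= 300))
  expect_true(all(ph$censored == (ph$raw_seconds == 300)))
  # all variance components zero: records equal the fixed-effect prediction
  p0 <- sim_params(G_A = matrix(0, 4, 4), G_M = matrix(0, 4, 4),
                   G_ID = matrix(0, 4, 4),
                   V_R = list(F = rep(1e-12, 4), M = rep(1e-12, 4)),
                   survival = list(intercept = 5, V_A = 0, cov_A = 0,
                                   weights = c(1, 1, 1) / 3))
  tr0 <- simulate_genetic_effects(ped, p0, seed = 2)
  ph0 <- simulate_phenotypes(ped, tr0, p0, seed = 3)
  be <- p0$beta
  pred <- 150 + 60 * (be$intercept + ifelse(ph0$sex == "M", be$sex_M, 0) +
                        be$age[ph0$time_point] +
                        ifelse(ph0$generation == "F2", be$gen_F2, 0) +
                        be$trial[ph0$trial] + be$context[ph0$context])
  expect_equal(ph0$raw_seconds, unname(pred), tolerance = 1e-6)
  # a latent far above the bound is recorded as a censored 300
  phi <- sim_params(beta = within(p0$beta, intercept <- 10),
                    G_A = matrix(0, 4, 4), G_M = matrix(0, 4, 4),
                    G_ID = matrix(0, 4, 4),
                    V_R = list(F = rep(1e-12, 4), M = rep(1e-12, 4)),
                    survival = list(intercept = 5, V_A = 0, cov_A = 0,
                                    weights = c(1, 1, 1) / 3))
  ph300 <- simulate_phenotypes(ped, tr0, phi, seed = 3)
  expect_true(all(ph300$raw_seconds == 300))
  expect_true(all(ph300$censored))
})

test_that("parent-offspring regression recovers the trial-mean heritability", {
  # large design so the regression SE is well below the tolerance
  des <- breeding_design(n_sires_P = 150, dams_per_sire = 2,
                         n_sires_F1 = 100, n_dams_F1 = 200, brood_mean = 4)
  pars <- sim_params(G_M = matrix(0, 4, 4)) # no maternal confound
  st <- simulate_study(des, pars, seed = 8)
  ph <- st$phenotypes[st$phenotypes$time_point == 1, ]
  lat <- (ph$raw_seconds - 150) / 60
  im <- tapply(lat, ph$id, mean)
  ped <- st$pedigree
  f2 <- ped[ped$generation == "F2", ]
  f2 <- f2[f2$id %in% names(im) & f2$sire %in% names(im) &
             f2$dam %in% names(im), ]
  mid <- (im[f2$sire] + im[f2$dam]) / 2
  off <- im[f2$id]
  slope <- stats::coef(stats::lm(off ~ mid))[2]
  # h2 of the mean of 2 trials: V_A / (V_A + V_ID + V_R/2)
  h2_mean <- 0.3 / (0.3 + 0.2 + 0.5 / 2)
  expect_lt(abs(slope - h2_mean), 0.08)
})

test_that("survival simulation: null, certainty and sign-flip behaviour", {
  big <- breeding_design(n_sires_P = 700, dams_per_sire = 2,
                         n_sires_F1 = 16, n_dams_F1 = 32, fixed_brood = 4)
  ped <- simulate_pedigree(big, seed = 1)
  # zero genetic covariance: survival uncorrelated with boldness additive value
  p0 <- sim_params(survival = list(intercept = 0.54, V_A = 0.5, cov_A = 0,
                                   weights = c(23, 56, 54) / 133))
  tr <- simulate_genetic_effects(ped, p0, seed = 2)
  sv <- simulate_survival(ped, tr, p0, seed = 3)
  a1 <- tr$additive[sv$id, 1]
  expect_gte(length(sv$id), 5000)
  expect_lt(abs(stats::cor(a1, as.numeric(sv$survived))), 0.03)
  # huge intercept: everyone survives to the final test
  pinf <- sim_params(survival = list(intercept = 50, V_A = 0.5, cov_A = 0,
                                     weights = c(23, 56, 54) / 133))
  svi <- simulate_survival(ped, tr, pinf, seed = 3)
  expect_true(all(svi$survived))
  expect_true(all(svi$last_tp == 4))
  # reversing the covariance sign flips the boldness-survival association
  pp <- sim_params(survival = list(intercept = 0.54, V_A = 0.5,
                                   cov_A = 0.155, weights = c(23, 56, 54) / 133))
  pn <- sim_params(survival = list(intercept = 0.54, V_A = 0.5,
                                   cov_A = -0.155, weights = c(23, 56, 54) / 133))
  trp <- simulate_genetic_effects(ped, pp, seed = 4)
  trn <- simulate_genetic_effects(ped, pn, seed = 4)
  svp <- simulate_survival(ped, trp, pp, seed = 5)
  svn <- simulate_survival(ped, trn, pn, seed = 5)
  cp <- stats::cor(trp$additive[svp$id, 1], as.numeric(svp$survived))
  cn <- stats::cor(trn$additive[svn$id, 1], as.numeric(svn$survived))
  expect_gt(cp, 0.05)   # high emergence time (shy) survives more
  expect_lt(cn, -0.05)
})

test_that("fixture matches the study's marginal counts", {
  fx <- fixture_study(seed = 1)
  ph <- fx$phenotypes
  ind_tp <- table(ph$time_point[!duplicated(paste(ph$id, ph$time_point))])
  expect_equal(unname(c(ind_tp)), c(399, 376, 320, 266))
  d1 <- ph[ph$time_point == 1 & !duplicated(ph$id), ]
  expect_equal(unname(c(table(d1$sex))), c(210, 189))
  fx2 <- fixture_study(seed = 1)
  expect_identical(fx$phenotypes, fx2$phenotypes)
  expect_identical(fx$pedigree, fx2$pedigree)
  # records only exist while the individual is alive
  last <- stats::setNames(fx$survival$last_tp, fx$survival$id)
  expect_true(all(ph$time_point <= last[ph$id]))
})
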