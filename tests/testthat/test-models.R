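quick_ctl <- chain_control(nitt = 4000, burnin = 800, thin = 5)

test_that("age decomposition is exact and invertible", {
  d <- data.frame(id = c(rep("a", 3), "b", rep("c", 4)),
                  time_point = c(1, 2, 3, 1, 1, 2, 3, 4))
  out <- decompose_age(d)
  expect_equal(out$age_m[out$id == "a"], rep(2, 3))
  expect_equal(out$age_wh[out$id == "a"], c(-1, 0, 1))
  expect_equal(out$age_m[out$id == "b"], 1)
  expect_equal(out$age_wh[out$id == "b"], 0)
  expect_equal(out$age_m[out$id == "c"], rep(2.5, 4))
  # exact reconstruction and zero within-individual sums
  expect_equal(out$age_m + out$age_wh, d$time_point)
  sums <- tapply(out$age_wh, out$id, sum)
  expect_equal(as.numeric(sums), rep(0, 3))
  # idempotent on the added columns
  out2 <- decompose_age(out)
  expect_equal(out2$age_m, out$age_m)
  expect_equal(out2$age_wh, out$age_wh)
})

test_that("model 1 separates shared from independent context effects", {
  set.seed(2)
  n <- 150
  ids <- sprintf("i%03d", 1:n)
  sex <- rep(c("F", "M"), length.out = n)
  # records only at TP2/TP3; context-specific individual latents
  build <- function(rho_shared) {
    sch_tp <- c(2, 2, 2, 3, 3, 3); sch_trial <- c(1, 2, 3, 1, 2, 3)
    shared <- stats::rnorm(n, 0, 1)
    recs <- do.call(rbind, lapply(seq_len(n), function(i) {
      uctx <- if (rho_shared) rep(shared[i], 3)
      else stats::rnorm(3, 0, 1) # independent latent per context
      names(uctx) <- c("S", "F", "O")
      sch_ctx <- c(sample(c("S", "F", "O")), sample(c("S", "F", "O")))
      data.frame(id = ids[i], sex = sex[i],
                 generation = if (i <= n / 2) "F1" else "F2",
                 time_point = sch_tp, trial = sch_trial, context = sch_ctx,
                 raw_seconds = 150 + 60 * (uctx[sch_ctx] +
                                             stats::rnorm(6, 0, 0.6)),
                 stringsAsFactors = FALSE)
    }))
    recs$raw_seconds <- pmin(pmax(recs$raw_seconds, 1), 300)
    recs$censored <- recs$raw_seconds >= 300
    recs$body_size <- 0
    recs$survived_tp4 <- TRUE
    ped <- rbind(
      data.frame(id = c("SIRE0", "DAM0"), sire = NA_character_,
                 dam = NA_character_, sex = c("M", "F"), generation = "P"),
      data.frame(id = ids, sire = "SIRE0", dam = "DAM0", sex = sex,
                 generation = recs$generation[match(ids, recs$id)]))
    load_study(ped, recs)
  }
  f_shared <- fit_model1(build(TRUE), control = quick_ctl, seed = 1)
  r_shared <- genetic_correlations(f_shared, term = "id")$table
  expect_true(all(r_shared$median > 0.9))
  expect_equal(ncol(f_shared$draws$vc$id), 6) # 3 variances + 3 covariances
  f_indep <- fit_model1(build(FALSE), control = quick_ctl, seed = 1)
  r_indep <- genetic_correlations(f_indep, term = "id")$table
  expect_true(all(abs(r_indep$median) < 0.15))
})

test_that("model 2 variants carry the documented blocks and recover structure", {
  set.seed(3)
  n <- 160
  ids <- sprintf("i%03d", 1:n)
  sex <- rep("F", n)
  # permanent-environment variance only at age 2
  u2 <- stats::rnorm(n, 0, 1)
  lat <- cbind(0, u2, 0, 0)
  sdy <- manual_study(ids, sex, lat, noise_sd = 0.6, seed = 4)
  f2a <- fit_model2(sdy, "F", "a", control = quick_ctl, seed = 1)
  expect_named(f2a$draws$vc, "id")
  R <- repeatability(f2a, "short_age_specific")
  expect_gt(R$median[2], 0.5)
  expect_true(all(R$median[c(1, 3, 4)] < 0.25))
  # variant b: strong overall individual effect dominates the age-specific one
  u0 <- stats::rnorm(n, 0, 1)
  lat_b <- cbind(u0, u0, u0, u0)
  sdy_b <- manual_study(ids, sex, lat_b, noise_sd = 0.6, seed = 5)
  f2b <- fit_model2(sdy_b, "F", "b", control = quick_ctl, seed = 1)
  expect_named(f2b$draws$vc, c("id", "id_overall"))
  v0 <- stats::median(vc_elem(f2b, "id_overall", "u"))
  vage <- sapply(as.character(1:4), function(a)
    stats::median(vc_elem(f2b, "id", a)))
  expect_true(all(v0 > vage))
  expect_error(repeatability(f2a, "long_term"), "variant-b")
  expect_error(repeatability(f2b, "short_age_specific"), "variant-a")
})

test_that("model 3b detects a negative male size slope and calibrates under the null", {
  des <- breeding_design(n_sires_P = 25, dams_per_sire = 2, n_sires_F1 = 8,
                         n_dams_F1 = 16, fixed_brood = 4)
  pars_neg <- sim_params(beta = within(sim_params()$beta,
                                       size <- c(F = 0, M = -0.3)))
  st <- simulate_study(des, pars_neg, seed = 6)
  f <- fit_model3b(as_study(st), "M", control = quick_ctl, seed = 1)
  est <- post_est(f$draws$fixed[, "size_std"])
  expect_lt(est$pmcmc, 0.05)
  expect_lt(est$median, 0)
  # null calibration: slope 0, >= 8/10 seeds non-significant
  hits <- 0L
  for (s in 1:10) {
    st0 <- simulate_study(des, sim_params(), seed = 200 + s)
    f0 <- fit_model3b(as_study(st0), "M",
                      control = chain_control(nitt = 2500, burnin = 500,
                                              thin = 5), seed = 1)
    if (post_est(f0$draws$fixed[, "size_std"])$pmcmc > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
  # constant size is rejected
  sdy <- as_study(st)
  sdy$data$body_size <- 1
  expect_error(fit_model3b(sdy, "M", control = quick_ctl), "constant")
})

test_that("model 3c separates selective disappearance from plasticity", {
  set.seed(7)
  n <- 160
  ids <- sprintf("i%03d", 1:n)
  sex <- rep("M", n)
  # (a) constructed dropout of low-latent (bold) individuals, no within-
  # individual change: between-individual age effect without plasticity
  b <- stats::rnorm(n, 0, 1)
  lat <- cbind(b, b, b, b)
  ord <- order(b) # lowest latent = boldest dies first
  last <- rep(4L, n); last[ord[1:25]] <- 1L; last[ord[26:50]] <- 2L
  last[ord[51:75]] <- 3L
  sdy_drop <- manual_study(ids, sex, lat, noise_sd = 0.4, last_tp = last,
                           seed = 8)
  f_drop <- fit_model3c(sdy_drop, "M", control = quick_ctl, seed = 1)
  dis <- f_drop$disappearance
  expect_lt(dis$pmcmc[dis$effect == "age_m (between-individual)"], 0.05)
  expect_gt(dis$pmcmc[dis$effect == "age_wh (plasticity)"], 0.05)
  expect_lt(dis$pmcmc[grep("selective", dis$effect)], 0.05)
  # (b) pure within-individual decline with random dropout
  b2 <- stats::rnorm(n, 0, 0.6)
  lat2 <- outer(b2, rep(1, 4)) + outer(rep(1, n), c(0, 0.35, 0.7, 1.05))
  last2 <- rep(4L, n)
  last2[sample(n, 75)] <- sample(1:3, 75, replace = TRUE)
  sdy_pl <- manual_study(ids, sex, lat2, noise_sd = 0.4, last_tp = last2,
                         seed = 9)
  f_pl <- fit_model3c(sdy_pl, "M", control = quick_ctl, seed = 1)
  dis2 <- f_pl$disappearance
  expect_lt(dis2$pmcmc[dis2$effect == "age_wh (plasticity)"], 0.05)
  expect_gt(dis2$pmcmc[grep("selective", dis2$effect)], 0.05)
  # (c) null calibration: random (non-selective) dropout, no trend
  hits <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    b0 <- stats::rnorm(n, 0, 0.6)
    last0 <- rep(4L, n)
    last0[sample(n, 60)] <- sample(1:3, 60, replace = TRUE)
    sdy0 <- manual_study(ids, sex, outer(b0, rep(1, 4)), noise_sd = 0.4,
                         last_tp = last0, seed = 400 + s)
    f0 <- fit_model3c(sdy0, "M",
                      control = chain_control(nitt = 2500, burnin = 500,
                                              thin = 5), seed = 1)
    d0 <- f0$disappearance
    if (d0$pmcmc[grep("selective", d0$effect)] > 0.05 &&
        d0$pmcmc[d0$effect == "age_wh (plasticity)"] > 0.05)
      hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("model 4 contracts: blocks, degeneracy flag, missing-trial error", {
  des <- breeding_design(n_sires_P = 20, dams_per_sire = 2, n_sires_F1 = 6,
                         n_dams_F1 = 12, fixed_brood = 4)
  st <- simulate_study(des, seed = 10)
  sdy <- as_study(st)
  f4 <- fit_model4(sdy, "both", control = quick_ctl, seed = 1)
  expect_equal(ncol(f4$draws$vc$animal), 3) # 2 variances + 1 covariance
  expect_true(all(c("var_gauss", "cov_gauss_binary") %in%
                    colnames(f4$draws$resid)))
  # residual correlation is bounded by the fixed binary variance
  r <- f4$draws$resid
  expect_true(all(r[, "cov_gauss_binary"]^2 < r[, "var_gauss"]))
  # all-survivors degeneracy is flagged
  pinf <- sim_params(survival = list(intercept = 50, V_A = 0.5, cov_A = 0,
                                     weights = c(23, 56, 54) / 133))
  sti <- simulate_study(des, pinf, seed = 11)
  expect_warning(fit_model4(as_study(sti), "both", control = quick_ctl,
                            seed = 1), "degeneracy")
})

test_that("added structure absorbs rather than creates individual variance", {
  fx <- fixture_study(seed = 3)
  sdy <- as_study(fx)
  ctl <- chain_control(nitt = 3000, burnin = 600, thin = 5)
  f2a <- fit_model2(sdy, "F", "a", control = ctl, seed = 1)
  f2b <- fit_model2(sdy, "F", "b", control = ctl, seed = 1)
  tot_a <- mean(sapply(as.character(1:4), function(a)
    mean(vc_elem(f2a, "id", a))))
  tot_b <- mean(vc_elem(f2b, "id_overall", "u")) +
    mean(sapply(as.character(1:4), function(a) mean(vc_elem(f2b, "id", a))))
  expect_gte(tot_b, tot_a - 0.1)
})
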