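test_that("hpd: brute-force window oracle, constants, and asymptotics", {
  expect_equal(hpd(rep(3.5, 30)), c(3.5, 3.5))
  expect_equal(hpd(1:100, 0.95), c(1, 95))
  # independent brute force over all contiguous windows of sorted draws
  hpd_brute <- function(x, prob) {
    s <- sort(x); n <- length(s); m <- ceiling(prob * n)
    best <- c(Inf, NA, NA)
    for (st in seq_len(n - m + 1)) {
      w <- s[st + m - 1] - s[st]
      if (w < best[1]) best <- c(w, s[st], s[st + m - 1])
    }
    best[2:3]
  }
  set.seed(5)
  for (i in 1:10) {
    x <- stats::rexp(80 + i * 7)
    expect_equal(hpd(x, 0.9), hpd_brute(x, 0.9))
  }
  set.seed(6)
  z <- stats::rnorm(100000)
  h <- hpd(z)
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)
  expect_error(hpd(1:10), "20 draws")
  # interval always contains the median; coverage shrinks monotonically
  set.seed(7)
  x <- stats::rgamma(500, 2)
  for (p in c(0.5, 0.8, 0.95)) {
    h <- hpd(x, p)
    expect_true(h[1] <= stats::median(x) && stats::median(x) <= h[2])
  }
  w <- sapply(c(0.5, 0.8, 0.95), function(p) diff(hpd(x, p)))
  expect_true(all(diff(w) > 0))
})

test_that("pmode finds the density peak", {
  expect_equal(pmode(rep(-2, 25)), -2)
  set.seed(8)
  expect_lt(abs(pmode(stats::rnorm(100000))), 0.05)
  mix <- c(stats::rnorm(30000, 0, 0.1), stats::rnorm(70000, 2, 0.1))
  expect_lt(abs(pmode(mix) - 2), 0.1)
  expect_error(pmode(1:5), "20 draws")
})

test_that("pmcmc implements the floored two-tailed sign rule", {
  expect_equal(pmcmc(rep(1, 1000)), 0.002)
  expect_equal(pmcmc(c(rep(1, 600), rep(-1, 400))), 0.8)
  expect_equal(pmcmc(c(rep(1, 500), rep(-1, 500))), 1.0)
})

test_that("heritability and maternal ratios are exact on constant draws", {
  fit <- fake_fit_3a(VA = rep(2, 4), VM = rep(1, 4), VID = rep(1, 4),
                     VR = rep(4, 4))
  hs <- heritability_series(fit)
  expect_equal(hs$h2$median, rep(0.25, 4))
  expect_equal(hs$m2$median, rep(0.125, 4))
  # degenerate partition: V_A only
  fit1 <- fake_fit_3a(VA = rep(3, 4), VM = rep(0, 4), VID = rep(0, 4),
                      VR = rep(0, 4))
  expect_equal(heritability_series(fit1)$h2$median, rep(1, 4))
})

test_that("variance shares sum to one per draw on a real fit", {
  fx <- fixture_study(seed = 2)
  sdy <- as_study(fx)
  fit <- fit_model3a(sdy, "M",
                     control = chain_control(nitt = 1500, burnin = 300,
                                             thin = 10), seed = 1)
  for (a in as.character(1:4)) {
    va <- vc_elem(fit, "animal", a); vm <- vc_elem(fit, "mother", a)
    vid <- vc_elem(fit, "id", a)
    vr <- fit$draws$resid[, paste0("age_class", a)]
    vp <- va + vm + vid + vr
    shares <- va / vp + vm / vp + vid / vp + vr / vp
    expect_equal(shares, rep(1, length(shares)))
    h2 <- va / vp
    expect_true(all(h2 >= 0 & h2 <= 1))
  }
})

test_that("repeatability formulas on constant draws", {
  fit <- fake_fit_3a(VA = rep(0, 4), VM = rep(0, 4), VID = rep(1, 4),
                     VR = rep(3, 4))
  R <- repeatability(fit, "short_age_specific")
  expect_equal(R$median, rep(0.25, 4))
  # zero overall individual variance gives long-term R = 0
  fitb <- fake_fit_3a(VA = rep(0, 4), VM = rep(0, 4), VID = rep(1, 4),
                      VR = rep(3, 4))
  fitb$draws$vc$id_overall <- matrix(0, 25, 1, dimnames = list(NULL, "u:u"))
  fitb$terms <- c(fitb$terms, list(list(name = "id_overall", q = 10, d = 1,
                                        trait_labels = "u", pedigree = FALSE)))
  expect_equal(repeatability(fitb, "long_term")$median, 0)
})

test_that("genetic correlations: exact values and the identity diagonal", {
  fit <- fake_fit_3a(VA = rep(1, 4), VM = rep(0, 4), VID = rep(0, 4),
                     VR = rep(1, 4), covA = 0.5)
  gc_ <- genetic_correlations(fit)
  expect_equal(gc_$table$median, rep(0.5, 6))
  expect_equal(gc_$n_skipped, 0)
  # same-trait correlation is exactly 1
  va <- vc_elem(fit, "animal", "1")
  expect_equal(vc_elem(fit, "animal", "1", "1") / va, rep(1, 25))
})

test_that("genotype-by-sex/age contrasts behave on identical and shifted draws", {
  f1 <- fake_fit_3a(VA = rep(1, 4), VM = rep(0, 4), VID = rep(0, 4),
                    VR = rep(1, 4))
  g_same <- gxs_gxa_tests(f1, f1)
  expect_equal(g_same$median, rep(0, 4))
  expect_equal(g_same$pmcmc, rep(1, 4))
  f2 <- fake_fit_3a(VA = rep(2, 4), VM = rep(0, 4), VID = rep(0, 4),
                    VR = rep(1, 4))
  g_diff <- gxs_gxa_tests(f2, f1)
  expect_equal(g_diff$median, rep(1, 4))
  # within-fit age differences on equal variances are zero
  g_within <- gxs_gxa_tests(f1)
  expect_equal(g_within$median, rep(0, 6))
  # draw-length mismatch truncates with a warning
  f3 <- f1
  f3$draws$vc$animal <- f3$draws$vc$animal[1:20, ]
  expect_warning(gxs_gxa_tests(f1, f3), "truncating")
})

test_that("age contrasts apply the Holm step-down correctly", {
  # the step-down rule on the worked example
  expect_equal(stats::p.adjust(c(0.01, 0.03, 0.04), method = "holm"),
               c(0.03, 0.06, 0.06))
  # construct fixed-effect draws with a known age-2 shift only
  set.seed(12)
  nd <- 800
  fx <- cbind(stats::rnorm(nd, 1.2, 0.25), stats::rnorm(nd, 0.02, 0.25),
              stats::rnorm(nd, 0.01, 0.25))
  colnames(fx) <- paste0("age_class", 2:4)
  fit <- list(draws = list(fixed = fx))
  class(fit) <- "ammc"
  ac <- age_contrasts(fit)
  expect_equal(nrow(ac), 6)
  # Holm-adjusted values are >= raw and the rule matches p.adjust
  expect_true(all(ac$pmcmc_holm >= ac$pmcmc))
  expect_equal(sort(ac$pmcmc_holm),
               sort(unname(stats::p.adjust(ac$pmcmc, "holm"))))
  sig <- ac$pair[ac$pmcmc_holm < 0.05]
  expect_true(all(c("1-2", "2-3", "2-4") %in% sig))
  expect_false(any(c("1-3", "1-4", "3-4") %in% sig))
  # identical draws across ages: all contrasts 0, adjusted p = 1
  fx0 <- matrix(0, 50, 3, dimnames = list(NULL, paste0("age_class", 2:4)))
  fit0 <- list(draws = list(fixed = fx0)); class(fit0) <- "ammc"
  ac0 <- age_contrasts(fit0)
  expect_equal(ac0$median, rep(0, 6))
  expect_equal(ac0$pmcmc_holm, rep(1, 6))
})

test_that("survival association formulas are exact on constant draws", {
  mk_fit4 <- function(vab, vas, cova, vrb, covr, nd = 25) {
    vc <- matrix(rep(c(vab, cova, vas), each = nd), nd, 3)
    colnames(vc) <- c("bold:bold", "surv:bold", "surv:surv")
    rs <- matrix(rep(c(vrb, covr), each = nd), nd, 2)
    colnames(rs) <- c("var_gauss", "cov_gauss_binary")
    structure(list(draws = list(vc = list(animal = vc), resid = rs),
                   terms = list(list(name = "animal", q = 5, d = 2,
                                     trait_labels = c("bold", "surv"),
                                     pedigree = TRUE))),
              class = "ammc")
  }
  # zero covariances: all associations zero
  f0 <- mk_fit4(1, 1, 0, 1, 0)
  sa0 <- survival_assoc(f0)
  expect_equal(sa0$r_A$median, 0)
  expect_equal(sa0$r_P$median, 0)
  expect_equal(sa0$b$median, 0)
  # cov_A = 0.4 with unit additive variances: r_A = 0.4
  f1 <- mk_fit4(1, 1, 0.4, 1, 0)
  sa1 <- survival_assoc(f1)
  expect_equal(sa1$r_A$median, 0.4)
  expect_equal(sa1$h2_survival$median, 0.5)
  expect_equal(sa1$r_P$median, 0.4 / sqrt(2 * 2))
  expect_equal(sa1$b$median, 0.2)
})
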