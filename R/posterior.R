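#' Highest posterior density interval
#'
#' Shortest contiguous interval of the sorted draws containing
#' `ceiling(prob * N)` draws; ties are broken by the lowest start.
#'
#' @param draws numeric vector (at least 20 draws).
#' @param prob target coverage (default 0.95).
#' @return `c(lower, upper)`.
#' @export
hpd <- function(draws, prob = 0.95) {
  n <- length(draws)
  if (n < 20) stop("need at least 20 draws for an HPD interval")
  s <- sort(draws)
  m <- ceiling(prob * n)
  if (m >= n) return(c(s[1], s[n]))
  starts <- seq_len(n - m + 1)
  widths <- s[starts + m - 1] - s[starts]
  i <- which.min(widths) # which.min takes the first (lowest start) on ties
  c(s[i], s[i + m - 1])
}

#' Posterior mode
#'
#' Argmax of a Gaussian kernel density estimate (Silverman's rule-of-thumb
#' bandwidth, 512-point grid spanning the draw range).
#'
#' @inheritParams hpd
#' @export
pmode <- function(draws) {
  n <- length(draws)
  if (n < 20) stop("need at least 20 draws for a mode estimate")
  if (max(draws) == min(draws)) return(draws[1])
  d <- stats::density(draws, bw = "nrd0", n = 512,
                      from = min(draws), to = max(draws))
  d$x[which.max(d$y)]
}

#' MCMC sign probability (pMCMC)
#'
#' Twice the smaller tail probability around zero, floored at the chain
#' resolution: `min(1, 2 * max(1/N, min(#draws >= 0, #draws <= 0) / N))`.
#' Draws exactly at zero count in both tails, so a quantity that is
#' identically zero gets p = 1. Meaningful for signed quantities only.
#'
#' @inheritParams hpd
#' @export
pmcmc <- function(draws) {
  n <- length(draws)
  npos <- sum(draws >= 0); nneg <- sum(draws <= 0)
  min(1, 2 * max(1 / n, min(npos, nneg) / n))
}

#' Effective sample size
#'
#' `N / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated by the
#' initial-positive-sequence rule (summation stops when a consecutive pair of
#' autocorrelations turns negative). A constant vector gets ESS 0 with a
#' `degenerate` attribute.
#'
#' @param x numeric vector of at least 10 draws.
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 10) stop("need at least 10 draws")
  if (stats::var(x) == 0)
    return(structure(0, degenerate = TRUE))
  lag_max <- min(n - 1, 2000)
  rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)[-1]
  # Geyer initial positive sequence on paired sums rho_{2m-1} + rho_{2m}
  s <- 0
  m <- 1
  while (m < length(rho)) {
    g <- rho[m] + if (m + 1 <= length(rho)) rho[m + 1] else 0
    if (g <= 0) break
    s <- s + g
    m <- m + 2
  }
  ess <- n / (1 + 2 * s)
  structure(min(ess, n), degenerate = FALSE)
}

#' Convergence report for a fitted model
#'
#' Computes the effective sample size of every stored fixed effect,
#' covariance element and residual parameter and compares it with a floor.
#'
#' @param fit an [ammc()] fit.
#' @param ess_floor minimum acceptable ESS (0 disables the check).
#' @return list with `table` (term, ess, pass) and overall `pass`.
#' @export
check_convergence <- function(fit, ess_floor = 1000) {
  M <- as.matrix(fit)
  ess <- apply(M, 2, function(col) as.numeric(effective_size(col)))
  keep <- apply(M, 2, function(col) stats::var(col) > 0) # fixed-at-1 params
  tab <- data.frame(term = colnames(M), ess = ess,
                    pass = ess >= ess_floor | !keep,
                    row.names = NULL)
  list(table = tab, pass = all(tab$pass))
}

#' Posterior summary of a scalar quantity
#'
#' Median, kernel-density mode, 95% HPD interval and (for signed quantities)
#' pMCMC, computed from the draws of any scalar derived quantity.
#'
#' @param draws numeric vector of posterior draws.
#' @param signed whether a sign test (pMCMC) is meaningful.
#' @param prob HPD coverage.
#' @return one-row data.frame `median, mode, hpd_low, hpd_high, pmcmc`.
#' @export
post_est <- function(draws, signed = TRUE, prob = 0.95) {
  h <- hpd(draws, prob)
  data.frame(median = stats::median(draws), mode = pmode(draws),
             hpd_low = h[1], hpd_high = h[2],
             pmcmc = if (signed) pmcmc(draws) else NA_real_)
}

# ---- accessors into the labelled draws of an ammc fit ----

vc_term_ <- function(fit, term) {
  m <- fit$draws$vc[[term]]
  if (is.null(m)) stop("no random term '", term, "' in this fit")
  m
}

#' Draws of one element of a covariance block
#'
#' @param fit an [ammc()] fit; @param term random-term name;
#' @param a,b trait labels (order irrelevant).
#' @export
vc_elem <- function(fit, term, a, b = a) {
  m <- vc_term_(fit, term)
  lab <- paste0(a, ":", b)
  lab2 <- paste0(b, ":", a)
  if (lab %in% colnames(m)) m[, lab]
  else if (lab2 %in% colnames(m)) m[, lab2]
  else stop("no element ", lab, " in term '", term, "'")
}

resid_elem_ <- function(fit, label) {
  m <- fit$draws$resid
  if (!label %in% colnames(m))
    stop("no residual class '", label, "'; have: ",
         paste(colnames(m), collapse = ", "))
  m[, label]
}

#' Age-specific heritability and maternal-effect series
#'
#' From an age-specific animal-model fit (individual + animal + mother random
#' terms across age classes, age-heterogeneous residuals): per draw and age
#' class j, `h2_j = V_A,j / (V_A,j + V_M,j + V_ID,j + V_R,j)` and analogously
#' `m2_j`; each ratio is computed per draw and then summarized, so posterior
#' uncertainty propagates into the summaries.
#'
#' @param fit model-3a style [ammc()] fit.
#' @param ages trait labels of the age classes (default the animal term's).
#' @return list of data.frames `h2` and `m2`, one row per age class, plus
#'   `draws` (per-draw ratio matrices).
#' @export
heritability_series <- function(fit, ages = NULL) {
  tl <- fit$terms[[which(vapply(fit$terms, `[[`, "", "name") == "animal")]]$trait_labels
  if (is.null(ages)) ages <- tl
  rn <- colnames(fit$draws$resid)
  h2d <- m2d <- NULL
  out_h <- out_m <- NULL
  for (j in seq_along(ages)) {
    a <- ages[j]
    va <- vc_elem(fit, "animal", a)
    vm <- vc_elem(fit, "mother", a)
    vid <- vc_elem(fit, "id", a)
    vr <- fit$draws$resid[, grep(paste0(a, "$"), rn)[1]]
    vp <- va + vm + vid + vr
    h2 <- va / vp; m2 <- vm / vp
    h2d <- cbind(h2d, h2); m2d <- cbind(m2d, m2)
    out_h <- rbind(out_h, cbind(age = a, post_est(h2, signed = FALSE)))
    out_m <- rbind(out_m, cbind(age = a, post_est(m2, signed = FALSE)))
  }
  colnames(h2d) <- colnames(m2d) <- ages
  list(h2 = out_h, m2 = out_m, draws = list(h2 = h2d, m2 = m2d))
}

#' Repeatability estimates
#'
#' Variance-partitioning repeatabilities on three time scales:
#' `short_age_specific` (from an age-specific-ID fit, model 2a):
#' `R_j = V_ID,j / (V_ID,j + V_R,j)`; `short_cross_age` (model 2b, which adds
#' an overall cross-age individual effect): `R_j = (V_ID + V_ID,j) /
#' (V_ID + V_ID,j + V_R,j)`; `long_term` (model 2b):
#' `R = V_ID / (V_ID + mean_j V_ID,j + mean_j V_R,j)`.
#'
#' @param fit model-2 style [ammc()] fit; variant b fits carry both an
#'   age-specific term `id` and an overall term `id_overall`.
#' @param kind which repeatability.
#' @return data.frame of summaries (one row per age class, or a single row
#'   for `long_term`).
#' @export
repeatability <- function(fit, kind = c("short_age_specific",
                                        "short_cross_age", "long_term")) {
  kind <- match.arg(kind)
  nm <- vapply(fit$terms, `[[`, "", "name")
  has_overall <- "id_overall" %in% nm
  idt <- fit$terms[[which(nm == "id")]]
  ages <- idt$trait_labels
  rn <- colnames(fit$draws$resid)
  vrj <- sapply(ages, function(a) fit$draws$resid[, grep(paste0(a, "$"), rn)[1]])
  vidj <- sapply(ages, function(a) vc_elem(fit, "id", a))
  if (kind == "short_age_specific") {
    if (has_overall)
      stop("short_age_specific repeatability uses the variant-a fit")
    out <- NULL
    for (j in seq_along(ages)) {
      r <- vidj[, j] / (vidj[, j] + vrj[, j])
      out <- rbind(out, cbind(age = ages[j], post_est(r, signed = FALSE)))
    }
    return(out)
  }
  if (!has_overall)
    stop(kind, " repeatability needs the variant-b fit (overall ID term)")
  vid0 <- vc_elem(fit, "id_overall", "u")
  if (kind == "short_cross_age") {
    out <- NULL
    for (j in seq_along(ages)) {
      r <- (vid0 + vidj[, j]) / (vid0 + vidj[, j] + vrj[, j])
      out <- rbind(out, cbind(age = ages[j], post_est(r, signed = FALSE)))
    }
    return(out)
  }
  r <- vid0 / (vid0 + rowMeans(vidj) + rowMeans(vrj))
  cbind(age = "all", post_est(r, signed = FALSE))
}

#' Cross-age genetic correlations
#'
#' Per draw, `r_A(j, j') = cov_A(j, j') / sqrt(V_A,j V_A,j')`; draws in which
#' either variance is zero are skipped and counted.
#'
#' @param fit model-3a style [ammc()] fit; @param term random term name.
#' @return list: `table` (one row per age pair with summaries), `draws`
#'   (matrix of per-draw correlations), `n_skipped`.
#' @export
genetic_correlations <- function(fit, term = "animal") {
  tl <- fit$terms[[which(vapply(fit$terms, `[[`, "", "name") == term)]]$trait_labels
  d <- length(tl)
  out <- NULL; drw <- NULL; skipped <- 0L
  for (j in seq_len(d - 1)) for (jp in (j + 1):d) {
    va <- vc_elem(fit, term, tl[j])
    vb <- vc_elem(fit, term, tl[jp])
    cab <- vc_elem(fit, term, tl[j], tl[jp])
    ok <- va > 0 & vb > 0
    skipped <- skipped + sum(!ok)
    r <- cab[ok] / sqrt(va[ok] * vb[ok])
    out <- rbind(out, cbind(pair = paste0(tl[j], "-", tl[jp]),
                            post_est(r, signed = TRUE)))
    rr <- rep(NA_real_, length(va)); rr[ok] <- r
    drw <- cbind(drw, rr)
  }
  colnames(drw) <- out$pair
  list(table = out, draws = drw, n_skipped = skipped)
}

#' Genotype-by-sex / genotype-by-age variance contrasts
#'
#' With two fits (one per sex), computes per age class the paired-draw
#' difference `V_A(fit1) - V_A(fit2)`; with a single fit, the within-fit
#' differences `V_A(j) - V_A(j')` across age classes. Draws are paired by
#' index; unequal chain lengths are truncated to the shorter with a warning.
#' An interaction is supported when the HPD interval of a difference excludes
#' zero.
#'
#' @param fit1,fit2 [ammc()] fits; @param term random-term name.
#' @return data.frame of contrast summaries (median, mode, HPD, pMCMC).
#' @export
gxs_gxa_tests <- function(fit1, fit2 = NULL, term = "animal") {
  tl <- fit1$terms[[which(vapply(fit1$terms, `[[`, "", "name") == term)]]$trait_labels
  out <- NULL
  if (!is.null(fit2)) {
    n1 <- nrow(vc_term_(fit1, term)); n2 <- nrow(vc_term_(fit2, term))
    if (n1 != n2)
      warning("draw lengths differ; truncating to ", min(n1, n2))
    n <- min(n1, n2)
    for (a in tl) {
      d <- vc_elem(fit1, term, a)[seq_len(n)] -
        vc_elem(fit2, term, a)[seq_len(n)]
      out <- rbind(out, cbind(contrast = paste0("age", a), post_est(d)))
    }
  } else {
    dd <- length(tl)
    for (j in seq_len(dd - 1)) for (jp in (j + 1):dd) {
      d <- vc_elem(fit1, term, tl[j]) - vc_elem(fit1, term, tl[jp])
      out <- rbind(out, cbind(contrast = paste0(tl[j], "-", tl[jp]),
                              post_est(d)))
    }
  }
  out
}

#' Pairwise age contrasts of the fixed age effects, Holm-adjusted
#'
#' Differences of the age-class means per draw (reference age included as 0),
#' pMCMC per pair, and the Holm-Bonferroni step-down adjustment over the
#' m = 6 pairs (via [stats::p.adjust()]).
#'
#' @param fit an [ammc()] fit with a 4-level age factor among the fixed
#'   effects.
#' @param prefix name of the age factor in the fixed-effect columns
#'   (default "age_class").
#' @return data.frame: pair, median, HPD, raw and Holm-adjusted pMCMC.
#' @export
age_contrasts <- function(fit, prefix = "age_class") {
  fx <- fit$draws$fixed
  cols <- grep(paste0("^", prefix), colnames(fx), value = TRUE)
  if (!length(cols)) stop("no fixed-effect columns matching '", prefix, "'")
  levs <- sub(paste0("^", prefix), "", cols)
  means <- cbind(0, fx[, cols, drop = FALSE]) # reference level first
  labs <- c(setdiff(as.character(1:9), levs)[1], levs)
  out <- NULL
  praw <- c()
  d <- ncol(means)
  for (j in seq_len(d - 1)) for (jp in (j + 1):d) {
    diff <- means[, jp] - means[, j]
    est <- post_est(diff)
    out <- rbind(out, cbind(pair = paste0(labs[j], "-", labs[jp]), est))
    praw <- c(praw, est$pmcmc)
  }
  out$pmcmc_holm <- stats::p.adjust(praw, method = "holm")
  out
}

#' Boldness-survival association summaries from a bivariate fit
#'
#' From a bivariate Gaussian-probit animal model (boldness at the first time
#' point, survival on the liability scale), per draw: survival heritability
#' `h2 = V_A,surv / (V_A,surv + 1)` (probit residual fixed at 1), the additive
#' genetic correlation `r_A = cov_A / sqrt(V_A,bold V_A,surv)`, the phenotypic
#' correlation `r_P = (cov_A + cov_R) / sqrt((V_A,bold + V_R,bold)(V_A,surv +
#' 1))` and the phenotypic regression of boldness on survival
#' `b = (cov_A + cov_R) / (V_A,bold + V_R,bold)`.
#'
#' @param fit model-4 style [ammc()] fit (see [fit_model4()]).
#' @param bold,surv trait labels (defaults `"bold"`, `"surv"`).
#' @return list of one-row summary data.frames `h2_survival, r_A, r_P, b`
#'   plus the per-draw vectors in `draws`.
#' @export
survival_assoc <- function(fit, bold = "bold", surv = "surv") {
  vab <- vc_elem(fit, "animal", bold)
  vas <- vc_elem(fit, "animal", surv)
  cova <- vc_elem(fit, "animal", bold, surv)
  vrb <- resid_elem_(fit, "var_gauss")
  covr <- resid_elem_(fit, "cov_gauss_binary")
  h2s <- vas / (vas + 1)
  ok <- vab > 0 & vas > 0
  ra <- rep(0, length(vab)); ra[ok] <- cova[ok] / sqrt(vab[ok] * vas[ok])
  rp <- (cova + covr) / sqrt((vab + vrb) * (vas + 1))
  b <- (cova + covr) / (vab + vrb)
  list(h2_survival = post_est(h2s, signed = FALSE),
       r_A = post_est(ra), r_P = post_est(rp), b = post_est(b),
       draws = list(h2_survival = h2s, r_A = ra, r_P = rp, b = b))
}
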