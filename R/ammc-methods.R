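#' @export
#' @method print ammc
print.ammc <- function(x, ...) {
  nd <- nrow(x$draws$fixed)
  cat("Bayesian mixed animal model (Gibbs sampler)\n")
  cat("  observations:", x$n_obs, "\n")
  cat("  families:", paste(names(table(x$family)), table(x$family),
                           sep = ":", collapse = ", "), "\n")
  cat("  fixed effects:", x$p, "\n")
  for (t in x$terms)
    cat(sprintf("  random ~%s: %d levels x %d trait(s)%s\n", t$name, t$q, t$d,
                if (t$pedigree) " [pedigree A]" else ""))
  cat("  stored draws:", nd,
      sprintf("(nitt %d, burnin %d, thin %d)\n",
              x$control$nitt, x$control$burnin, x$control$thin))
  if (x$njitter > 0)
    cat("  note:", x$njitter, "jittered/guarded numerical operations\n")
  invisible(x)
}

#' Flatten all stored draws to a labelled matrix
#'
#' Columns: fixed effects, covariance-block elements (prefixed by term name)
#' and residual parameters (prefixed `R.`).
#' @param x an [ammc()] fit.
#' @param ... unused.
#' @export
#' @method as.matrix ammc
as.matrix.ammc <- function(x, ...) {
  parts <- list(x$draws$fixed)
  for (nm in names(x$draws$vc)) {
    m <- x$draws$vc[[nm]]
    colnames(m) <- paste0(nm, ".", colnames(m))
    parts <- c(parts, list(m))
  }
  r <- x$draws$resid
  colnames(r) <- paste0("R.", colnames(r))
  do.call(cbind, c(parts, list(r)))
}

#' Summarize a fitted model
#'
#' Posterior median, mode, 95% HPD and pMCMC for every fixed effect,
#' covariance element and residual parameter, plus effective sample sizes.
#'
#' @param object an [ammc()] fit.
#' @param ess whether to compute effective sample sizes (slower).
#' @param ... unused.
#' @export
#' @method summary ammc
summary.ammc <- function(object, ess = TRUE, ...) {
  sum_block <- function(m, signed) {
    do.call(rbind, lapply(colnames(m), function(cn) {
      cbind(parameter = cn,
            post_est(m[, cn], signed = if (length(signed) == 1) signed
                     else cn %in% signed))
    }))
  }
  fx <- sum_block(object$draws$fixed, TRUE)
  vcs <- lapply(names(object$draws$vc), function(nm) {
    m <- object$draws$vc[[nm]]
    offdiag <- colnames(m)[vapply(strsplit(colnames(m), ":"),
                                  function(s) s[1] != s[2], TRUE)]
    cbind(term = nm, sum_block(m, offdiag))
  })
  names(vcs) <- names(object$draws$vc)
  rs <- sum_block(object$draws$resid,
                  intersect("cov_gauss_binary", colnames(object$draws$resid)))
  esstab <- if (ess) check_convergence(object, ess_floor = 0)$table else NULL
  out <- list(fixed = fx, vc = vcs, resid = rs, ess = esstab,
              control = object$control, n_obs = object$n_obs)
  class(out) <- "summary.ammc"
  out
}

#' @export
#' @method print summary.ammc
print.summary.ammc <- function(x, digits = 3, ...) {
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, digits)
    df
  }
  cat("Fixed effects:\n"); print(fmt(x$fixed), row.names = FALSE)
  for (nm in names(x$vc)) {
    cat("\nCovariance block ~", nm, ":\n", sep = "")
    print(fmt(x$vc[[nm]][, -1]), row.names = FALSE)
  }
  cat("\nResidual:\n"); print(fmt(x$resid), row.names = FALSE)
  if (!is.null(x$ess))
    cat("\nmin effective sample size:", round(min(x$ess$ess)), "\n")
  invisible(x)
}

#' @export
coef.ammc <- function(object, ...) {
  apply(object$draws$fixed, 2, stats::median)
}

#' Posterior-mean linear predictor
#' @param object an [ammc()] fit.
#' @param ... unused; predictions for new data are not supported (the
#'   posterior mean of the location effects is stored, the full draws are
#'   not).
#' @export
predict.ammc <- function(object, ...) object$fitted

#' Marginal residuals (observed minus posterior-mean linear predictor)
#'
#' For right-censored records the observed value is the censoring bound, so
#' their residuals are conservative; binary records get `NA` (their latent
#' liabilities are not part of the observed scale).
#' @inheritParams predict.ammc
#' @export
residuals.ammc <- function(object, ...) {
  r <- object$response - object$fitted
  r[object$famcode == 2L] <- NA_real_
  r
}

#' Trace plots of the covariance draws
#'
#' @param x an [ammc()] fit; @param which regexp selecting columns of
#'   [as.matrix.ammc()] (default: all covariance and residual parameters);
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ammc <- function(x, which = "\\.|^R", ...) {
  M <- as.matrix(x)
  M <- M[, grep(which, colnames(M)), drop = FALSE]
  graphics::matplot(M, type = "l", lty = 1, xlab = "stored iteration",
                    ylab = "value", ...)
  graphics::legend("topright", legend = colnames(M), col = seq_len(ncol(M)),
                   lty = 1, cex = 0.6, bty = "n")
  invisible(x)
}
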