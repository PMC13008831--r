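#' Unstructured-covariance random term
#'
#' Describes one random term of an [ammc()] model: a grouping column in the
#' data (individual identity, dam identity, or the pedigree-linked `animal`
#' term) with either a single variance (`by = NULL`) or an unstructured
#' covariance matrix across the levels of a trait/age-class factor `by`
#' (character-state parameterisation).
#'
#' @param by column name of the trait dimension (e.g. an age-class factor),
#'   or `NULL` for a single variance.
#' @param pedigree if `TRUE` the term's levels are the pedigree individuals
#'   and its covariance across levels is the additive relationship matrix A
#'   (the sampler uses the sparse A-inverse).
#' @param group optional grouping column overriding the term's name in the
#'   `random` list, so the same column can carry several terms (e.g. an
#'   age-specific and an overall individual effect).
#' @param px parameter expansion: adds a redundant working-scale multiplier
#'   per trait to the Gibbs scheme, which greatly improves mixing of variance
#'   blocks near zero and of scale trade-offs between competing terms; the
#'   effective prior on each standard deviation becomes half-t-like with
#'   scale `sqrt(alpha_v)`. Off by default in the engine; the model-suite
#'   constructors switch it on.
#' @param alpha_v prior variance of the working multipliers (default 1000).
#' @return term descriptor used in the `random` list of [ammc()].
#' @export
us <- function(by = NULL, pedigree = FALSE, group = NULL, px = FALSE,
               alpha_v = 1000) {
  structure(list(by = by, pedigree = pedigree, group = group, px = px,
                 alpha_v = alpha_v),
            class = "ammc_term")
}

#' Residual structures
#'
#' `resid_classes(by)` gives independent residuals with a separate variance
#' per level of `by` (heterogeneous; `by = NULL` for a single variance);
#' cross-class residual covariances are zero. Classes consisting of binary
#' (probit) records have their variance fixed at 1 for identification.
#'
#' `resid_bivar(unit)` gives a 2 x 2 unstructured residual covariance across
#' the two records of each level of `unit` (one Gaussian, one binary); the
#' binary diagonal element is fixed at 1 and the Gaussian variance and the
#' covariance are sampled, so a residual (environmental) covariance between
#' the two responses is estimable.
#'
#' @param by,unit column names in the data.
#' @export
resid_classes <- function(by = NULL) {
  structure(list(type = 0L, by = by), class = "ammc_resid")
}

#' @rdname resid_classes
#' @export
resid_bivar <- function(unit) {
  structure(list(type = 1L, unit = unit), class = "ammc_resid")
}

#' Chain controls
#'
#' @param nitt total iterations; @param burnin discarded iterations;
#' @param thin storage stride. The stored draw count is
#'   `floor((nitt - burnin) / thin)`.
#' @export
chain_control <- function(nitt = 50000, burnin = 5000, thin = 10) {
  stopifnot(burnin < nitt, thin >= 1)
  list(nitt = as.integer(nitt), burnin = as.integer(burnin),
       thin = as.integer(thin))
}

# Adler-32 style rolling checksum over a serialized object; cheap digest for
# provenance/manifests (not cryptographic)
adler32_ <- function(x) {
  b <- as.integer(serialize(x, NULL, xdr = TRUE))
  b <- b[-seq_len(14)] # strip header (carries R version)
  n <- length(b)
  MOD <- 65521
  a <- (1 + sum(as.numeric(b))) %% MOD
  s <- (n + sum(as.numeric(b) * (n - seq_len(n) + 1))) %% MOD
  sprintf("%04x%04x", s, a)
}

#' Fit a Bayesian mixed-effects "animal" model by Gibbs sampling
#'
#' The workhorse of the package: a single-chain Gibbs sampler for linear
#' mixed models with arbitrary combinations of iid and pedigree-linked
#' (additive genetic) random terms, each with a single variance or an
#' unstructured covariance matrix across the levels of a trait/age factor,
#' Gaussian / right-censored Gaussian / binary probit responses, and either
#' heterogeneous-by-class or bivariate-unit residual structures. Location
#' effects are drawn as one joint block from their multivariate-normal full
#' conditional via a sparse Cholesky factorization of the mixed-model
#' equations; covariance blocks from inverse-Wishart full conditionals
#' (prior: scale `nu * V`, degrees of freedom `nu`); censored records and
#' binary liabilities from truncated-normal full conditionals.
#'
#' @param fixed two-sided formula; the left-hand side names the (already
#'   scaled) response column.
#' @param data data.frame, one row per observation. Censored-Gaussian models
#'   need a logical `censored` column (TRUE = right-censored at `bound`).
#' @param random named list of [us()] terms; each name is a column of `data`
#'   holding the level labels of that grouping factor.
#' @param resid [resid_classes()] or [resid_bivar()].
#' @param family `"gaussian"`, `"cengaussian"` or `"probit"`, or the name of
#'   a column of `data` giving a per-record family (for multi-response
#'   stacked data).
#' @param bound right-censoring bound on the response scale (scalar or
#'   per-record vector); used for `cengaussian` records.
#' @param pedigree validated pedigree, required when any term has
#'   `pedigree = TRUE`; rows of `data` must then reference pedigree ids.
#' @param prior list with optional elements `G` (named per random term, each
#'   `list(V =, nu =)`) and `R` (`list(V =, nu =, lambda0 =)`). Defaults:
#'   `V` = identity and `nu = 0.002` for every block (weakly informative; a
#'   larger `nu` noticeably shrinks covariance-block correlations toward 0),
#'   residual `V = 1, nu = 0.002`.
#' @param control [chain_control()].
#' @param seed integer seed; identical seeds and inputs give identical draws.
#' @param store_latent store the imputed censored values / liabilities per
#'   saved iteration (memory heavy; for diagnostics on small models).
#' @return object of class `ammc`; see [summary.ammc()].
#' @export
ammc <- function(fixed, data, random = list(), resid = resid_classes(),
                 family = "cengaussian", bound = Inf, pedigree = NULL,
                 prior = list(), control = chain_control(), seed = 1L,
                 store_latent = FALSE) {
  cl <- match.call()
  data <- as.data.frame(data)
  nrec <- nrow(data)
  if (nrec < 1) stop("no observations")

  # ---- response and families ----
  mf <- stats::model.frame(fixed, data, na.action = stats::na.pass)
  y <- as.numeric(stats::model.response(mf))
  if (anyNA(y)) stop("missing values in the response")
  famchr <- if (length(family) == 1 && family %in% names(data))
    as.character(data[[family]]) else rep(match.arg(
      family, c("gaussian", "cengaussian", "probit")), nrec)
  if (!all(famchr %in% c("gaussian", "cengaussian", "probit")))
    stop("unknown response family")
  bound <- rep_len(as.numeric(bound), nrec)
  famcode <- integer(nrec)
  famcode[famchr == "probit"] <- 2L
  if (any(famchr == "cengaussian")) {
    if (is.null(data$censored))
      stop("cengaussian responses need a logical 'censored' column")
    cen <- famchr == "cengaussian" & as.logical(data$censored)
    if (any(cen & !is.finite(bound)))
      stop("censored records need a finite bound")
    famcode[cen] <- 1L
    y[cen] <- bound[cen]
  }
  if (any(famcode == 2L) && !all(y[famcode == 2L] %in% c(0, 1)))
    stop("probit responses must be 0/1")

  # ---- fixed design ----
  tt <- stats::terms(fixed, data = data)
  X <- stats::model.matrix(tt, mf)
  keep <- colSums(abs(X)) > 0
  X <- X[, keep, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    warning("dropping aliased fixed-effect column(s): ",
            paste(drop, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  p <- ncol(X)

  # ---- random terms ----
  nterm <- length(random)
  if (nterm && is.null(names(random)))
    stop("'random' must be a named list (names = grouping columns)")
  Ainv <- NULL
  term_info <- vector("list", nterm)
  offset <- p
  for (k in seq_len(nterm)) {
    tk <- random[[k]]
    if (!inherits(tk, "ammc_term")) stop("random terms must be built with us()")
    tname <- names(random)[k]
    gname <- if (!is.null(tk$group)) tk$group else tname
    gval <- as.character(data[[gname]])
    if (is.null(data[[gname]]) || anyNA(gval))
      stop("grouping column '", gname, "' missing or has NAs")
    if (tk$pedigree) {
      if (is.null(pedigree)) stop("term '", gname, "' needs a pedigree")
      if (is.null(Ainv)) Ainv <- ainverse(pedigree)
      levs <- rownames(Ainv)
      if (!all(gval %in% levs))
        stop("individual(s) in '", gname, "' absent from the pedigree: ",
             paste(utils::head(setdiff(gval, levs), 5), collapse = ", "))
    } else {
      levs <- sort(unique(gval))
    }
    q <- length(levs)
    if (!is.null(tk$by)) {
      byv <- data[[tk$by]]
      if (is.null(byv)) stop("unknown trait factor '", tk$by, "'")
      byf <- factor(byv)
      d <- nlevels(byf)
      tl <- levels(byf)
      ti <- as.integer(byf)
    } else {
      d <- 1L; tl <- "u"; ti <- rep(1L, nrec)
    }
    term_info[[k]] <- list(name = tname, offset = offset, q = q, d = d,
                           levels = levs, trait_labels = tl,
                           level_idx = match(gval, levs), trait_idx = ti,
                           pedigree = tk$pedigree, px = isTRUE(tk$px),
                           alpha_v = tk$alpha_v)
    offset <- offset + q * d
  }
  ncol_all <- offset

  # ---- residual structure ----
  if (!inherits(resid, "ammc_resid")) stop("resid must be a residual spec")
  rtype <- resid$type
  if (rtype == 0L) {
    rcf <- if (is.null(resid$by)) factor(rep("r", nrec)) else factor(data[[resid$by]])
    rclass <- as.integer(rcf) - 1L
    nclass <- nlevels(rcf)
    rfixed <- integer(nclass)
    for (c in seq_len(nclass)) {
      fams <- famcode[rclass == c - 1L]
      if (length(fams) && any(fams == 2L)) {
        if (!all(fams == 2L))
          stop("probit records must form their own residual class")
        rfixed[c] <- 1L
      }
      if (length(fams) && all(fams == 1L))
        warning("all observations censored in residual class '",
                levels(rcf)[c], "'; its variance is weakly identified")
    }
  } else {
    uf <- factor(data[[resid$unit]])
    sp <- split(seq_len(nrec), uf)
    if (any(lengths(sp) != 2L))
      stop("resid_bivar units must have exactly two records each")
    unit_r1 <- unit_r2 <- integer(length(sp))
    for (u in seq_along(sp)) {
      rr <- sp[[u]]
      isb <- famcode[rr] == 2L
      if (sum(isb) != 1L)
        stop("each resid_bivar unit needs one binary and one Gaussian record")
      unit_r1[u] <- rr[!isb]; unit_r2[u] <- rr[isb]
    }
  }

  # ---- design rows (record-major entry list) ----
  ex_rec <- ex_col <- list(); ex_val <- list()
  xi <- which(X != 0, arr.ind = TRUE)
  ex_rec[[1]] <- xi[, 1]; ex_col[[1]] <- xi[, 2]; ex_val[[1]] <- X[xi]
  for (k in seq_len(nterm)) {
    ti <- term_info[[k]]
    ex_rec[[k + 1]] <- seq_len(nrec)
    ex_col[[k + 1]] <- ti$offset + (ti$trait_idx - 1L) * ti$q + ti$level_idx
    ex_val[[k + 1]] <- rep(1, nrec)
  }
  erec <- unlist(ex_rec); ecol <- unlist(ex_col); eval_ <- unlist(ex_val)
  o <- order(erec, ecol)
  erec <- erec[o]; ecol <- ecol[o]; eval_ <- eval_[o]
  w_ptr <- c(0L, cumsum(tabulate(erec, nbins = nrec)))
  w_col <- ecol - 1L
  w_val <- eval_

  # ---- C pattern ----
  Wsp <- Matrix::sparseMatrix(i = erec, j = ecol, x = 1,
                              dims = c(nrec, ncol_all))
  if (rtype == 0L) {
    Cdat <- Matrix::crossprod(Wsp)
  } else {
    Bu <- Matrix::sparseMatrix(i = c(unit_r1, unit_r2),
                               j = c(seq_along(unit_r1), seq_along(unit_r2)),
                               x = 1, dims = c(nrec, length(unit_r1)))
    Cdat <- Matrix::crossprod(Wsp, Matrix::tcrossprod(Bu) %*% Wsp)
  }
  blocks <- list(Matrix::Diagonal(p))
  for (k in seq_len(nterm)) {
    ti <- term_info[[k]]
    Kpat <- if (ti$pedigree) abs(Ainv) else Matrix::Diagonal(ti$q)
    blocks[[k + 1]] <- kronecker(matrix(1, ti$d, ti$d), Kpat)
  }
  Cpr <- Matrix::bdiag(blocks)
  Cfull <- methods::as(methods::as(
    abs(Cdat) + abs(Cpr), "generalMatrix"), "CsparseMatrix")
  Cfull <- Matrix::drop0(Cfull)
  ncnz <- length(Cfull@x)
  keyC <- as.numeric(Cfull@i) +
    as.numeric(rep(seq_len(ncol_all) - 1L, diff(Cfull@p))) * ncol_all
  lookupC <- function(i0, j0) { # 0-based row/col -> 0-based index into Cx
    idx <- match(as.numeric(i0) + as.numeric(j0) * ncol_all, keyC)
    if (anyNA(idx)) stop("internal: C pattern lookup failed")
    idx - 1L
  }

  # ---- symbolic factorization ----
  C0 <- Cfull + Matrix::Diagonal(ncol_all, Matrix::rowSums(Cfull) + 1)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(C0), perm = TRUE,
                         LDL = FALSE, super = FALSE)
  ex <- Matrix::expand(ch)
  Lpat <- methods::as(ex$L, "CsparseMatrix")
  pivec <- ch@perm # 0-based: permuted slot k holds original index perm[k]
  invp <- integer(ncol_all); invp[pivec + 1L] <- seq_len(ncol_all) - 1L
  Lp <- Lpat@p; Li <- Lpat@i
  stopifnot(all(Li[Lp[-length(Lp)] + 1L] == seq_len(ncol_all) - 1L))
  # row lists: for each row j of L, the (col k < j, storage pos) pairs
  lcol <- rep(seq_len(ncol_all) - 1L, diff(Lp))
  offd <- Li != lcol
  rl_row <- Li[offd]; rl_col <- lcol[offd]; rl_posv <- which(offd) - 1L
  o2 <- order(rl_row, rl_col)
  rl_ptr <- c(0L, cumsum(tabulate(rl_row + 1L, nbins = ncol_all)))
  rl_k <- rl_col[o2]; rl_pos <- rl_posv[o2]
  # column map: permuted-lower entries of C per permuted column
  ci <- Cfull@i; cj <- rep(seq_len(ncol_all) - 1L, diff(Cfull@p))
  pr <- invp[ci + 1L]; pc <- invp[cj + 1L]
  low <- pr >= pc
  cm_rowv <- pr[low]; cm_colv <- pc[low]; cm_idxv <- which(low) - 1L
  o3 <- order(cm_colv, cm_rowv)
  cm_ptr <- c(0L, cumsum(tabulate(cm_colv + 1L, nbins = ncol_all)))
  cm_row <- cm_rowv[o3]; cm_idx <- cm_idxv[o3]

  # ---- scatter maps ----
  spl <- split(seq_along(erec), erec)
  stopifnot(length(spl) == nrec)
  pA <- unlist(lapply(spl, function(e) rep(e, each = length(e))),
               use.names = FALSE)
  pB <- unlist(lapply(spl, function(e) rep(e, times = length(e))),
               use.names = FALSE)
  dm_idx <- lookupC(ecol[pA] - 1L, ecol[pB] - 1L)
  xm_idx <- integer(0)
  if (rtype == 1L) {
    xa <- xb <- list()
    for (u in seq_along(unit_r1)) {
      e1 <- spl[[unit_r1[u]]]; e2 <- spl[[unit_r2[u]]]
      xa[[u]] <- rep(e1, each = length(e2))
      xb[[u]] <- rep(e2, times = length(e1))
    }
    xa <- unlist(xa); xb <- unlist(xb)
    m1 <- lookupC(ecol[xa] - 1L, ecol[xb] - 1L)
    m2 <- lookupC(ecol[xb] - 1L, ecol[xa] - 1L)
    xm_idx <- as.integer(rbind(m1, m2))
  }
  ridge_idx <- lookupC(seq_len(p) - 1L, seq_len(p) - 1L)

  # ---- priors and per-term prior scatter maps ----
  terms_cpp <- vector("list", nterm)
  for (k in seq_len(nterm)) {
    ti <- term_info[[k]]
    d <- ti$d; q <- ti$q
    pg <- prior$G[[ti$name]]
    V <- if (!is.null(pg$V)) pg$V else diag(1, d)
    nu <- if (!is.null(pg$nu)) pg$nu else 0.002
    V <- as.matrix(V)
    stopifnot(nrow(V) == d, ncol(V) == d)
    if (ti$pedigree) {
      Kg <- methods::as(methods::as(Ainv, "generalMatrix"), "CsparseMatrix")
      kp <- Kg@p; ki <- Kg@i; kx <- Kg@x
      iid <- 0L
    } else {
      kp <- ki <- integer(0); kx <- numeric(0); iid <- 1L
    }
    # prior precision scatter: entries of Ginv (x) Kinv
    if (iid) {
      ii <- rep(seq_len(q) - 1L, d * d)
      jjj <- ii
      kv <- rep(1, q)
      nk <- q
    } else {
      ii <- Kg@i
      jjj <- rep(seq_len(q) - 1L, diff(Kg@p))
      kv <- Kg@x
      nk <- length(kv)
      ii <- rep(ii, d * d); jjj <- rep(jjj, d * d)
    }
    ab <- expand.grid(a = seq_len(d) - 1L, b = seq_len(d) - 1L)
    pa <- rep(ab$a, each = nk); pb <- rep(ab$b, each = nk)
    rowi <- ti$offset + pa * q + ii
    coli <- ti$offset + pb * q + jjj
    pidx <- lookupC(rowi, coli)
    pkx <- rep(if (iid) rep(1, q) else kv, d * d)
    terms_cpp[[k]] <- list(offset = ti$offset, q = q, d = d, iid = iid,
                           kp = kp, ki = ki, kx = kx,
                           pidx = pidx, pa = pa, pb = pb, pkx = pkx,
                           V = V, nu = nu,
                           px = as.integer(ti$px), alphaV = ti$alpha_v)
  }
  pr_R <- prior$R
  rv0 <- if (!is.null(pr_R$V)) pr_R$V else 1
  rnu <- if (!is.null(pr_R$nu)) pr_R$nu else 0.002
  lambda0 <- if (!is.null(pr_R$lambda0)) pr_R$lambda0 else 0.01

  prob <- list(y = y, fam = famcode, bound = bound,
               w_ptr = as.integer(w_ptr), w_col = as.integer(w_col),
               w_val = w_val, ncol = ncol_all, p = p,
               terms = terms_cpp, rtype = as.integer(rtype),
               pivec = as.integer(pivec),
               Lp = as.integer(Lp), Li = as.integer(Li),
               rl_ptr = as.integer(rl_ptr), rl_k = as.integer(rl_k),
               rl_pos = as.integer(rl_pos),
               cm_ptr = as.integer(cm_ptr), cm_row = as.integer(cm_row),
               cm_idx = as.integer(cm_idx),
               dm_idx = as.integer(dm_idx), xm_idx = as.integer(xm_idx),
               ridge_idx = as.integer(ridge_idx), ridge = 1e-8,
               ncnz = as.integer(ncnz),
               rv0 = rv0, rnu = rnu, lambda0 = lambda0)
  if (rtype == 0L) {
    prob$rclass <- as.integer(rclass)
    prob$nclass <- as.integer(nclass)
    prob$rfixed <- as.integer(rfixed)
  } else {
    prob$unit_r1 <- as.integer(unit_r1 - 1L)
    prob$unit_r2 <- as.integer(unit_r2 - 1L)
  }
  ctl <- list(nitt = control$nitt, burnin = control$burnin,
              thin = control$thin, store_latent = isTRUE(store_latent))

  res <- with_seed_(seed, .gibbs_run(prob, ctl))

  # ---- label the draws ----
  colnames(res$fixed) <- colnames(X)
  vc <- list()
  for (k in seq_len(nterm)) {
    ti <- term_info[[k]]
    d <- ti$d; tl <- ti$trait_labels
    lab <- character(0)
    for (b in seq_len(d)) for (a in b:d) lab <- c(lab, paste0(tl[a], ":", tl[b]))
    m <- res$vc[[k]]
    colnames(m) <- lab
    vc[[ti$name]] <- m
  }
  rl <- res$resid
  colnames(rl) <- if (rtype == 0L) {
    if (is.null(resid$by)) "units" else paste0(resid$by, levels(rcf))
  } else c("var_gauss", "cov_gauss_binary")
  empty <- if (nterm == 0) integer(0) else
    vapply(term_info, function(ti) {
      used <- unique((ti$trait_idx - 1L) * ti$q + ti$level_idx)
      ti$q * ti$d - length(used)
    }, integer(1))
  theta_mean <- res$theta_mean
  Wreal <- Matrix::sparseMatrix(i = erec, j = ecol, x = eval_,
                                dims = c(nrec, ncol_all))
  fitted_mean <- as.numeric(Wreal %*% theta_mean)
  out <- list(call = cl,
              draws = list(fixed = res$fixed, vc = vc, resid = rl),
              latent = if (isTRUE(store_latent)) res$latent else NULL,
              terms = lapply(term_info, function(ti)
                ti[c("name", "q", "d", "trait_labels", "pedigree")]),
              response = y, family = famchr, famcode = famcode,
              fitted = fitted_mean, theta_mean = theta_mean, p = p,
              fixed_names = colnames(X),
              control = control, seed = seed,
              prior = list(G = lapply(terms_cpp, function(t)
                list(V = t$V, nu = t$nu)),
                R = list(V = rv0, nu = rnu, lambda0 = lambda0)),
              njitter = res$njitter,
              n_obs = nrec,
              empty_level_count = stats::setNames(
                empty, vapply(term_info, `[[`, "", "name")),
              data_digest = adler32_(list(y, famcode, erec, ecol, eval_)))
  class(out) <- "ammc"
  out
}
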