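#' Load and scale a study (pedigree + phenotype table)
#'
#' Validates both inputs against their schemas, checks that every phenotyped
#' individual exists in the pedigree with a matching sex, and standardizes
#' the emergence score: the raw times (seconds, right-censored at 300) are
#' mean-centered and scaled to SD units, with the censoring bound mapped to
#' the same scale, `(300 - mean) / sd`. Scaling constants are computed over
#' all records - censored values entering as 300 - before any sex subsetting,
#' so all downstream models share one scale.
#'
#' @param pedigree path to a pedigree CSV or a pedigree data.frame.
#' @param phenotypes path to a phenotype CSV (long format, columns
#'   `id,sex,generation,time_point,trial,context,raw_seconds,censored,
#'   body_size,survived_tp4`) or an equivalent data.frame.
#' @param censor_bound raw-scale censoring bound (default 300 s).
#' @return object of class `bold_study`: list with `pedigree`, `data` (the
#'   records plus derived model columns `bold`, `age_class`, `trial_f`,
#'   `animal`, `mother`) and `scaling` (`mean`, `sd`, `bound_raw`,
#'   `bound_scaled`).
#' @export
load_study <- function(pedigree, phenotypes, censor_bound = 300) {
  ped <- if (is.character(pedigree)) read_pedigree(pedigree)
  else validate_and_sort(pedigree)
  ph <- if (is.character(phenotypes))
    utils::read.csv(phenotypes, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
  else as.data.frame(phenotypes)
  req <- c("id", "sex", "generation", "time_point", "trial", "context",
           "raw_seconds", "censored", "body_size", "survived_tp4")
  miss <- setdiff(req, names(ph))
  if (length(miss))
    stop("phenotype table is missing column(s): ", paste(miss, collapse = ", "))
  ph$censored <- as.logical(ph$censored)
  ph$survived_tp4 <- as.logical(ph$survived_tp4)
  bad <- which(!(ph$raw_seconds > 0 & ph$raw_seconds <= censor_bound))
  if (length(bad))
    stop("raw_seconds outside (0, ", censor_bound, "] in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(ph$censored & ph$raw_seconds != censor_bound)
  if (length(bad))
    stop("censored records must sit at the bound; row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (!all(ph$context %in% c("S", "F", "O")))
    stop("context must be one of S, F, O")
  if (!all(ph$time_point %in% 1:4)) stop("time_point must be 1..4")
  missing_ids <- setdiff(ph$id, ped$id)
  if (length(missing_ids))
    stop("phenotyped individual(s) absent from pedigree: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  sex_of <- stats::setNames(ped$sex, ped$id)
  if (any(ph$sex != sex_of[ph$id]))
    stop("sex mismatch between phenotype table and pedigree")

  m <- mean(ph$raw_seconds); s <- stats::sd(ph$raw_seconds)
  if (s == 0) stop("constant raw scores; nothing to scale")
  d <- ph
  d$bold <- (d$raw_seconds - m) / s
  d$age_class <- factor(d$time_point, levels = 1:4)
  d$trial_f <- factor(d$trial)
  d$context <- factor(d$context, levels = c("S", "F", "O"))
  d$generation <- factor(d$generation)
  d$animal <- d$id
  dam_of <- stats::setNames(ped$dam, ped$id)
  d$mother <- unname(dam_of[d$id])
  if (anyNA(d$mother))
    stop("phenotyped individual(s) with unknown dam cannot enter the ",
         "maternal-effect models")
  structure(list(pedigree = ped, data = d,
                 scaling = list(trait = "boldness", mean = m, sd = s,
                                bound_raw = censor_bound,
                                bound_scaled = (censor_bound - m) / s)),
            class = "bold_study")
}

#' @export
#' @method print bold_study
print.bold_study <- function(x, ...) {
  cat("Loaded study:", nrow(x$pedigree), "pedigree members,",
      length(unique(x$data$id)), "phenotyped individuals,",
      nrow(x$data), "records\n")
  tab <- table(x$data$time_point[!duplicated(paste(x$data$id, x$data$time_point))])
  cat("  individuals per time point:", paste(tab, collapse = ", "), "\n")
  cat(sprintf("  scaling: mean %.1f s, sd %.1f s, scaled bound %.2f\n",
              x$scaling$mean, x$scaling$sd, x$scaling$bound_scaled))
  invisible(x)
}

#' Wrap simulator output as a loaded study
#'
#' @param sim output of [simulate_study()] or [fixture_study()].
#' @return a `bold_study` (see [load_study()]).
#' @export
as_study <- function(sim) load_study(sim$pedigree, sim$phenotypes)

#' @rdname load_study
#' @param x phenotype table; @param path output CSV path.
#' @export
write_phenotypes <- function(x, path) {
  cols <- c("id", "sex", "generation", "time_point", "trial", "context",
            "raw_seconds", "censored", "body_size", "survived_tp4")
  utils::write.csv(as.data.frame(x)[, cols], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Parse a plain-text key = value run configuration
#'
#' Lines of `key = value`; `#` starts a comment; unknown keys are errors.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  if (any(lengths(kv) != 3)) stop("malformed config line(s)")
  out <- stats::setNames(lapply(kv, function(x) {
    v <- trimws(x[3])
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv)) nv else v
  }), vapply(kv, `[[`, "", 2))
  out
}

pipeline_stage_ <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", stage, "] failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run a complete simulate/load - fit - summarize pipeline
#'
#' Executes one model on either a named input dataset or simulator output,
#' runs the convergence check, computes the model's derived summaries, and
#' writes a reproducible bundle to `out_dir`: `draws.csv` (all stored draws),
#' `summary.csv` (posterior summaries of every parameter), `derived.csv`
#' (model-specific quantities: heritability/maternal series and cross-age
#' genetic correlations for model 3a, repeatabilities for models 2a/2b,
#' among-individual cross-context correlations for model 1, the
#' selective-disappearance report for model 3c, survival associations for
#' model 4), `log.txt` and `manifest.json` with content digests, so a rerun
#' with the same config is byte-identical.
#'
#' @param config named list or path to a key=value config file. Keys:
#'   `source` (`"simulate"`, `"fixture"`, or `"files"`), `pedigree`,
#'   `phenotypes` (paths, when `source = "files"`), `out_dir`, `model` (one
#'   of 1, 2a, 2b, 3a, 3b, 3c, 4), `sex` (`F`/`M`/`both`), `nitt`, `burnin`,
#'   `thin`, `seed`, `ess_floor`.
#' @return (invisibly) list with the fit, derived tables and manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  allowed <- c("source", "pedigree", "phenotypes", "out_dir", "model", "sex",
               "nitt", "burnin", "thin", "seed", "ess_floor")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("pipeline stage [0: config] failed: unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  get <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  seed <- as.integer(get("seed", 1))
  model <- as.character(get("model", "3a"))
  sex <- as.character(get("sex", "F"))
  control <- chain_control(nitt = get("nitt", 50000),
                           burnin = get("burnin", 5000),
                           thin = get("thin", 10))
  out_dir <- get("out_dir", NULL)

  study <- pipeline_stage_("1: data", {
    src <- as.character(get("source", "files"))
    switch(src,
           simulate = as_study(simulate_study(seed = seed)),
           fixture = as_study(fixture_study(seed = seed)),
           files = {
             if (is.null(cfg$pedigree) || is.null(cfg$phenotypes))
               stop("source = files needs 'pedigree' and 'phenotypes' paths")
             if (!file.exists(cfg$pedigree))
               stop("pedigree file not found: ", cfg$pedigree)
             if (!file.exists(cfg$phenotypes))
               stop("phenotype file not found: ", cfg$phenotypes)
             load_study(cfg$pedigree, cfg$phenotypes)
           },
           stop("unknown source '", src, "'"))
  })

  fit <- pipeline_stage_("2: fit", switch(
    model,
    "1" = fit_model1(study, control = control, seed = seed),
    "2a" = fit_model2(study, sex, "a", control = control, seed = seed),
    "2b" = fit_model2(study, sex, "b", control = control, seed = seed),
    "3a" = fit_model3a(study, sex, control = control, seed = seed),
    "3b" = fit_model3b(study, sex, control = control, seed = seed),
    "3c" = fit_model3c(study, sex, control = control, seed = seed),
    "4" = fit_model4(study, sex, control = control, seed = seed),
    stop("unknown model '", model, "'")))

  conv <- pipeline_stage_("3: convergence",
                          check_convergence(fit, get("ess_floor", 0)))

  derived <- pipeline_stage_("4: summaries", switch(
    model,
    "1" = genetic_correlations(fit, term = "id")$table,
    "2a" = repeatability(fit, "short_age_specific"),
    "2b" = rbind(repeatability(fit, "short_cross_age"),
                 repeatability(fit, "long_term")),
    "3a" = {
      hs <- heritability_series(fit)
      rbind(cbind(quantity = "h2", hs$h2[, c("age", "median", "hpd_low",
                                             "hpd_high", "mode")]),
            cbind(quantity = "m2", hs$m2[, c("age", "median", "hpd_low",
                                             "hpd_high", "mode")]),
            cbind(quantity = "r_A",
                  stats::setNames(genetic_correlations(fit)$table[
                    , c("pair", "median", "hpd_low", "hpd_high", "mode")],
                    c("age", "median", "hpd_low", "hpd_high", "mode"))))
    },
    "3b" = cbind(parameter = "size_std",
                 post_est(fit$draws$fixed[, "size_std"])),
    "3c" = fit$disappearance,
    "4" = {
      sa <- survival_assoc(fit)
      rbind(cbind(quantity = "h2_survival", sa$h2_survival),
            cbind(quantity = "r_A", sa$r_A),
            cbind(quantity = "r_P", sa$r_P),
            cbind(quantity = "b", sa$b))
    }))

  manifest <- NULL
  if (!is.null(out_dir)) {
    pipeline_stage_("5: write", {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      wr <- function(df, file) {
        path <- file.path(out_dir, file)
        utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
        path
      }
      draws_path <- wr(as.data.frame(as.matrix(fit)), "draws.csv")
      sm <- summary(fit, ess = FALSE)
      sum_tab <- rbind(
        cbind(block = "fixed", sm$fixed),
        do.call(rbind, lapply(names(sm$vc), function(nm)
          cbind(block = nm, sm$vc[[nm]][, -1]))),
        cbind(block = "residual", sm$resid))
      sum_path <- wr(sum_tab, "summary.csv")
      der_path <- wr(derived, "derived.csv")
      log_lines <- c(
        paste("model", model), paste("sex", sex), paste("seed", seed),
        paste("nitt", control$nitt), paste("burnin", control$burnin),
        paste("thin", control$thin),
        paste("records", fit$n_obs),
        paste("data_digest", fit$data_digest),
        paste("convergence_pass", conv$pass))
      writeLines(log_lines, file.path(out_dir, "log.txt"))
      manifest <<- list(
        model = model, sex = sex, seed = seed,
        control = control[c("nitt", "burnin", "thin")],
        data_digest = fit$data_digest,
        digests = list(
          draws = adler32_(readLines(draws_path)),
          summary = adler32_(readLines(sum_path)),
          derived = adler32_(readLines(der_path))))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    })
  }
  invisible(list(fit = fit, convergence = conv, derived = derived,
                 manifest = manifest))
}
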