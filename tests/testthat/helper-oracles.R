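# Independent oracles and data constructors used across the test files.

# Recursive-kinship oracle for the additive relationship matrix. Independent
# of the package's tabular method: A = 2 * kinship, computed by the textbook
# recursion phi(i,i) = (1 + phi(s_i, d_i)) / 2, phi(i,j) = (phi(s_i, j) +
# phi(d_i, j)) / 2 with j preceding i.
amatrix_oracle <- function(ped) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  n <- nrow(ped)
  phi <- matrix(NA_real_, n, n)
  kin <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (!is.na(phi[i, j])) return(phi[i, j])
    v <- if (i == j) {
      0.5 * (1 + kin(si[i], di[i]))
    } else {
      if (i < j) { tmp <- i; i <- j; j <- tmp } # make i the later individual
      0.5 * (kin(si[i], j) + kin(di[i], j))
    }
    phi[i, j] <<- v; phi[j, i] <<- v
    v
  }
  for (i in seq_len(n)) for (j in seq_len(i)) kin(i, j)
  out <- 2 * phi
  dimnames(out) <- list(ped$id, ped$id)
  out
}

# random valid pedigree: founders plus individuals with parents drawn from
# earlier individuals of the appropriate sex
random_pedigree <- function(n, seed) {
  set.seed(seed)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  id <- sprintf("i%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i > 4 && stats::runif(1) < 0.75) {
      ms <- which(sex[seq_len(i - 1)] == "M")
      fs <- which(sex[seq_len(i - 1)] == "F")
      if (length(ms) && stats::runif(1) < 0.9)
        sire[i] <- id[ms[sample.int(length(ms), 1)]]
      if (length(fs) && stats::runif(1) < 0.9)
        dam[i] <- id[fs[sample.int(length(fs), 1)]]
    }
  }
  validate_and_sort(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                               generation = "X", stringsAsFactors = FALSE))
}

# Build a loaded study from per-individual latent values by age class
# (latent scale: seconds = 150 + 60 * latent), following the standard trial
# schedule. last_tp truncates each individual's records (dropout).
manual_study <- function(ids, sex, latent, noise_sd = 0.3, last_tp = NULL,
                         seed = 1) {
  set.seed(seed)
  n <- length(ids)
  if (is.null(last_tp)) last_tp <- rep(4L, n)
  sch_tp <- c(1, 1, 2, 2, 2, 3, 3, 3, 4, 4)
  sch_trial <- c(1, 2, 1, 2, 3, 1, 2, 3, 1, 2)
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    keep <- sch_tp <= last_tp[i]
    sch_ctx <- c("S", "S", sample(c("S", "F", "O")), sample(c("S", "F", "O")),
                 "S", "S")
    data.frame(id = ids[i], sex = sex[i],
               generation = if (i <= n / 2) "F1" else "F2",
               time_point = sch_tp[keep], trial = sch_trial[keep],
               context = sch_ctx[keep],
               raw_seconds = 150 + 60 * (latent[i, sch_tp[keep]] +
                                           stats::rnorm(sum(keep), 0, noise_sd)),
               stringsAsFactors = FALSE)
  }))
  recs$raw_seconds <- pmin(pmax(recs$raw_seconds, 1), 300)
  recs$censored <- recs$raw_seconds >= 300
  recs$body_size <- stats::rnorm(n)[match(recs$id, ids)]
  recs$survived_tp4 <- (last_tp == 4L)[match(recs$id, ids)]
  ped <- rbind(
    data.frame(id = c("SIRE0", "DAM0"), sire = NA_character_,
               dam = NA_character_, sex = c("M", "F"), generation = "P",
               stringsAsFactors = FALSE),
    data.frame(id = ids, sire = "SIRE0", dam = "DAM0", sex = sex,
               generation = recs$generation[match(ids, recs$id)],
               stringsAsFactors = FALSE))
  load_study(ped, recs)
}

# fabricate a minimal model-3a-shaped fit with constant draws, for exact
# arithmetic checks of the derived-statistics formulas
vech_labels <- function(labels) {
  d <- length(labels)
  out <- character(0)
  for (b in seq_len(d)) for (a in b:d)
    out <- c(out, paste0(labels[a], ":", labels[b]))
  out
}

fake_fit_3a <- function(VA, VM, VID, VR, covA = NULL, ndraw = 25) {
  d <- 4
  lab <- vech_labels(as.character(1:4))
  mk <- function(diagv, covv = 0) {
    m <- matrix(0, ndraw, d * (d + 1) / 2, dimnames = list(NULL, lab))
    col <- 0
    for (b in 1:d) for (a in b:d) {
      col <- col + 1
      m[, col] <- if (a == b) diagv[a] else covv
    }
    m
  }
  rs <- matrix(rep(VR, each = ndraw), ndraw, 4,
               dimnames = list(NULL, paste0("age_class", 1:4)))
  terms <- lapply(c("id", "animal", "mother"), function(nm)
    list(name = nm, q = 10, d = 4, trait_labels = as.character(1:4),
         pedigree = nm == "animal"))
  structure(list(draws = list(
    fixed = matrix(0, ndraw, 1, dimnames = list(NULL, "(Intercept)")),
    vc = list(id = mk(VID), animal = mk(VA, if (is.null(covA)) 0 else covA),
              mother = mk(VM)),
    resid = rs), terms = terms), class = "ammc")
}
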