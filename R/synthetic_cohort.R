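#' Default synthetic lipid panel composition
#'
#' Per-class species counts proportional to a large clinical HILIC-SRM
#' panel (371 neutral lipids, 94 sphingolipids, 235 glycerophospholipids,
#' 56 lysophospholipids, 25 free fatty acids across 22 classes), scaled
#' down about five-fold so that desk-scale simulations stay fast while
#' preserving the class structure.
#'
#' @return named integer vector, class code -> number of species.
#' @export
default_lipid_panel <- function() {
  c(CE = 12L, DG = 15L, TG = 48L,
    Cer = 5L, dhCer = 2L, HexCer = 4L, Hex2Cer = 2L, SM = 6L,
    PC = 14L, `PC-O` = 8L, PE = 7L, `PE-O` = 5L, PG = 3L, PI = 6L, PS = 4L,
    LPC = 4L, `LPC-O` = 2L, LPE = 2L, LPG = 1L, LPI = 1L, LPS = 1L,
    FFA = 5L)
}

#' Default class concentration scale (nmol/L)
#'
#' Geometric centres of per-class plasma concentrations, spanning six
#' orders of magnitude from cholesteryl esters (millimolar) down to
#' phosphatidylglycerols (low nanomolar).
#'
#' @return named numeric vector, class code -> nmol/L.
#' @export
default_class_scale <- function() {
  c(CE = 5e6, TG = 5e5, PC = 3e5, FFA = 1e5, SM = 5e4, LPC = 4e4,
    DG = 2e4, PE = 2e4, `PC-O` = 1e4, PI = 1e4, `PE-O` = 5e3, Cer = 5e3,
    LPE = 2e3, `LPC-O` = 1e3, dhCer = 500, LPI = 500, PS = 100,
    Hex2Cer = 50, LPG = 50, HexCer = 30, LPS = 20, PG = 5)
}

#' Default per-class analytical CV (fraction)
#'
#' Around 8% for most classes (matching a median between-batch QC CV of
#' ~8.5%), higher for the coeluting neutral lipids and for PS, whose
#' signal sits near the detection limit in reference plasma.
#'
#' @return named numeric vector, class code -> CV fraction.
#' @export
default_analytical_cv <- function() {
  cv <- setNames(rep(0.08, length(lipid_classes())), lipid_classes())
  cv[c("CE", "DG", "TG")] <- 0.15
  cv["PS"] <- 0.25
  cv
}

## carbon/double-bond ranges used to lay out deterministic species grids
panel_chain_ranges <- function() {
  list(CE = c(14, 22, 0), DG = c(30, 40, 0), TG = c(44, 58, 0),
       Cer = c(34, 44, 1), dhCer = c(34, 42, 0), HexCer = c(34, 44, 1),
       Hex2Cer = c(34, 44, 1), SM = c(30, 44, 1),
       PC = c(30, 40, 0), `PC-O` = c(30, 40, 0), PE = c(32, 40, 0),
       `PE-O` = c(32, 40, 0), PG = c(32, 40, 0), PI = c(32, 40, 0),
       PS = c(34, 40, 0),
       LPC = c(16, 22, 0), `LPC-O` = c(16, 20, 0), LPE = c(16, 22, 0),
       LPG = c(16, 20, 0), LPI = c(16, 20, 0), LPS = c(16, 20, 0),
       FFA = c(14, 24, 0))
}

#' Build a synthetic transition registry
#'
#' Deterministically lays out species over class-typical carbon ranges in
#' runs of consecutive double-bond counts (so that the M+2 interference
#' chains the isotope-correction stage must handle are present), creates
#' two deuterated internal standards per represented class, and assigns
#' each species its most structurally similar IS.
#'
#' @param n_per_class named integer vector, class -> species count.
#' @param class_scale named numeric vector, class -> nmol/L (IS spike
#'   concentrations are set to the class scale).
#' @return a registry `data.frame` (see [read_registry()]).
#' @export
build_synthetic_registry <- function(n_per_class = default_lipid_panel(),
                                     class_scale = default_class_scale()) {
  ranges <- panel_chain_ranges()
  species <- list()
  standards <- list()
  for (cls in names(n_per_class)) {
    n <- n_per_class[[cls]]
    if (n < 1) next
    r <- ranges[[cls]]
    if (is.null(r)) r <- c(30, 40, 0)
    base <- sub("-O$", "", cls)
    eth <- if (grepl("-O$", cls)) "O-" else ""
    carbons <- integer(0); dbs <- integer(0)
    pass <- 0L   # even-chain grid first, then odd chains, then higher db runs
    while (length(carbons) < n) {
      db0 <- r[3] + 4L * (pass %/% 2L)
      for (c_now in seq(r[1] + pass %% 2L, r[2], by = 2)) {
        if (length(carbons) >= n) break
        run <- min(4L, n - length(carbons))
        carbons <- c(carbons, rep(c_now, run))
        dbs <- c(dbs, seq(db0, length.out = run))
      }
      pass <- pass + 1L
    }
    nm <- sprintf("%s %s%d:%d", base, eth, carbons, dbs)
    ## two IS per class at the range ends
    is_c <- c(r[1] + 1, r[2] - 1)
    is_db <- c(r[3], r[3] + 1)
    is_id <- sprintf("%s %s%d:%d (d7)", base, eth, is_c, is_db)
    standards[[cls]] <- data.frame(
      id = is_id, lipid_class = cls, carbons = is_c, double_bonds = is_db,
      spike_concentration = class_scale[[cls]], stringsAsFactors = FALSE)
    species[[cls]] <- data.frame(
      name = nm, class = cls, carbons = carbons, double_bonds = dbs,
      stringsAsFactors = FALSE)
  }
  std <- do.call(rbind, standards)
  sp <- do.call(rbind, species)
  rownames(sp) <- rownames(std) <- NULL
  assigned <- vapply(seq_len(nrow(sp)), function(i) {
    s <- lipid_species(sp$name[i], sp$class[i], sp$carbons[i],
                       sp$double_bonds[i])
    assign_internal_standard(s, std)$id
  }, character(1))
  sp$internal_standard_id <- assigned
  sp$is_spike_concentration_nM <-
    std$spike_concentration[match(assigned, std$id)]
  validate_registry(sp)
}

#' Synthetic cohort configuration
#'
#' Defines the "stated world" of the generator: a repeated-measures
#' population cohort measured in plate batches with periodic
#' reference-plasma QC injections. Defaults emulate a 364-participant,
#' three-time-point study acquired in 13 batches with a QC every 12
#' study samples, per-lipid individual set points (random intercepts),
#' sex effects of 5-30%, small age trends, multiplicative between-batch
#' offsets and class-specific analytical noise.
#'
#' @param n_participants number of participants (default 364).
#' @param n_timepoints time points per participant (default 3).
#' @param n_batches acquisition batches / plates (default 13).
#' @param qc_interval QC reference injection every this many study
#'   injections (default 12), plus QCs at batch start and end.
#' @param n_lipids_per_class named integer vector (see
#'   [default_lipid_panel()]).
#' @param class_concentration_scale named numeric vector, nmol/L.
#' @param sex_effect_range two fractions; each lipid's |sex effect| is
#'   drawn uniformly from this range (on the concentration ratio scale,
#'   random sign), default 5-30%. Use `c(0, 0)` for a global null.
#' @param icc_target intraclass correlation of the biological variation,
#'   in `[0, 1)`.
#' @param biological_sd_log2 total biological SD on the log2 scale
#'   (between + within), default 0.5.
#' @param analytical_cv named numeric vector of per-class analytical CV
#'   fractions (multiplicative lognormal noise on the measured signal).
#' @param batch_offset_sd SD of per-(batch, lipid) offsets; on the log2
#'   scale when `batch_effect_scale = "log2"` (default), or as a fraction
#'   of the class scale when `"linear"`.
#' @param batch_effect_scale `"log2"` (multiplicative on concentration)
#'   or `"linear"` (additive on concentration).
#' @param age_slope_sd SD of per-lipid age trends, as a per-year fraction.
#' @param age_mean,age_sd baseline age distribution (years), default
#'   N(52.7, 5.2^2); follow-ups add `followup_years`.
#' @param followup_years offsets of the time points in years,
#'   default `c(0, 5, 10)`.
#' @param baseline_spread_log2 SD of per-species baselines around the
#'   class scale (log2).
#' @param lod optional named vector, class -> detection limit (nmol/L);
#'   species below it in truth are left-censored to zero area (MNAR).
#' @param isotope_contamination add forward-simulated M+2 isotopic
#'   interference along the registry's double-bond chains (default TRUE).
#' @param is_area_nominal nominal internal-standard peak area.
#' @param injection_factor_sd_log2 SD (log2) of the per-injection matrix /
#'   sensitivity factor shared by analyte and IS channels.
#' @param seed integer; mandatory for simulation.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 364,
                          n_timepoints = 3,
                          n_batches = 13,
                          qc_interval = 12,
                          n_lipids_per_class = default_lipid_panel(),
                          class_concentration_scale = default_class_scale(),
                          sex_effect_range = c(0.05, 0.30),
                          icc_target = 0.6,
                          biological_sd_log2 = 0.5,
                          analytical_cv = default_analytical_cv(),
                          batch_offset_sd = 0.1,
                          batch_effect_scale = c("log2", "linear"),
                          age_slope_sd = 0.004,
                          age_mean = 52.7, age_sd = 5.2,
                          followup_years = c(0, 5, 10),
                          baseline_spread_log2 = 1.0,
                          lod = NULL,
                          isotope_contamination = TRUE,
                          is_area_nominal = 1e5,
                          injection_factor_sd_log2 = 0.25,
                          seed = NULL) {
  batch_effect_scale <- match.arg(batch_effect_scale)
  cfg <- list(n_participants = as.integer(n_participants),
              n_timepoints = as.integer(n_timepoints),
              n_batches = as.integer(n_batches),
              qc_interval = as.integer(qc_interval),
              n_lipids_per_class = n_lipids_per_class,
              class_concentration_scale = class_concentration_scale,
              sex_effect_range = sex_effect_range,
              icc_target = icc_target,
              biological_sd_log2 = biological_sd_log2,
              analytical_cv = analytical_cv,
              batch_offset_sd = batch_offset_sd,
              batch_effect_scale = batch_effect_scale,
              age_slope_sd = age_slope_sd,
              age_mean = age_mean, age_sd = age_sd,
              followup_years = followup_years,
              baseline_spread_log2 = baseline_spread_log2,
              lod = lod,
              isotope_contamination = isotope_contamination,
              is_area_nominal = is_area_nominal,
              injection_factor_sd_log2 = injection_factor_sd_log2,
              seed = seed)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_participants < 1) stop("n_participants must be >= 1")
    if (n_timepoints < 1) stop("n_timepoints must be >= 1")
    if (n_batches < 1) stop("n_batches must be >= 1")
    if (qc_interval < 1) stop("qc_interval must be >= 1")
    if (length(n_lipids_per_class) == 0 || sum(n_lipids_per_class) < 1) {
      stop("empty lipid panel: n_lipids_per_class must request >= 1 species")
    }
    bad <- setdiff(names(n_lipids_per_class), lipid_classes())
    if (length(bad)) stop("unknown class(es) in panel: ", paste(bad, collapse = ", "))
    miss <- setdiff(names(n_lipids_per_class), names(class_concentration_scale))
    if (length(miss)) stop("no concentration scale for class(es): ",
                           paste(miss, collapse = ", "))
    miss2 <- setdiff(names(n_lipids_per_class), names(analytical_cv))
    if (length(miss2)) stop("no analytical CV for class(es): ",
                            paste(miss2, collapse = ", "))
    if (length(sex_effect_range) != 2 || any(sex_effect_range < 0) ||
        sex_effect_range[1] > sex_effect_range[2]) {
      stop("sex_effect_range must be an increasing pair of fractions >= 0")
    }
    if (icc_target < 0 || icc_target >= 1) stop("icc_target must be in [0, 1)")
    if (biological_sd_log2 < 0 || batch_offset_sd < 0 || age_slope_sd < 0 ||
        any(analytical_cv < 0)) {
      stop("CVs, SDs and fractions must be >= 0")
    }
    if (length(followup_years) != n_timepoints) {
      stop("followup_years must have one offset per time point")
    }
  })
  invisible(cfg)
}

#' Block-randomized plate layout
#'
#' Assigns participants to batches so that (i) all time points of one
#' participant fall in the same batch, acquired in randomized order, and
#' (ii) each batch holds a similar proportion of males and females
#' (round-robin dealing of sex-interleaved, shuffled participants).
#' Within each batch the injection sequence is: one blank, a QC, the
#' randomized study injections with a QC inserted after every
#' `qc_interval` of them, and a closing QC.
#'
#' @param participants data frame with columns `participant_id`, `sex`
#'   (`"F"`/`"M"`), `age_baseline`.
#' @param config a [cohort_config()].
#' @return manifest data frame with columns `injection_id`,
#'   `participant_id`, `timepoint`, `sex`, `age`, `batch`, `well`,
#'   `order`, `role`.
#' @export
randomize_plates <- function(participants, config) {
  stopifnot(all(c("participant_id", "sex", "age_baseline") %in%
                  names(participants)))
  B <- config$n_batches
  Tn <- config$n_timepoints
  ## interleave shuffled females and males, then deal round-robin so each
  ## batch's sex proportion tracks the cohort's
  f <- sample(participants$participant_id[participants$sex == "F"])
  m <- sample(participants$participant_id[participants$sex == "M"])
  k <- max(length(f), length(m))
  inter <- as.vector(rbind(c(f, rep(NA, k - length(f))),
                           c(m, rep(NA, k - length(m)))))
  inter <- inter[!is.na(inter)]
  ## deal consecutive (F, M) pairs to the same batch so the stride of the
  ## round-robin cannot alias with the sex alternation
  batch_of <- setNames(((seq_along(inter) - 1) %/% 2) %% B + 1, inter)

  cohort_pf <- mean(participants$sex == "F")
  rows <- vector("list", B)
  for (b in seq_len(B)) {
    ids <- names(batch_of)[batch_of == b]
    if (length(ids)) {
      pf <- mean(participants$sex[match(ids, participants$participant_id)] == "F")
      slack <- 1 / length(ids)
      if (abs(pf - cohort_pf) > 0.1 + slack) {
        warning(sprintf("batch %d sex balance is best-effort (%.0f%% F vs %.0f%% cohort)",
                        b, 100 * pf, 100 * cohort_pf))
      }
    }
    study <- expand.grid(participant_id = ids, timepoint = seq_len(Tn),
                         stringsAsFactors = FALSE)
    study <- study[sample(nrow(study)), , drop = FALSE]
    roles <- c("blank", "QC")
    pid <- c(NA, NA)
    tp <- c(NA, NA)
    n_since_qc <- 0
    for (i in seq_len(nrow(study))) {
      roles <- c(roles, "study"); pid <- c(pid, study$participant_id[i])
      tp <- c(tp, study$timepoint[i])
      n_since_qc <- n_since_qc + 1
      if (n_since_qc == config$qc_interval) {
        roles <- c(roles, "QC"); pid <- c(pid, NA); tp <- c(tp, NA)
        n_since_qc <- 0
      }
    }
    roles <- c(roles, "QC"); pid <- c(pid, NA); tp <- c(tp, NA)
    ord <- seq_along(roles)
    rows[[b]] <- data.frame(
      injection_id = sprintf("B%02d_%03d", b, ord),
      participant_id = pid, timepoint = tp, batch = b,
      well = sprintf("%s%d", LETTERS[(ord - 1) %% 8 + 1], (ord - 1) %/% 8 + 1),
      order = ord, role = roles, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  idx <- match(manifest$participant_id, participants$participant_id)
  manifest$sex <- participants$sex[idx]
  manifest$age <- participants$age_baseline[idx] +
    ifelse(is.na(manifest$timepoint), NA,
           config$followup_years[manifest$timepoint])
  rownames(manifest) <- NULL
  manifest[, c("injection_id", "participant_id", "timepoint", "sex", "age",
               "batch", "well", "order", "role")]
}

#' Simulate a full synthetic lipidomics cohort
#'
#' Generates true per-lipid concentrations (participant set points, sex
#' and age effects), a block-randomized injection manifest, per-batch
#' offsets, and observed SRM peak areas for analyte and internal-standard
#' channels, optionally with forward-simulated isotopic interference.
#'
#' The observation model per lipid `l` and study injection `i` is, on the
#' log2 concentration scale,
#' `mu_l + beta_sex_l * female + beta_age_l * (age - age_mean) + b_(participant,l) + eps_il`
#' with `Var(b) = icc_target * biological_sd_log2^2` and
#' `Var(eps)` its complement. QC injections share one fixed reference
#' concentration vector (the per-species baseline `2^mu`), so injected
#' batch offsets are fully identifiable from the QC rows. Areas are
#' `concentration / IS_spike * IS_area` with a shared per-injection
#' sensitivity factor on both channels (so the IS ratio cancels it) and
#' mean-one lognormal analytical noise on the analyte channel.
#'
#' @param config a [cohort_config()]; `config$seed` is required.
#' @return list of class `synthetic_cohort` with elements `manifest`,
#'   `registry`, `truth` (ground-truth parameters and noise-free
#'   concentrations) and `areas` (an [abundance_matrix()] in state
#'   `raw_area`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(config$seed)) stop("config$seed is mandatory when simulating")
  set.seed(config$seed)

  registry <- build_synthetic_registry(config$n_lipids_per_class,
                                       config$class_concentration_scale)
  L <- nrow(registry)
  n <- config$n_participants

  participants <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    sex = sample(rep_len(c("F", "M"), n)),
    age_baseline = rnorm(n, config$age_mean, config$age_sd),
    stringsAsFactors = FALSE)

  manifest <- randomize_plates(participants, config)

  ## ground-truth parameters
  mu <- log2(config$class_concentration_scale[registry$class]) +
    rnorm(L, 0, config$baseline_spread_log2)
  mu <- unname(mu)
  if (diff(config$sex_effect_range) == 0 && config$sex_effect_range[1] == 0) {
    beta_sex <- rep(0, L)
  } else {
    beta_sex <- sample(c(-1, 1), L, replace = TRUE) *
      log2(1 + runif(L, config$sex_effect_range[1], config$sex_effect_range[2]))
  }
  beta_age <- rnorm(L, 0, log2(1 + config$age_slope_sd))
  sigma2_b <- config$icc_target * config$biological_sd_log2^2
  sigma2_w <- (1 - config$icc_target) * config$biological_sd_log2^2
  b <- matrix(rnorm(n * L, 0, sqrt(sigma2_b)), n, L,
              dimnames = list(participants$participant_id, registry$name))

  is_study <- manifest$role == "study"
  is_qc <- manifest$role == "QC"
  n_inj <- nrow(manifest)

  log2conc <- matrix(NA_real_, n_inj, L,
                     dimnames = list(manifest$injection_id, registry$name))
  pj <- match(manifest$participant_id, participants$participant_id)
  female <- as.numeric(manifest$sex == "F")
  age_c <- manifest$age - config$age_mean
  eps <- matrix(rnorm(sum(is_study) * L, 0, sqrt(sigma2_w)), sum(is_study), L)
  log2conc[is_study, ] <-
    matrix(mu, sum(is_study), L, byrow = TRUE) +
    outer(female[is_study], beta_sex) +
    outer(age_c[is_study], beta_age) +
    b[pj[is_study], , drop = FALSE] + eps
  log2conc[is_qc, ] <- matrix(mu, sum(is_qc), L, byrow = TRUE)

  true_conc <- 2^log2conc
  true_conc[manifest$role == "blank", ] <- 0

  ## batch effects
  if (config$batch_effect_scale == "log2") {
    delta <- matrix(rnorm(config$n_batches * L, 0, config$batch_offset_sd),
                    config$n_batches, L)
    conc_obs <- 2^(log2conc + delta[manifest$batch, , drop = FALSE])
  } else {
    delta <- matrix(rnorm(config$n_batches * L, 0, config$batch_offset_sd),
                    config$n_batches, L) *
      matrix(2^mu, config$n_batches, L, byrow = TRUE)
    conc_obs <- pmax(true_conc + delta[manifest$batch, , drop = FALSE], 0)
  }
  conc_obs[manifest$role == "blank", ] <- 0

  ## analytical noise (mean-one lognormal, class-specific CV) on the
  ## analyte channel; the per-injection factor is shared with the IS
  cv <- config$analytical_cv[registry$class]
  sdlog <- sqrt(log(1 + cv^2))
  noise <- exp(sweep(matrix(rnorm(n_inj * L), n_inj, L), 2, sdlog, `*`) -
                 matrix(sdlog^2 / 2, n_inj, L, byrow = TRUE))
  lambda <- 2^rnorm(n_inj, 0, config$injection_factor_sd_log2)

  spike <- registry$is_spike_concentration_nM
  analyte <- conc_obs * noise / matrix(spike, n_inj, L, byrow = TRUE) *
    config$is_area_nominal * lambda

  if (!is.null(config$lod)) {
    lod_l <- config$lod[registry$class]
    lod_l[is.na(lod_l)] <- 0
    analyte[true_conc < matrix(lod_l, n_inj, L, byrow = TRUE)] <- 0
  }

  std_ids <- unique(registry$internal_standard_id)
  is_cols <- matrix(config$is_area_nominal * lambda, n_inj, length(std_ids),
                    dimnames = list(manifest$injection_id,
                                    paste0("IS:", std_ids)))
  areas <- cbind(analyte, is_cols)

  prov <- sprintf("simulate_cohort(seed=%d)", config$seed)
  if (config$isotope_contamination) {
    graph <- interference_graph(registry)
    areas <- contaminate_isotopes(areas, graph)
    prov <- c(prov, "contaminate_isotopes")
  }

  truth <- structure(list(
    lipids = data.frame(name = registry$name, class = registry$class,
                        mu_log2 = mu, beta_sex = beta_sex,
                        beta_age = beta_age, sigma2_b = sigma2_b,
                        sigma2_w = sigma2_w, stringsAsFactors = FALSE),
    participant_effects = b,
    batch_offsets = delta,
    batch_effect_scale = config$batch_effect_scale,
    qc_log2 = setNames(mu, registry$name),
    true_concentration = true_conc,
    icc = if (sigma2_b + sigma2_w > 0) sigma2_b / (sigma2_b + sigma2_w) else NA_real_),
    class = "cohort_truth")

  structure(list(manifest = manifest, registry = registry, truth = truth,
                 participants = participants,
                 areas = abundance_matrix(areas, state = "raw_area",
                                          provenance = prov)),
            class = "synthetic_cohort")
}

#' @exportS3Method base::print
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d injections (%d study, %d QC, %d blank), %d lipids, %d batches\n",
              nrow(x$manifest), sum(x$manifest$role == "study"),
              sum(x$manifest$role == "QC"), sum(x$manifest$role == "blank"),
              nrow(x$registry), max(x$manifest$batch)))
  invisible(x)
}
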