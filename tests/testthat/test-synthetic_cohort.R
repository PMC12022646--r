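test_that("simulation is reproducible from the seed and sensitive to it", {
  s1 <- simulate_cohort(small_config(seed = 9))
  s2 <- simulate_cohort(small_config(seed = 9))
  s3 <- simulate_cohort(small_config(seed = 10))
  expect_identical(unclass(s1$areas), unclass(s2$areas))
  expect_identical(s1$manifest, s2$manifest)
  expect_false(identical(unclass(s1$areas), unclass(s3$areas)))
  expect_error(simulate_cohort(cohort_config(seed = NULL)), "seed is mandatory")
})

test_that("with all noise sources off, quantification recovers the baselines exactly", {
  cv0 <- setNames(rep(0, length(lipid_classes())), lipid_classes())
  cfg <- small_config(analytical_cv = cv0, batch_offset_sd = 0,
                      biological_sd_log2 = 0, icc_target = 0,
                      sex_effect_range = c(0, 0), age_slope_sd = 0,
                      seed = 4)
  sim <- simulate_cohort(cfg)
  conc <- quantify(sim$areas, sim$registry)
  sid <- sim$manifest$injection_id[sim$manifest$role == "study"]
  baseline <- matrix(2^sim$truth$lipids$mu_log2, length(sid),
                     nrow(sim$registry), byrow = TRUE)
  expect_equal(unname(unclass(conc)[sid, ]), unname(baseline),
               tolerance = 1e-12)
})

test_that("plate layout keeps participants in one batch with balanced sexes and bracketing QCs", {
  cfg <- small_config(n_participants = 48, n_batches = 4, qc_interval = 12,
                      seed = 2)
  sim <- simulate_cohort(cfg)
  man <- sim$manifest
  study <- man[man$role == "study", ]

  # all time points of a participant share one batch
  spans <- tapply(study$batch, study$participant_id,
                  function(b) length(unique(b)))
  expect_true(all(spans == 1))
  expect_true(all(table(study$participant_id) == cfg$n_timepoints))

  # per-batch sex proportion within 10% of the cohort proportion
  pf <- tapply(study$sex == "F", study$batch, mean)
  expect_true(all(abs(pf - 0.5) <= 0.1))

  # layout: blank first, QC bracketing, interior QCs every 12 study samples
  for (b in unique(man$batch)) {
    batch <- man[man$batch == b, ]
    batch <- batch[order(batch$order), ]
    expect_equal(batch$role[1], "blank")
    expect_equal(batch$role[2], "QC")
    expect_equal(batch$role[nrow(batch)], "QC")
    n_study <- sum(batch$role == "study")
    expect_equal(sum(batch$role == "QC"),
                 2 + floor(n_study / cfg$qc_interval))
  }
})

test_that("shuffled cohorts keep balance properties across seeds", {
  participants <- data.frame(participant_id = sprintf("P%03d", 1:40),
                             sex = rep(c("F", "M"), 20),
                             age_baseline = 52.7)
  cfg <- small_config(n_participants = 40, n_batches = 4)
  for (s in 1:50) {
    set.seed(s)
    man <- randomize_plates(participants[sample(40), ], cfg)
    study <- man[man$role == "study", ]
    pf <- tapply(study$sex == "F", study$batch, mean)
    expect_true(all(abs(pf - 0.5) <= 0.1 + 1 / 10))
    spans <- tapply(study$batch, study$participant_id,
                    function(b) length(unique(b)))
    expect_true(all(spans == 1))
  }
})

test_that("QC injections share one reference concentration across batches", {
  sim <- simulate_cohort(small_config(seed = 6, batch_offset_sd = 0.2))
  qcid <- sim$manifest$injection_id[sim$manifest$role == "QC"]
  truth_qc <- sim$truth$true_concentration[qcid, ]
  expect_true(all(apply(truth_qc, 2, function(v) diff(range(v))) == 0))
  expect_equal(unname(truth_qc[1, ]), unname(2^sim$truth$qc_log2))
})

test_that("simulated variance components hit the requested ICC", {
  # noise-free biology: estimate the variance ratio from the generated
  # effects via a one-way moment decomposition of the true log2 values
  cv0 <- setNames(rep(0, length(lipid_classes())), lipid_classes())
  cfg <- small_config(n_participants = 300, icc_target = 0.5,
                      sex_effect_range = c(0, 0), age_slope_sd = 0,
                      analytical_cv = cv0, batch_offset_sd = 0,
                      n_lipids_per_class = c(PC = 5, TG = 5), seed = 12)
  sim <- simulate_cohort(cfg)
  sid <- sim$manifest$injection_id[sim$manifest$role == "study"]
  lt <- log2(sim$truth$true_concentration[sid, ])
  part <- sim$manifest$participant_id[match(sid, sim$manifest$injection_id)]
  k <- cfg$n_timepoints
  icc_hat <- apply(lt, 2, function(y) {
    gm <- tapply(y, part, mean)
    msb <- k * var(gm)
    msw <- mean(tapply(y, part, var))
    sb <- (msb - msw) / k
    sb / (sb + msw)
  })
  expect_lt(abs(median(icc_hat) - 0.5), 0.05)
})

test_that("left-censoring at a class LOD zeroes low-abundance areas", {
  cfg <- small_config(seed = 3, lod = c(LPC = 1e9))  # absurd LOD: all censored
  sim <- simulate_cohort(cfg)
  lpc <- sim$registry$name[sim$registry$class == "LPC"]
  sid <- sim$manifest$injection_id[sim$manifest$role == "study"]
  expect_true(all(unclass(sim$areas)[sid, lpc] == 0))
  pc <- sim$registry$name[sim$registry$class == "PC"]
  expect_true(all(unclass(sim$areas)[sid, pc] > 0))
})

test_that("config validation rejects degenerate worlds", {
  expect_error(cohort_config(n_lipids_per_class = c(PC = 0), seed = 1),
               "empty lipid panel")
  expect_error(cohort_config(icc_target = 1, seed = 1), "icc_target")
  expect_error(cohort_config(qc_interval = 0, seed = 1), "qc_interval")
  expect_error(cohort_config(n_lipids_per_class = c(ZZ = 3), seed = 1),
               "unknown class")
  expect_error(cohort_config(sex_effect_range = c(0.3, 0.1), seed = 1),
               "sex_effect_range")
})

test_that("default class scales span six orders of magnitude", {
  sc <- default_class_scale()
  expect_gte(log10(max(sc) / min(sc)), 6)
  expect_setequal(names(sc), lipid_classes())
  expect_setequal(names(default_lipid_panel()), lipid_classes())
})
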