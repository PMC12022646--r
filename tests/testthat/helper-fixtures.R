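# Shared fixtures: a tiny hand-built registry with known interference
# chains, and a small-cohort config for fast simulations.

tiny_registry <- function() {
  data.frame(
    name = c("PC 34:0", "PC 34:1", "PC 34:2", "PC 36:1",
             "TG 52:1", "TG 52:2", "LPC 18:0"),
    class = c("PC", "PC", "PC", "PC", "TG", "TG", "LPC"),
    carbons = c(34, 34, 34, 36, 52, 52, 18),
    double_bonds = c(0, 1, 2, 1, 1, 2, 0),
    internal_standard_id = c(rep("PC 33:1 (d7)", 4), rep("TG 51:1 (d7)", 2),
                             "LPC 17:0 (d7)"),
    is_spike_concentration_nM = c(rep(3e5, 4), rep(5e5, 2), 4e4),
    stringsAsFactors = FALSE)
}

tiny_standards <- function() {
  data.frame(
    id = c("PC 33:1 (d7)", "TG 51:1 (d7)", "LPC 17:0 (d7)"),
    lipid_class = c("PC", "TG", "LPC"),
    carbons = c(33, 51, 17), double_bonds = c(1, 1, 0),
    spike_concentration = c(3e5, 5e5, 4e4),
    stringsAsFactors = FALSE)
}

small_config <- function(...) {
  defaults <- list(n_participants = 30, n_batches = 3,
                   n_lipids_per_class = c(PC = 8, TG = 8, SM = 4, LPC = 4),
                   isotope_contamination = FALSE, seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

# quantify -> batch-correct convenience used across tests
run_quant_correct <- function(sim, scale = "linear") {
  conc <- quantify(sim$areas, sim$registry)
  man <- sim$manifest
  qc <- man$role == "QC"; nb <- man$role != "blank"
  model <- fit_batch_model(conc[man$injection_id[qc], , drop = FALSE],
                           man$batch[qc], scale = scale)
  corrected <- apply_batch_correction(conc[man$injection_id[nb], , drop = FALSE],
                                      model, man$batch[nb])
  list(conc = conc, model = model, corrected = corrected, manifest = man)
}
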