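#' Quantify peak areas by stable isotope dilution
#'
#' Converts raw (or isotope-corrected) SRM peak areas into estimated
#' concentrations: each lipid's concentration is the peak-area ratio
#' between the analyte and its assigned (most structurally similar,
#' coeluting) internal standard, multiplied by the IS's known spiked
#' concentration:
#' `conc[i, l] = area[i, l] / area[i, IS(l)] * spike(IS(l))`.
#'
#' Because the IS coelutes with its analytes, any per-injection factor
#' (matrix effect, sensitivity drift) multiplies both channels and cancels
#' in the ratio. A zero analyte area is a valid measurement (below
#' detection) and propagates as zero; a missing or non-positive IS area
#' invalidates the cell (NA, counted in the `n_flagged_missing`
#' attribute) because no ratio is defined there.
#'
#' @param areas an [abundance_matrix()] in state `raw_area` or
#'   `isotope_corrected`, holding analyte columns and their IS channels
#'   (columns prefixed `"IS:"`).
#' @param registry registry `data.frame` mapping each analyte column to
#'   `internal_standard_id` and `is_spike_concentration_nM`.
#' @return an [abundance_matrix()] in state `concentration` (nmol/L) with
#'   the IS columns dropped.
#' @export
quantify <- function(areas, registry) {
  stopifnot(inherits(areas, "abundance_matrix"))
  if (!am_state(areas) %in% c("raw_area", "isotope_corrected")) {
    stop("`areas` must be in state raw_area or isotope_corrected, got ",
         am_state(areas))
  }
  lipids <- intersect(registry$name, colnames(areas))
  if (!length(lipids)) stop("no registry lipids found among matrix columns")
  reg <- registry[match(lipids, registry$name), ]
  is_cols <- paste0("IS:", reg$internal_standard_id)
  absent <- setdiff(unique(is_cols), colnames(areas))
  if (length(absent)) {
    stop("internal-standard column(s) absent from matrix: ",
         paste(absent, collapse = ", "))
  }
  a <- unclass_matrix(areas)
  analyte <- a[, lipids, drop = FALSE]
  is_area <- a[, is_cols, drop = FALSE]
  bad_is <- is.na(is_area) | is_area <= 0
  is_area[bad_is] <- NA_real_
  conc <- analyte / is_area *
    matrix(reg$is_spike_concentration_nM, nrow(a), length(lipids), byrow = TRUE)
  dimnames(conc) <- list(rownames(a), lipids)
  out <- advance_state(abundance_matrix(conc, state = am_state(areas),
                                        units = "area",
                                        provenance = am_provenance(areas)),
                       "concentration", "quantify")
  attr(out, "n_flagged_missing") <- sum(bad_is & !is.na(analyte))
  out
}
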