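#' Injections-by-lipids abundance matrix with processing provenance
#'
#' A thin wrapper around a numeric matrix (rows = injections, columns =
#' lipid transitions, with internal-standard channels prefixed `"IS:"`)
#' that carries a processing-state tag, a unit label and an ordered
#' provenance of the operations applied so far.
#'
#' The state machine is forward-only:
#' `raw_area -> isotope_corrected -> concentration -> batch_corrected`.
#' Isotopic overlap is a property of the measured signal, so it is removed
#' on the area scale before stable-isotope-dilution quantification; stages
#' may be skipped (e.g. raw areas can be quantified directly) but never
#' revisited. Units switch from `"area"` to `"nmol/L"` exactly at
#' quantification.
#'
#' @param values numeric matrix, injections x lipids; row names are
#'   injection ids, column names lipid shorthand names (IS channels
#'   prefixed `"IS:"`).
#' @param state one of `"raw_area"`, `"isotope_corrected"`,
#'   `"concentration"`, `"batch_corrected"`.
#' @param units `"area"` or `"nmol/L"`; defaults to the unit implied by
#'   `state`.
#' @param provenance character vector of operations already applied.
#' @return An `abundance_matrix` object (a classed numeric matrix).
#' @export
abundance_matrix <- function(values,
                             state = "raw_area",
                             units = NULL,
                             provenance = character()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (injections x lipids)")
  }
  state <- match.arg(state, abundance_states())
  if (is.null(units)) {
    units <- if (state %in% c("raw_area", "isotope_corrected")) "area" else "nmol/L"
  }
  if (is.null(colnames(values))) {
    stop("`values` must have column names (lipid shorthand names)")
  }
  structure(values,
            class = c("abundance_matrix", "matrix", "array"),
            state = state, units = units, provenance = provenance)
}

#' @rdname abundance_matrix
#' @export
abundance_states <- function() {
  c("raw_area", "isotope_corrected", "concentration", "batch_corrected")
}

#' @rdname abundance_matrix
#' @param x an `abundance_matrix`.
#' @export
am_state <- function(x) attr(x, "state", exact = TRUE)

#' @rdname abundance_matrix
#' @export
am_units <- function(x) attr(x, "units", exact = TRUE)

#' @rdname abundance_matrix
#' @export
am_provenance <- function(x) attr(x, "provenance", exact = TRUE)

## Forward-only state transition; `op` is appended to the provenance.
advance_state <- function(x, new_state, op, units = NULL) {
  states <- abundance_states()
  old <- am_state(x)
  if (match(new_state, states) <= match(old, states)) {
    stop(sprintf("illegal state transition %s -> %s (states only move forward)",
                 old, new_state))
  }
  if (is.null(units)) units <- am_units(x)
  if (new_state %in% c("concentration", "batch_corrected")) units <- "nmol/L"
  abundance_matrix(unclass_matrix(x), state = new_state, units = units,
                   provenance = c(am_provenance(x), op))
}

## strip the class/attributes but keep dimnames
unclass_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "state") <- NULL
  attr(y, "units") <- NULL
  attr(y, "provenance") <- NULL
  y
}

#' @exportS3Method base::print
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d injections x %d lipids [state=%s, units=%s]\n",
              nrow(x), ncol(x), am_state(x), am_units(x)))
  prov <- am_provenance(x)
  if (length(prov)) cat("provenance:", paste(prov, collapse = " -> "), "\n")
  invisible(x)
}

#' Read / write an abundance matrix as CSV
#'
#' The CSV convention is one row per injection with the injection id in the
#' first column (`injection_id`); lipid columns use shorthand names and
#' internal-standard channels are prefixed `"IS:"`.
#'
#' @param path file path.
#' @param state,units passed to [abundance_matrix()] on read.
#' @return [read_abundance_csv()] returns an `abundance_matrix`;
#'   [write_abundance_csv()] invisibly returns `path`.
#' @export
read_abundance_csv <- function(path, state = "raw_area", units = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "injection_id") {
    stop("first column of an abundance CSV must be `injection_id`")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$injection_id
  abundance_matrix(m, state = state, units = units)
}

#' @rdname read_abundance_csv
#' @param x an `abundance_matrix`.
#' @export
write_abundance_csv <- function(x, path) {
  df <- data.frame(injection_id = rownames(x), unclass_matrix(x),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
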