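#' Lipid class codes covered by the panel
#'
#' The 22 lipid (sub)class codes used throughout the package, following
#' shorthand nomenclature: cholesteryl esters (CE), di-/triacylglycerols
#' (DG, TG), the sphingolipids (Cer, dhCer, HexCer, Hex2Cer, SM),
#' glycerophospholipids and their lysospecies (PC, PE, PG, PI, PS and the
#' LP* forms), ether-linked variants carrying the `-O` designation
#' (PC-O, PE-O, LPC-O), and free fatty acids (FFA).
#'
#' @return character vector of the 22 class codes.
#' @export
lipid_classes <- function() {
  c("CE", "DG", "TG",
    "Cer", "dhCer", "HexCer", "Hex2Cer", "SM",
    "LPC", "LPC-O", "LPE", "PC", "PC-O", "PE", "PE-O",
    "LPI", "PI", "LPG", "PG", "LPS", "PS",
    "FFA")
}

#' Construct a lipid species record
#'
#' @param name shorthand name, e.g. `"PC 34:1"` or `"PC 16:0/18:1"`.
#' @param lipid_class one of [lipid_classes()].
#' @param total_carbons,total_double_bonds species-level totals.
#' @param ether_linked logical; must agree with the `-O` designation of the
#'   class code.
#' @param suffix opaque annotation suffix (e.g. `";O2"`), carried but not
#'   interpreted.
#' @param internal_standard_id,is_spike_concentration optional IS
#'   assignment (id and spiked concentration, nmol/L).
#' @return a `lipid_species` list.
#' @export
lipid_species <- function(name, lipid_class, total_carbons, total_double_bonds,
                          ether_linked = grepl("-O$", lipid_class),
                          suffix = "",
                          internal_standard_id = NA_character_,
                          is_spike_concentration = NA_real_) {
  if (!lipid_class %in% lipid_classes()) {
    stop(sprintf("unknown lipid class %s", dQuote(lipid_class)))
  }
  if (ether_linked != grepl("-O$", lipid_class)) {
    stop("`ether_linked` must be TRUE iff the class code carries the -O designation")
  }
  total_carbons <- as.integer(total_carbons)
  total_double_bonds <- as.integer(total_double_bonds)
  if (total_carbons < 0 || total_double_bonds < 0) {
    stop("carbon and double-bond counts must be non-negative")
  }
  if (total_double_bonds > total_carbons) {
    stop(sprintf("%s: double bonds (%d) exceed carbons (%d)",
                 name, total_double_bonds, total_carbons))
  }
  if (!is.na(is_spike_concentration) && is_spike_concentration <= 0) {
    stop("IS spike concentration must be > 0")
  }
  structure(list(name = name, lipid_class = lipid_class,
                 total_carbons = total_carbons,
                 total_double_bonds = total_double_bonds,
                 ether_linked = ether_linked, suffix = suffix,
                 internal_standard_id = internal_standard_id,
                 is_spike_concentration = is_spike_concentration),
            class = "lipid_species")
}

#' @exportS3Method base::print
print.lipid_species <- function(x, ...) {
  cat(sprintf("lipid_species %s [class=%s, C%d:%d%s%s]\n", x$name,
              x$lipid_class, x$total_carbons, x$total_double_bonds,
              if (x$ether_linked) ", ether" else "",
              if (nzchar(x$suffix)) paste0(", suffix=", x$suffix) else ""))
  invisible(x)
}

#' Parse lipid shorthand nomenclature
#'
#' Accepts species-level (`"TG 52:2"`) and chain-level
#' (`"PC 16:0/18:1"`, separators `/` or `_`) descriptors; chain-level
#' carbons and double bonds are summed to species-level totals. An `O-`
#' prefix on the chain descriptor marks an alkyl/ether linkage and maps
#' the class to its `-O` variant (e.g. `"LPC O-18:1"` -> class `LPC-O`).
#' Oxygen/hydroxyl annotations such as `";O2"` are carried as an opaque
#' suffix, not interpreted.
#'
#' @param name shorthand string `"<CLASS> <C>:<DB>"`.
#' @return a [lipid_species()] (without IS assignment).
#' @examples
#' parse_shorthand("PC 16:0/18:1")  # class PC, 34 carbons, 1 double bond
#' parse_shorthand("LPC O-18:1")    # class LPC-O, ether-linked
#' @export
parse_shorthand <- function(name) {
  if (!is.character(name) || length(name) != 1 || is.na(name)) {
    stop("`name` must be a single shorthand string")
  }
  s <- trimws(name)
  parts <- regmatches(s, regexpr("^\\S+", s))
  if (!length(parts)) stop(sprintf("cannot parse shorthand %s", dQuote(name)))
  cls <- parts
  rest <- trimws(sub("^\\S+\\s*", "", s))
  if (!nzchar(rest)) {
    stop(sprintf("malformed shorthand %s: missing chain descriptor", dQuote(name)))
  }
  ether <- grepl("^O-", rest)
  if (ether) rest <- sub("^O-", "", rest)
  if (ether) cls <- paste0(cls, "-O")
  if (!cls %in% lipid_classes()) {
    stop(sprintf("unknown lipid class %s in %s", dQuote(cls), dQuote(name)))
  }
  ## split off an opaque ";..." suffix before reading the chains
  suffix <- ""
  if (grepl(";", rest, fixed = TRUE)) {
    suffix <- sub("^[^;]*", "", rest)
    rest <- sub(";.*$", "", rest)
  }
  chains <- strsplit(rest, "[/_]")[[1]]
  if (!length(chains)) {
    stop(sprintf("malformed shorthand %s: empty chain descriptor", dQuote(name)))
  }
  carbons <- 0L
  dbs <- 0L
  for (ch in chains) {
    m <- regmatches(ch, regexec("^([0-9]+):([0-9]+)$", ch))[[1]]
    if (length(m) != 3) {
      stop(sprintf("malformed chain token %s in %s", dQuote(ch), dQuote(name)))
    }
    carbons <- carbons + as.integer(m[2])
    dbs <- dbs + as.integer(m[3])
  }
  lipid_species(name = s, lipid_class = cls, total_carbons = carbons,
                total_double_bonds = dbs, ether_linked = ether,
                suffix = suffix)
}

#' Format a lipid species back to shorthand
#'
#' Species-level formatting; inverse of [parse_shorthand()] at the species
#' level (chain-level input round-trips through its species-level totals).
#'
#' @param species a [lipid_species()].
#' @return shorthand string.
#' @export
format_shorthand <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  base <- sub("-O$", "", species$lipid_class)
  sprintf("%s %s%d:%d%s", base, if (species$ether_linked) "O-" else "",
          species$total_carbons, species$total_double_bonds, species$suffix)
}

#' Assign the most structurally similar internal standard
#'
#' Among internal standards of the species' own lipid class, picks the one
#' minimising `|delta carbons|`, breaking ties by `|delta double bonds|`
#' and then by lexicographic IS id — a deterministic, auditable rendering
#' of the "most structurally similar IS" rule.
#'
#' @param species a [lipid_species()].
#' @param standards data frame of internal standards with columns
#'   `id`, `lipid_class`, `carbons`, `double_bonds`, `spike_concentration`.
#' @return one-row data frame (the chosen standard).
#' @export
assign_internal_standard <- function(species, standards) {
  stopifnot(inherits(species, "lipid_species"))
  required <- c("id", "lipid_class", "carbons", "double_bonds",
                "spike_concentration")
  if (!all(required %in% names(standards))) {
    stop("`standards` must have columns ", paste(required, collapse = ", "))
  }
  cand <- standards[standards$lipid_class == species$lipid_class, , drop = FALSE]
  if (!nrow(cand)) {
    stop(sprintf("no internal standard available for class %s",
                 species$lipid_class))
  }
  dc <- abs(cand$carbons - species$total_carbons)
  ddb <- abs(cand$double_bonds - species$total_double_bonds)
  cand[order(dc, ddb, cand$id), , drop = FALSE][1, , drop = FALSE]
}

## canonical registry columns (the TSV interface adds the _nM unit suffix)
registry_columns <- function() {
  c("name", "class", "carbons", "double_bonds",
    "internal_standard_id", "is_spike_concentration_nM")
}

#' Read / write a transition registry TSV
#'
#' The registry table holds one row per measured lipid transition with a
#' strict header: `name`, `class`, `carbons`, `double_bonds`,
#' `internal_standard_id`, `is_spike_concentration_nM` (an optional
#' `fragment_carbons` column is accepted for fragment-aware isotope
#' correction). UTF-8, tab-separated.
#'
#' @param path file path.
#' @return a registry `data.frame`.
#' @export
read_registry <- function(path) {
  df <- read.delim(path, check.names = FALSE, fileEncoding = "UTF-8")
  req <- registry_columns()
  extra <- setdiff(names(df), c(req, "fragment_carbons"))
  if (!all(req %in% names(df)) || length(extra)) {
    stop("registry header must be exactly: ",
         paste(req, collapse = ", "),
         " (optional: fragment_carbons); got: ",
         paste(names(df), collapse = ", "))
  }
  validate_registry(df)
}

#' @rdname read_registry
#' @param registry a registry `data.frame`.
#' @export
write_registry <- function(registry, path) {
  keep <- intersect(c(registry_columns(), "fragment_carbons"), names(registry))
  write.table(registry[, keep], path, sep = "\t", row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

## Validates classes, counts and IS consistency; returns the data frame.
validate_registry <- function(df) {
  bad <- setdiff(unique(df$class), lipid_classes())
  if (length(bad)) stop("unknown lipid class(es): ", paste(bad, collapse = ", "))
  if (any(df$double_bonds > df$carbons)) {
    stop("registry rows with double_bonds > carbons: ",
         paste(df$name[df$double_bonds > df$carbons], collapse = ", "))
  }
  if (any(df$is_spike_concentration_nM <= 0)) {
    stop("IS spike concentrations must be > 0")
  }
  if (anyDuplicated(df$name)) {
    stop("duplicate lipid names in registry: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  ## one spike concentration per IS id
  sp <- tapply(df$is_spike_concentration_nM, df$internal_standard_id,
               function(v) length(unique(v)))
  if (any(sp > 1)) {
    stop("inconsistent spike concentration for IS id(s): ",
         paste(names(sp)[sp > 1], collapse = ", "))
  }
  df
}

#' Derive the internal-standard table from a registry
#'
#' @param registry a registry `data.frame` (see [read_registry()]).
#' @return data frame with one row per distinct internal standard:
#'   `id`, `lipid_class`, `spike_concentration` (nmol/L).
#' @export
registry_standards <- function(registry) {
  u <- !duplicated(registry$internal_standard_id)
  data.frame(id = registry$internal_standard_id[u],
             lipid_class = registry$class[u],
             spike_concentration = registry$is_spike_concentration_nM[u],
             stringsAsFactors = FALSE)
}
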