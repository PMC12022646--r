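#' M+2 isotopologue fraction of a carbon skeleton
#'
#' Probability that a molecule with `n` carbons contains exactly two 13C
#' atoms, under the binomial model with natural 13C abundance
#' p = 0.0107: `choose(n, 2) * p^2 * (1-p)^(n-2)`. This is the fraction
#' of a species' monoisotopic signal that appears two mass units higher
#' and, at unit quadrupole resolution, on the SRM transition of the
#' same-class species with one more double bond removed (i.e. one fewer
#' double bond... see [interference_graph()] for the direction).
#'
#' @param n_carbons integer vector of carbon counts.
#' @param p natural 13C abundance (default 0.0107).
#' @return numeric vector of M+2 fractions; 0 where `n_carbons < 2`.
#' @examples
#' m2_fraction(2)   # 0.0107^2 = 1.1449e-4
#' @export
m2_fraction <- function(n_carbons, p = 0.0107) {
  n <- as.numeric(n_carbons)
  out <- ifelse(n < 2, 0, choose(n, 2) * p^2 * (1 - p)^(pmax(n - 2, 0)))
  unname(out)
}

#' Build the type-II isotopic interference graph
#'
#' In class-separated SRM acquisition, same-class species coelute, and the
#' M+2 isotopologue (two 13C) of a species overlaps the transition of the
#' same-class, same-carbon species with one FEWER double bond (each double
#' bond removes two hydrogens, so that species is two mass units heavier —
#' exactly where the donor's M+2 falls). Edges therefore run
#' donor (db = d+1) -> acceptor (db = d) with weight
#' `f = m2_fraction(carbons)`, optionally scaled by the share of carbon
#' pairs retained in the monitored fragment.
#'
#' @param registry registry `data.frame`; rows define the nodes. For
#'   `mode = "precursor_and_fragment"` a `fragment_carbons` column gives
#'   the carbons retained in the monitored fragment; if absent the mode
#'   falls back to `precursor_only` with a warning.
#' @param mode `"precursor_only"` (full precursor M+2 fraction) or
#'   `"precursor_and_fragment"` (both heavy carbons must sit in the
#'   monitored fragment: `f` scaled by
#'   `choose(fragment_carbons, 2) / choose(carbons, 2)`).
#' @return data frame of class `interference_graph` with columns
#'   `donor`, `acceptor`, `f`.
#' @export
interference_graph <- function(registry,
                               mode = c("precursor_only",
                                        "precursor_and_fragment")) {
  mode <- match.arg(mode)
  if (mode == "precursor_and_fragment" &&
      !"fragment_carbons" %in% names(registry)) {
    warning("registry has no `fragment_carbons` column; falling back to precursor_only")
    mode <- "precursor_only"
  }
  key <- paste(registry$class, registry$carbons)
  edges <- list()
  for (k in unique(key)) {
    g <- registry[key == k, , drop = FALSE]
    if (nrow(g) < 2) next
    g <- g[order(g$double_bonds), , drop = FALSE]
    for (i in seq_len(nrow(g) - 1)) {
      if (g$double_bonds[i + 1] == g$double_bonds[i] + 1) {
        donor <- g[i + 1, ]     # one more double bond, 2 Da lighter
        acceptor <- g[i, ]
        f <- m2_fraction(donor$carbons)
        if (mode == "precursor_and_fragment") {
          nf <- donor$fragment_carbons
          f <- f * ifelse(is.na(nf) | nf < 2, 1,
                          choose(pmin(nf, donor$carbons), 2) /
                            choose(donor$carbons, 2))
        }
        edges[[length(edges) + 1]] <-
          data.frame(donor = donor$name, acceptor = acceptor$name, f = f,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(edges)) do.call(rbind, edges) else
    data.frame(donor = character(), acceptor = character(), f = numeric())
  rownames(out) <- NULL
  if (any(out$f < 0 | out$f >= 1)) stop("edge weights must satisfy 0 <= f < 1")
  structure(out, class = c("interference_graph", "data.frame"), mode = mode)
}

#' Read an expert-supplied interference edge list
#'
#' TSV with columns `donor`, `acceptor`, `f`; checked for `0 <= f < 1`
#' and acyclicity.
#'
#' @param path file path.
#' @return an `interference_graph` data frame.
#' @export
read_interference_edges <- function(path) {
  df <- read.delim(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!all(c("donor", "acceptor", "f") %in% names(df))) {
    stop("edge list must have columns donor, acceptor, f")
  }
  if (any(df$f < 0 | df$f >= 1)) stop("edge weights must satisfy 0 <= f < 1")
  topological_order(df)  # errors on cycles
  structure(df[, c("donor", "acceptor", "f")],
            class = c("interference_graph", "data.frame"), mode = "custom")
}

## Kahn's algorithm over the edge list; errors on cycles.
topological_order <- function(graph) {
  nodes <- unique(c(graph$donor, graph$acceptor))
  if (!length(nodes)) return(character())
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(graph$acceptor)
  indeg[names(tab)] <- as.integer(tab)
  order <- character(0)
  active <- rep(TRUE, nrow(graph))
  queue <- nodes[indeg == 0]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    out <- which(active & graph$donor == v)
    for (e in out) {
      active[e] <- FALSE
      a <- graph$acceptor[e]
      indeg[a] <- indeg[a] - 1L
      if (indeg[a] == 0L) queue <- c(queue, a)
    }
  }
  if (length(order) != length(nodes)) {
    stop("interference graph is cyclic; cannot correct")
  }
  order
}

#' Forward-simulate isotopic contamination
#'
#' The physical forward model of type-II interference: each acceptor
#' channel observes its own (clean) signal plus `f` times the clean
#' monoisotopic signal of its donor. Used by the synthetic generator and
#' as the exact-inverse oracle for [correct_isotopic_overlap()].
#'
#' @param mat numeric matrix or [abundance_matrix()]; columns include all
#'   graph nodes.
#' @param graph an [interference_graph()].
#' @return matrix of the same shape with contaminated acceptor columns.
#' @export
contaminate_isotopes <- function(mat, graph) {
  missing_cols <- setdiff(unique(c(graph$donor, graph$acceptor)), colnames(mat))
  if (length(missing_cols)) {
    stop("graph nodes absent from matrix: ", paste(missing_cols, collapse = ", "))
  }
  out <- mat
  for (e in seq_len(nrow(graph))) {
    out[, graph$acceptor[e]] <- out[, graph$acceptor[e]] +
      graph$f[e] * mat[, graph$donor[e]]
  }
  out
}

#' Correct type-II isotopic overlap
#'
#' Processes species in topological order of the interference graph (in
#' each (class, carbons) chain: decreasing double-bond count, since the
#' most unsaturated species has no donor): each acceptor's observed
#' signal is reduced by `f` times its donor's already-corrected signal.
#' This inverts [contaminate_isotopes()] exactly on non-negative input;
#' results driven below zero by noise are clipped to 0 and counted in the
#' `n_clipped` attribute.
#'
#' @param mat an [abundance_matrix()] in state `raw_area` (or a bare
#'   numeric matrix, returned as such).
#' @param graph an [interference_graph()] whose nodes are matrix columns.
#' @param clip clip negative corrected values to zero (default TRUE).
#' @return corrected matrix; for `abundance_matrix` input the state
#'   advances to `isotope_corrected`.
#' @export
correct_isotopic_overlap <- function(mat, graph, clip = TRUE) {
  is_am <- inherits(mat, "abundance_matrix")
  if (is_am && am_state(mat) != "raw_area") {
    stop("isotopic overlap is corrected on the area scale (state raw_area), got ",
         am_state(mat))
  }
  missing_cols <- setdiff(unique(c(graph$donor, graph$acceptor)), colnames(mat))
  if (length(missing_cols)) {
    stop("graph nodes absent from matrix: ", paste(missing_cols, collapse = ", "))
  }
  ord <- topological_order(graph)
  values <- if (is_am) unclass_matrix(mat) else mat
  n_clipped <- 0L
  for (v in ord) {
    inc <- which(graph$acceptor == v)
    for (e in inc) {
      values[, v] <- values[, v] - graph$f[e] * values[, graph$donor[e]]
    }
    if (length(inc) && clip) {
      neg <- values[, v] < 0
      n_clipped <- n_clipped + sum(neg)
      values[neg, v] <- 0
    }
  }
  if (is_am) {
    out <- advance_state(abundance_matrix(values, state = "raw_area",
                                          provenance = am_provenance(mat)),
                         "isotope_corrected", "correct_isotopic_overlap")
  } else {
    out <- values
  }
  attr(out, "n_clipped") <- n_clipped
  out
}
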