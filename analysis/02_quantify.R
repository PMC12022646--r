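#!/usr/bin/env Rscript

# Stage 2 — isotope correction and stable isotope dilution quantification.
#
# Removes type-II isotopic interference (the M+2 isotopologue of a species
# contaminating the transition of its same-class, same-carbon neighbour
# with one fewer double bond) on the area scale, then converts areas to
# concentrations as analyte/IS peak-area ratio times the IS spike.

suppressMessages(library(lipidcohort))

registry <- read_registry("results/registry.tsv")
areas <- read_abundance_csv("results/areas_raw.csv")

graph <- interference_graph(registry)
cat(sprintf("interference graph: %d edges over %d species\n",
            nrow(graph), nrow(registry)))
areas_c <- correct_isotopic_overlap(areas, graph)
cat(sprintf("%d cells clipped at zero during correction\n",
            attr(areas_c, "n_clipped")))

conc <- quantify(areas_c, registry)
cat(sprintf("quantified %d lipids (state: %s, units: %s)\n",
            ncol(conc), am_state(conc), am_units(conc)))
write_abundance_csv(conc, "results/concentrations.csv")
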