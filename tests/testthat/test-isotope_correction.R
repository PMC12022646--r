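test_that("M+2 fraction follows the carbon binomial closed form", {
  expect_equal(m2_fraction(2), 0.0107^2, tolerance = 1e-12)
  expect_equal(m2_fraction(2), 1.1449e-4, tolerance = 1e-9)
  expect_equal(m2_fraction(0), 0)
  expect_equal(m2_fraction(1), 0)
  # independent oracle: the k = 2 term of the full binomial distribution
  expect_equal(m2_fraction(40), dbinom(2, 40, 0.0107), tolerance = 1e-14)
  expect_equal(m2_fraction(c(10, 20, 52)), dbinom(2, c(10, 20, 52), 0.0107),
               tolerance = 1e-14)
})

test_that("interference edges run from one-more-double-bond donors to acceptors", {
  g <- interference_graph(tiny_registry())
  # PC 34 chain: 34:1 -> 34:0, 34:2 -> 34:1; TG 52: 52:2 -> 52:1
  expect_setequal(paste(g$donor, g$acceptor, sep = " -> "),
                  c("PC 34:1 -> PC 34:0", "PC 34:2 -> PC 34:1",
                    "TG 52:2 -> TG 52:1"))
  expect_equal(g$f[g$donor == "PC 34:1"], m2_fraction(34))
  expect_equal(g$f[g$donor == "TG 52:2"], m2_fraction(52))
  # PC 36:1 shares the class but not the carbon count: no edge
  expect_false(any(grepl("36", c(g$donor, g$acceptor))))
})

test_that("single-edge correction reproduces the worked example", {
  g <- structure(data.frame(donor = "A", acceptor = "B", f = 0.06),
                 class = c("interference_graph", "data.frame"))
  m <- matrix(c(1000, 160), 1, 2, dimnames = list("I1", c("A", "B")))
  out <- correct_isotopic_overlap(m, g)
  expect_equal(unname(out[1, "B"]), 100)   # 160 - 0.06 * 1000
  expect_equal(unname(out[1, "A"]), 1000)  # donors without donors unchanged
})

test_that("an empty graph is the identity", {
  g <- interference_graph(tiny_registry()[7, , drop = FALSE])  # single species
  expect_equal(nrow(g), 0)
  m <- matrix(runif(10), 2, 5, dimnames = list(NULL, letters[1:5]))
  expect_equal(correct_isotopic_overlap(m, g), m, ignore_attr = TRUE)
})

test_that("correction is the exact inverse of forward contamination", {
  # chain of 3 within one (class, carbons) group, truth constructed forward
  reg <- tiny_registry()
  g <- interference_graph(reg)
  set.seed(5)
  truth <- matrix(runif(7 * 6, 0, 1e5), 6, 7,
                  dimnames = list(sprintf("I%d", 1:6), reg$name))
  truth[1, "PC 34:2"] <- 0   # zeros stay exact
  obs <- contaminate_isotopes(truth, g)
  rec <- correct_isotopic_overlap(obs, g)
  expect_lt(max(abs(rec - truth) / pmax(truth, 1)), 1e-9)

  # property over random acyclic graphs and matrices
  for (rep in 1:15) {
    n_db <- sample(2:6, 1)
    regr <- data.frame(name = sprintf("PC 36:%d", 0:(n_db - 1)),
                       class = "PC", carbons = 36,
                       double_bonds = 0:(n_db - 1),
                       internal_standard_id = "x",
                       is_spike_concentration_nM = 1)
    gr <- interference_graph(regr)
    X <- matrix(runif(4 * n_db, 0, 1e6), 4, n_db,
                dimnames = list(NULL, regr$name))
    rec <- correct_isotopic_overlap(contaminate_isotopes(X, gr), gr)
    expect_lt(max(abs(rec - X) / pmax(X, 1)), 1e-9)
    # acceptors never exceed their observed signal
    obs <- contaminate_isotopes(X, gr)
    expect_true(all(rec <= obs + 1e-12))
  }
})

test_that("negative corrections clip at zero with a flag and cycles are rejected", {
  g <- structure(data.frame(donor = "A", acceptor = "B", f = 0.5),
                 class = c("interference_graph", "data.frame"))
  m <- matrix(c(1000, 100), 1, 2, dimnames = list("I1", c("A", "B")))
  out <- correct_isotopic_overlap(m, g)
  expect_equal(unname(out[1, "B"]), 0)
  expect_equal(attr(out, "n_clipped"), 1L)

  cyc <- data.frame(donor = c("A", "B"), acceptor = c("B", "A"),
                    f = c(0.1, 0.1))
  expect_error(correct_isotopic_overlap(m, cyc), "cyclic")
})

test_that("fragment-aware mode scales f by the carbon-pair share of the fragment", {
  reg <- tiny_registry()[1:3, ]
  reg$fragment_carbons <- c(18, 18, 18)
  g_full <- interference_graph(reg, mode = "precursor_only")
  g_frag <- interference_graph(reg, mode = "precursor_and_fragment")
  expect_equal(g_frag$f, g_full$f * choose(18, 2) / choose(34, 2))

  # no fragment column -> warned fallback
  expect_warning(g_fb <- interference_graph(tiny_registry()[1:3, ],
                                            mode = "precursor_and_fragment"),
                 "falling back")
  expect_equal(g_fb$f, g_full$f)
})

test_that("edge-list TSV override is validated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(donor = "PC 34:1", acceptor = "PC 34:0", f = 0.07),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  g <- read_interference_edges(path)
  expect_equal(g$f, 0.07)
  write.table(data.frame(donor = c("A", "B"), acceptor = c("B", "A"),
                         f = c(0.1, 0.2)),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_interference_edges(path), "cyclic")
})
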