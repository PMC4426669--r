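# Small hand-built count table: two conditions not needed for most of
# these, one is enough.
tiny_counts <- function(high, low, ids = sprintf("sh%02d", seq_along(high))) {
  out <- data.frame(shrna_id = ids, condition = "stress",
                    count_high = high, count_low = low,
                    stringsAsFactors = FALSE)
  class(out) <- c("bin_count_table", "data.frame")
  out
}

tiny_library <- function(ids, control) {
  lib <- data.frame(shrna_id = ids,
                    gene_id = ifelse(control, "CONTROL",
                                     paste0("G_", ids)),
                    is_control = control, stringsAsFactors = FALSE)
  class(lib) <- c("screen_library", "data.frame")
  lib
}

test_that("bin frequencies follow the pseudocount formula", {
  f <- compute_frequencies(tiny_counts(c(200, 100), c(150, 150)),
                           pseudocount = 0)
  expect_equal(f$freq_high, c(2 / 3, 1 / 3))
  expect_equal(sum(f$freq_low), 1)

  f2 <- compute_frequencies(tiny_counts(c(0, 50, 0), c(1, 1, 1)),
                            pseudocount = 0.5)
  expect_equal(f2$freq_high, c(0.5 / 51.5, 50.5 / 51.5, 0.5 / 51.5))

  # scale invariance at pseudocount 0
  fa <- compute_frequencies(tiny_counts(c(30, 60, 10), c(5, 5, 90)), 0)
  fb <- compute_frequencies(tiny_counts(c(300, 600, 100), c(50, 50, 900)), 0)
  expect_equal(fa$freq_high, fb$freq_high)
  expect_equal(fa$freq_low, fb$freq_low)

  expect_error(compute_frequencies(tiny_counts(c(0, 0), c(1, 1)), 0),
               "all-zero")
  expect_error(compute_frequencies(tiny_counts(c(-1, 2), c(1, 1))),
               "negative")
})

test_that("epsilon is the control-centered log2 High/Low ratio", {
  # symmetric table: controls at ratio 1, target A collapsed in High
  cts <- tiny_counts(c(0, 50, 25, 25), c(50, 0, 25, 25),
                     ids = c("A", "B", "C1", "C2"))
  lib <- tiny_library(c("A", "B", "C1", "C2"), c(FALSE, FALSE, TRUE, TRUE))
  eps <- compute_epsilon(compute_frequencies(cts, 0.5), lib)
  expect_equal(eps$epsilon[eps$shrna_id == "A"], log2(0.5 / 50.5),
               tolerance = 1e-12)
  expect_equal(log2(0.5 / 50.5), -6.658, tolerance = 1e-3)
  # control median is exactly zero after centering
  expect_identical(median(eps$epsilon[lib$is_control]), 0)

  # centering subtracts a non-zero control median
  cts2 <- tiny_counts(c(10, 20, 20), c(10, 10, 10), c("A", "C1", "C2"))
  lib2 <- tiny_library(c("A", "C1", "C2"), c(FALSE, TRUE, TRUE))
  eps2 <- compute_epsilon(compute_frequencies(cts2, 0), lib2)
  # A's raw ratio is 1 (equal freq shares cancel totals): check centering
  raw_a <- log2((10 / 50) / (10 / 30))
  raw_c <- log2((20 / 50) / (10 / 30))
  expect_equal(eps2$epsilon[eps2$shrna_id == "A"], raw_a - raw_c,
               tolerance = 1e-12)

  expect_error(compute_epsilon(compute_frequencies(cts, 0), lib), "zero")
  lib_noctrl <- tiny_library(c("A", "B", "C1", "C2"), rep(FALSE, 4))
  expect_error(compute_epsilon(compute_frequencies(cts, 0.5), lib_noctrl),
               "controls")
})

test_that("exact Mann-Whitney reproduces enumeration on spec instances", {
  r <- mann_whitney_exact(c(2.0, 2.1, 1.9), c(0, 0.1, -0.1, 0.05, -0.05))
  expect_equal(r$U, 15)
  expect_equal(r$p, 2 / 56)

  r2 <- mann_whitney_exact(0, c(-1, 1))
  expect_equal(r2$p, 1)

  # two-sided symmetry under negation
  x <- c(0.3, 1.2, -0.4); y <- c(0.1, -0.2, 0.5, 0.9)
  expect_equal(mann_whitney_exact(x, y)$p,
               mann_whitney_exact(-x, -y)$p)
  expect_error(mann_whitney_exact(numeric(0), 1), "empty")
  expect_error(mann_whitney_exact(1:7, 1:6), "<= 12")
})

test_that("exact Mann-Whitney agrees with the bitmask oracle (sweep)", {
  set.seed(42)
  for (n in 1:4) {
    for (m in 1:(8 - n)) {
      for (rep in 1:2) {
        # mix of continuous values and ties
        x <- sample(seq(0, 2, by = 0.5), n, replace = TRUE)
        y <- sample(seq(0, 2, by = 0.5), m, replace = TRUE)
        got <- mann_whitney_exact(x, y)
        expect_equal(got$U, oracle_u(x, y))
        expect_equal(got$p, oracle_mw_p(x, y), tolerance = 1e-12)
      }
    }
  }
})

test_that("asymptotic Mann-Whitney handles ties and degenerate input", {
  expect_equal(mann_whitney_asymptotic(rep(1, 5), rep(1, 9))$p, 1)
  x <- c(0.3, 1.2, -0.4, 0.8); y <- rnorm(40)
  expect_equal(mann_whitney_asymptotic(x, y)$p,
               mann_whitney_asymptotic(-x, -y)$p)
  # U bounds
  r <- mann_whitney_asymptotic(x, y)
  expect_true(r$U >= 0 && r$U <= length(x) * length(y))
})

test_that("gene scores flag thin genes and find a strong planted hit", {
  d <- screen_design(
    n_genes = 20, shrnas_per_gene = 25, n_controls = 1000,
    effects = data.frame(gene_id = "GENE0001", stress = 0,
                         stress_drug = 1.0))
  lib <- generate_library(d, seed = 1)
  cts <- simulate_sorted_screen(lib, d, depth = 1e6, seed = 2)
  eps <- compute_epsilon(compute_frequencies(cts), lib)
  sc <- gene_pvalues(eps, lib)
  hit <- sc[sc$gene_id == "GENE0001" & sc$condition == "stress_drug", ]
  expect_lt(hit$p, 1e-6)
  expect_equal(hit$direction, 1)
  # score sign convention and U bounds
  expect_true(all(sc$s[sc$scored] == sc$direction[sc$scored] *
                    (-log10(sc$p[sc$scored]))))
  expect_true(all(sc$p[sc$scored] > 0 & sc$p[sc$scored] <= 1))

  # a gene left with < min_shrnas usable hairpins is flagged, not scored
  eps2 <- eps
  drop <- lib$shrna_id[lib$gene_id == "GENE0002"][-1]
  eps2$usable[eps2$shrna_id %in% drop] <- FALSE
  sc2 <- gene_pvalues(eps2, lib)
  g2 <- sc2[sc2$gene_id == "GENE0002", ]
  expect_true(all(!g2$scored))
  expect_true(all(is.na(g2$p)))
})

test_that("gene_pvalues enforces its control preconditions", {
  lib <- tiny_library(c("A1", "A2", "C1", "C2"),
                      c(FALSE, FALSE, TRUE, TRUE))
  lib$gene_id[1:2] <- "G_A"  # one gene, two usable hairpins
  eps <- data.frame(shrna_id = lib$shrna_id, condition = "stress",
                    epsilon = c(1, 2, 0, 0.1), usable = TRUE)
  expect_error(gene_pvalues(eps, lib), ">= 30 controls")
  sc <- gene_pvalues(eps, lib, method = "exact")
  expect_true(sc$scored[1])
})

test_that("modifier classification follows the two-arm geometry", {
  mk <- function(s_stress, s_drug) {
    list(
      stress = data.frame(gene_id = "g", s = s_stress, scored = TRUE),
      drug = data.frame(gene_id = "g", s = s_drug, scored = TRUE))
  }
  cls <- function(ss, sd) {
    t <- mk(ss, sd)
    classify_modifiers(t$stress, t$drug)$class
  }
  expect_equal(cls(0.2, 8.0), "resistance")
  expect_equal(cls(-0.1, -6.0), "hypersensitizing")
  expect_equal(cls(7.0, 7.2), "reporter_modifier")
  expect_equal(cls(0.5, 1.0), "none")
  # dead zone: baseline displacement above tau_base blocks resistance
  expect_equal(cls(2.5, 8.0), "none")

  a <- data.frame(gene_id = c("g1", "g2"), s = c(0, 0), scored = TRUE)
  b <- data.frame(gene_id = c("g1", "g3"), s = c(0, 0), scored = TRUE)
  expect_error(classify_modifiers(a, b), "same genes")
})

test_that("every scored gene gets exactly one class", {
  set.seed(7)
  n <- 200
  a <- data.frame(gene_id = sprintf("g%03d", 1:n),
                  s = rnorm(n, sd = 3), scored = TRUE)
  b <- data.frame(gene_id = a$gene_id, s = rnorm(n, sd = 3), scored = TRUE)
  calls <- classify_modifiers(a, b)
  expect_equal(nrow(calls), n)
  expect_true(all(calls$class %in%
    c("resistance", "hypersensitizing", "reporter_modifier", "none")))
})
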