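test_that("library generation respects design geometry", {
  d <- screen_design(n_genes = 2, shrnas_per_gene = 3, n_controls = 4)
  lib <- generate_library(d, seed = 1)
  expect_equal(nrow(lib), 10)
  expect_equal(sum(lib$is_control), 4)
  expect_true(all(table(lib$gene_id[!lib$is_control]) == 3))

  # default-scale arithmetic: 500 * 25 + 1000
  lib2 <- generate_library(null_screen_design(500), seed = 1)
  expect_equal(nrow(lib2), 13500)

  # full published-scale geometry is accepted
  d3 <- screen_design(n_genes = 2933, shrnas_per_gene = 25)
  lib3 <- generate_library(d3, seed = 1)
  expect_equal(nrow(lib3), 2933 * 25 + 1000)

  expect_error(screen_design(n_genes = 0), "positive")
  expect_error(screen_design(n_genes = 2, baseline_abundance = c(1, 2)),
               "length")
})

test_that("abundances are positive, normalized, and deterministic", {
  d <- screen_design(n_genes = 5, shrnas_per_gene = 4, n_controls = 10)
  lib <- generate_library(d, seed = 7)
  expect_true(all(lib$abundance > 0))
  expect_equal(sum(lib$abundance), 1, tolerance = 1e-12)
  expect_identical(lib, generate_library(d, seed = 7))
  # controls carry zero effect in every condition
  expect_true(all(lib$delta_stress[lib$is_control] == 0))
  expect_true(all(lib$delta_stress_drug[lib$is_control] == 0))
})

test_that("sorted-screen counts are multinomial per bin and reproducible", {
  d <- screen_design(n_genes = 4, shrnas_per_gene = 5, n_controls = 20)
  lib <- generate_library(d, seed = 1)
  cts <- simulate_sorted_screen(lib, d, depth = 5000, seed = 3)
  for (cond in d$conditions) {
    i <- cts$condition == cond
    expect_equal(sum(cts$count_high[i]), 5000)
    expect_equal(sum(cts$count_low[i]), 5000)
  }
  expect_true(all(cts$count_high >= 0 & cts$count_low >= 0))
  expect_identical(cts, simulate_sorted_screen(lib, d, depth = 5000, seed = 3))
  expect_false(identical(
    cts, simulate_sorted_screen(lib, d, depth = 5000, seed = 4)))
  expect_error(simulate_sorted_screen(lib, d, depth = 0), "depth")
  expect_error(simulate_sorted_screen(lib, d, dispersion = -1), "dispersion")
})

test_that("a strong positive effect drives extreme High:Low enrichment", {
  # delta = +10 puts essentially all of that hairpin's cells beyond the
  # pooled 2/3 quantile: High:Low count ratio must exceed 50 at high depth
  d <- screen_design(n_genes = 2, shrnas_per_gene = 2, n_controls = 200,
                     effects = data.frame(gene_id = "GENE0001",
                                          stress = 10, stress_drug = 10))
  lib <- generate_library(d, seed = 1)
  cts <- simulate_sorted_screen(lib, d, depth = 1e6, seed = 2,
                                cells_per_shrna = 500)
  hit <- cts$condition == "stress" & grepl("GENE0001", cts$shrna_id)
  ratio <- (cts$count_high[hit] + 0.5) / (cts$count_low[hit] + 0.5)
  expect_true(all(ratio > 50))
})

test_that("mean neutral epsilon is unbiased across seeds", {
  d <- null_screen_design(50)
  seed_means <- vapply(1:20, function(s) {
    lib <- generate_library(d, seed = s)
    cts <- simulate_sorted_screen(lib, d, depth = 1e5, seed = s + 500)
    eps <- compute_epsilon(compute_frequencies(cts), lib)
    i <- eps$condition == "stress" & eps$usable &
      !grepl("CTRL", eps$shrna_id)
    mean(eps$epsilon[i])
  }, numeric(1))
  z <- mean(seed_means) / (sd(seed_means) / sqrt(length(seed_means)))
  expect_lt(abs(z), 3)
})

test_that("noise-free gradient reproduces the Gaussian peak exactly", {
  pr <- data.frame(protein_id = "P1", mu_ctrl = 7, mu_drug = 7, width = 1,
                   amplitude = 1, n_peptides = 1)
  gd <- gradient_design(pr, noise_cv = 0)
  tab <- simulate_gradient(gd, "ctrl", seed = 1)
  one <- tab[tab$replicate == 1, ]
  expect_equal(one$intensity, exp(-(1:13 - 7)^2 / 2), tolerance = 1e-13)

  # multi-peptide proteins still sum to the closed form when noiseless
  pr$n_peptides <- 7
  tab2 <- simulate_gradient(gradient_design(pr, noise_cv = 0), "ctrl", 1)
  expect_equal(tab2$intensity[tab2$replicate == 2],
               exp(-(1:13 - 7)^2 / 2), tolerance = 1e-13)
})

test_that("gradient replicates are distinct but reproducible", {
  gd <- dimer_gradient_design()
  a <- simulate_gradient(gd, "drug", seed = 5)
  b <- simulate_gradient(gd, "drug", seed = 5)
  expect_identical(a, b)
  r1 <- a$intensity[a$replicate == 1]
  r2 <- a$intensity[a$replicate == 2]
  expect_false(identical(r1, r2))
  expect_error(
    gradient_design(data.frame(protein_id = "P", mu_ctrl = 0, mu_drug = 7,
                               width = 1, amplitude = 1, n_peptides = 1)),
    "peak fractions")
})

test_that("decay generator matches its closed form", {
  # F(1) = 0.5 for k = ln 2, no plateau, no noise
  p <- decay_preset("custom", k = log(2), noise_sd = 0,
                    timepoints = c(0, 1), n_rep = 1)
  d <- simulate_decay(p, seed = 1)
  expect_equal(d$bound_fraction[d$time_min == 1], 0.5, tolerance = 1e-12)

  # intrinsic exchange: 20% released after 20 min
  pi_ <- decay_preset("intrinsic", noise_sd = 0,
                      timepoints = c(0, 20), n_rep = 1)
  di <- simulate_decay(pi_, seed = 1)
  expect_equal(di$bound_fraction[di$time_min == 20], 0.800,
               tolerance = 1e-12)

  # GEF-catalyzed: F(10) = 2^(-10/3.2)
  pg <- decay_preset("gef_basal", noise_sd = 0, timepoints = c(0, 10),
                     n_rep = 1)
  dg <- simulate_decay(pg, seed = 1)
  expect_equal(dg$bound_fraction[dg$time_min == 10], 2^(-10 / 3.2),
               tolerance = 1e-12)

  expect_error(decay_preset("no_such_preset"), "unknown decay preset")
  expect_error(decay_preset("custom", k = 1, timepoints = c(2, 1)),
               "increasing")
})

test_that("decay noise is clipped to [0, 1.05] and seeded", {
  p <- decay_preset("gef_isrib", noise_sd = 0.5, n_rep = 5)
  d <- simulate_decay(p, seed = 9)
  expect_true(all(d$bound_fraction >= 0 & d$bound_fraction <= 1.05))
  expect_identical(d, simulate_decay(p, seed = 9))
})

test_that("dose-response generator matches the 4PL closed form", {
  p <- dose_preset("custom", ec50 = 1e-8, noise_cv = 0, n_rep = 1,
                   doses = c(1e-6, 1e-7, 1e-8, 1e-9, 1e-10))
  d <- simulate_dose_response(p, seed = 1)
  # half-maximal response at dose = ec50
  expect_equal(d$response[d$dose_molar == 1e-8], (100 + 10) / 2,
               tolerance = 1e-12)
  # saturating dose approaches the top asymptote
  p2 <- dose_preset("custom", ec50 = 1e-12, noise_cv = 0, n_rep = 1,
                    doses = c(1e-3, 1e-5, 1e-7, 1e-8, 1e-9))
  d2 <- simulate_dose_response(p2, seed = 1)
  expect_equal(d2$response[d2$dose_molar == 1e-3], 100, tolerance = 1e-3)

  expect_error(dose_preset("custom", ec50 = -1), "ec50")
  expect_error(dose_preset("A1", doses = c(1, 1, 2, 3, 4) * 1e-9),
               "distinct")
  expect_error(dose_preset("no_such_analog"), "unknown dose preset")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_decay(decay_preset("gef_basal"), seed = 1))
  invisible(simulate_dose_response(dose_preset("A1"), seed = 1))
  invisible(simulate_gradient(dimer_gradient_design(), "ctrl", seed = 1))
  expect_identical(.Random.seed, before)
})
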