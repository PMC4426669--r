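#' Design of a pooled FACS-sorted shRNA screen
#'
#' Describes the geometry and planted truth of a simulated pooled
#' screen: how many genes, how many hairpins per gene, how many
#' non-targeting negative controls, and the per-gene reporter shift
#' `delta` in each condition. `delta` is expressed in units of the
#' within-cell reporter standard deviation (fixed at 1), so
#' `delta = +1` moves a knockdown population one reporter SD toward the
#' High bin.
#'
#' @param n_genes number of targeted genes.
#' @param shrnas_per_gene hairpins per gene (default 25, the average in
#'   the screened proteostasis sub-library).
#' @param n_controls number of negative-control hairpins (default 1000;
#'   the screened library carries >1000).
#' @param conditions ordered condition labels; the first is the
#'   stress-only arm, the second the stress + drug arm.
#' @param effects `NULL` (all-neutral) or a data.frame with column
#'   `gene_id` plus one numeric delta column per condition.
#' @param baseline_abundance optional per-shRNA relative abundances
#'   (length `n_genes * shrnas_per_gene + n_controls`, positive, summing
#'   to 1). When `NULL`, [generate_library()] draws mildly variable
#'   lognormal abundances (sdlog `abundance_sdlog`), emulating uneven
#'   library representation.
#' @param abundance_sdlog sdlog of the lognormal abundance draw.
#' @return an object of class `screen_design`.
#' @export
screen_design <- function(n_genes,
                          shrnas_per_gene = 25,
                          n_controls = 1000,
                          conditions = c("stress", "stress_drug"),
                          effects = NULL,
                          baseline_abundance = NULL,
                          abundance_sdlog = 0.5) {
  if (n_genes < 1 || shrnas_per_gene < 1 || n_controls < 1) {
    stopf("n_genes, shrnas_per_gene and n_controls must be positive")
  }
  if (length(conditions) < 1 || anyDuplicated(conditions)) {
    stopf("conditions must be distinct labels")
  }
  n_shrna <- n_genes * shrnas_per_gene + n_controls
  if (!is.null(baseline_abundance)) {
    if (length(baseline_abundance) != n_shrna) {
      stopf("baseline_abundance must have length %d", n_shrna)
    }
    if (any(baseline_abundance <= 0)) stopf("abundances must be positive")
    if (abs(sum(baseline_abundance) - 1) > 1e-9) {
      stopf("abundances must sum to 1 (within 1e-9)")
    }
  }
  if (!is.null(effects)) {
    if (!is.data.frame(effects) || !"gene_id" %in% names(effects)) {
      stopf("effects must be a data.frame with a gene_id column")
    }
    missing_cond <- setdiff(conditions, names(effects))
    if (length(missing_cond)) {
      stopf("effects lacks delta column(s): %s",
            paste(missing_cond, collapse = ", "))
    }
  }
  structure(
    list(n_genes = as.integer(n_genes),
         shrnas_per_gene = as.integer(shrnas_per_gene),
         n_controls = as.integer(n_controls),
         conditions = conditions,
         effects = effects,
         baseline_abundance = baseline_abundance,
         abundance_sdlog = abundance_sdlog),
    class = "screen_design")
}

#' Demo screen design with planted modifier genes
#'
#' 500 genes x 25 shRNAs + 1000 negative controls, with recoverable
#' planted truth: 5 drug-resistance genes (`delta = +1.0` only in the
#' drug arm), 3 hypersensitizers (`delta = -0.8` only in the drug arm)
#' and 10 reporter modifiers (`delta = -0.8` in both arms). Gene ids of
#' the planted classes are retrievable from the `"planted"` attribute.
#'
#' @param n_genes total genes (default 500).
#' @return a `screen_design` with an attached `planted` attribute.
#' @export
demo_screen_design <- function(n_genes = 500) {
  if (n_genes < 18) stopf("demo design needs at least 18 genes")
  gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  resistance <- gene_ids[1:5]
  hypersens <- gene_ids[6:8]
  reporter <- gene_ids[9:18]
  eff <- data.frame(gene_id = c(resistance, hypersens, reporter),
                    stress = c(rep(0, 8), rep(-0.8, 10)),
                    stress_drug = c(rep(1.0, 5), rep(-0.8, 3), rep(-0.8, 10)),
                    stringsAsFactors = FALSE)
  d <- screen_design(n_genes = n_genes, effects = eff)
  attr(d, "planted") <- list(resistance = resistance,
                             hypersensitizing = hypersens,
                             reporter_modifier = reporter)
  d
}

#' All-neutral screen design for null calibration
#'
#' @param n_genes number of genes (default 500).
#' @inheritParams screen_design
#' @return a `screen_design` with every delta equal to zero.
#' @export
null_screen_design <- function(n_genes = 500, shrnas_per_gene = 25,
                               n_controls = 1000) {
  screen_design(n_genes = n_genes, shrnas_per_gene = shrnas_per_gene,
                n_controls = n_controls)
}

#' Instantiate the shRNA library of a screen design
#'
#' Expands a [screen_design()] into one row per hairpin with its gene
#' assignment (negative controls carry `gene_id = "CONTROL"`), baseline
#' abundance and per-condition reporter shift delta. Deterministic for a
#' fixed seed.
#'
#' @param design a `screen_design`.
#' @param seed integer seed.
#' @return a data.frame of class `screen_library` with columns
#'   `shrna_id`, `gene_id`, `is_control`, `abundance` and one
#'   `delta_<condition>` column per condition.
#' @export
generate_library <- function(design, seed = 0) {
  stopifnot(inherits(design, "screen_design"))
  gene_ids <- sprintf("GENE%04d", seq_len(design$n_genes))
  lib <- data.frame(
    shrna_id = c(sprintf("%s_sh%02d",
                         rep(gene_ids, each = design$shrnas_per_gene),
                         rep(seq_len(design$shrnas_per_gene), design$n_genes)),
                 sprintf("CTRL_sh%04d", seq_len(design$n_controls))),
    gene_id = c(rep(gene_ids, each = design$shrnas_per_gene),
                rep("CONTROL", design$n_controls)),
    stringsAsFactors = FALSE)
  lib$is_control <- lib$gene_id == "CONTROL"
  n <- nrow(lib)
  if (is.null(design$baseline_abundance)) {
    ab <- with_seed(seed, rlnorm(n, meanlog = 0, sdlog = design$abundance_sdlog))
    lib$abundance <- ab / sum(ab)
  } else {
    lib$abundance <- design$baseline_abundance
  }
  for (cond in design$conditions) {
    delta <- rep(0, n)
    if (!is.null(design$effects)) {
      idx <- match(lib$gene_id, design$effects$gene_id)
      hit <- !is.na(idx) & !lib$is_control
      delta[hit] <- design$effects[[cond]][idx[hit]]
    }
    lib[[paste0("delta_", cond)]] <- delta
  }
  class(lib) <- c("screen_library", "data.frame")
  lib
}

#' Simulate sorting and sequencing of a pooled reporter screen
#'
#' Emulates the FACS-sorted screen readout. For each condition, cells
#' carrying hairpin *s* express the reporter at
#' `Normal(delta_s, 1)`; the pooled population is cut at its empirical
#' 1/3 and 2/3 quantiles; the bottom and top thirds form the Low and
#' High bins; and each bin is sequenced to `depth` reads drawn
#' multinomially over the bin's hairpin composition. With
#' `dispersion > 0`, counts are instead drawn per hairpin from a
#' negative binomial with size `1/dispersion` (counts then no longer
#' sum exactly to `depth`).
#'
#' @param library a `screen_library` from [generate_library()].
#' @param design the matching `screen_design` (supplies condition labels).
#' @param depth sequencing reads per bin.
#' @param dispersion negative-binomial overdispersion (0 = multinomial).
#' @param cells_per_shrna simulated cells per library hairpin
#'   (coverage; default 100).
#' @param seed integer seed.
#' @return a data.frame of class `bin_count_table` with columns
#'   `shrna_id`, `condition`, `count_high`, `count_low`.
#' @export
simulate_sorted_screen <- function(library, design, depth = 1e6,
                                   dispersion = 0, cells_per_shrna = 100,
                                   seed = 0) {
  stopifnot(inherits(library, "screen_library"))
  if (nrow(library) == 0) stopf("empty library")
  if (depth <= 0) stopf("depth must be positive")
  if (dispersion < 0) stopf("dispersion must be non-negative")
  n <- nrow(library)
  ncells <- as.integer(round(cells_per_shrna * n))
  with_seed(seed, {
    out <- lapply(design$conditions, function(cond) {
      delta <- library[[paste0("delta_", cond)]]
      idx <- sample.int(n, ncells, replace = TRUE, prob = library$abundance)
      r <- rnorm(ncells) + delta[idx]
      thr <- quantile(r, c(1 / 3, 2 / 3), names = FALSE)
      comp_low <- tabulate(idx[r <= thr[1]], nbins = n)
      comp_high <- tabulate(idx[r >= thr[2]], nbins = n)
      draw <- function(comp) {
        p <- comp / sum(comp)
        if (dispersion > 0) {
          rnbinom(n, mu = depth * p, size = 1 / dispersion)
        } else {
          as.integer(rmultinom(1, size = depth, prob = p))
        }
      }
      data.frame(shrna_id = library$shrna_id,
                 condition = cond,
                 count_high = draw(comp_high),
                 count_low = draw(comp_low),
                 stringsAsFactors = FALSE)
    })
    counts <- do.call(rbind, out)
    rownames(counts) <- NULL
    class(counts) <- c("bin_count_table", "data.frame")
    counts
  })
}
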