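#' Per-shRNA bin frequencies from sequencing counts
#'
#' Within each (bin, condition), frequency =
#' `(count + pseudocount) / sum(count + pseudocount)`. The default
#' pseudocount of 0.5 keeps downstream log-ratios finite for hairpins
#' that drop out of one bin.
#'
#' @param counts a `bin_count_table` (columns `shrna_id`, `condition`,
#'   `count_high`, `count_low`).
#' @param pseudocount non-negative pseudocount added per hairpin per bin.
#' @return a data.frame of class `frequency_table` with the count
#'   columns plus `freq_high`, `freq_low` (each summing to 1 within a
#'   condition).
#' @export
compute_frequencies <- function(counts, pseudocount = 0.5) {
  req <- c("shrna_id", "condition", "count_high", "count_low")
  if (!all(req %in% names(counts))) {
    stopf("counts must have columns: %s", paste(req, collapse = ", "))
  }
  if (pseudocount < 0) stopf("pseudocount must be non-negative")
  if (any(counts$count_high < 0) || any(counts$count_low < 0)) {
    stopf("negative counts")
  }
  out <- counts
  for (cond in unique(out$condition)) {
    i <- out$condition == cond
    for (bin in c("high", "low")) {
      x <- out[[paste0("count_", bin)]][i] + pseudocount
      tot <- sum(x)
      if (tot == 0) stopf("all-zero %s bin in condition '%s'", bin, cond)
      out[[paste0("freq_", bin)]][i] <- x / tot
    }
  }
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Per-shRNA epsilon phenotypes
#'
#' The phenotype of hairpin *s* is the log2 ratio of its High-bin to
#' Low-bin frequency, recentered so that the median over
#' negative-control hairpins is exactly 0 in each condition. Hairpins
#' with zero raw counts in both bins carry no information and are
#' flagged unusable (excluded from centering and scoring).
#'
#' @param freqs a `frequency_table` from [compute_frequencies()].
#' @param library a `screen_library` (supplies the control flags).
#' @return a data.frame of class `phenotype_table` with columns
#'   `shrna_id`, `condition`, `epsilon`, `usable`.
#' @export
compute_epsilon <- function(freqs, library) {
  if (!all(c("freq_high", "freq_low") %in% names(freqs))) {
    stopf("freqs must come from compute_frequencies()")
  }
  is_ctrl <- library$is_control[match(freqs$shrna_id, library$shrna_id)]
  if (anyNA(is_ctrl)) stopf("freqs contains hairpins absent from the library")
  if (!any(is_ctrl)) stopf("library has no negative controls")
  if (any(freqs$freq_high == 0 | freqs$freq_low == 0)) {
    stopf("zero frequency encountered; use a positive pseudocount")
  }
  out <- data.frame(shrna_id = freqs$shrna_id, condition = freqs$condition,
                    epsilon = log2(freqs$freq_high / freqs$freq_low),
                    usable = (freqs$count_high + freqs$count_low) > 0,
                    stringsAsFactors = FALSE)
  for (cond in unique(out$condition)) {
    i <- out$condition == cond
    ctrl_med <- median(out$epsilon[i & is_ctrl & out$usable])
    out$epsilon[i] <- out$epsilon[i] - ctrl_med
  }
  class(out) <- c("phenotype_table", "data.frame")
  out
}

# Mann-Whitney U of x vs y with the 1/2-tie convention.
mw_u <- function(x, y) {
  n <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n)]) - n * (n + 1) / 2
}

#' Exact Mann-Whitney test by exhaustive enumeration
#'
#' Enumerates all `choose(nx + ny, nx)` assignments of the pooled
#' observed values to the two groups, computes U for each, and returns
#' the two-sided `p = min(1, 2 * min(P(U <= u), P(U >= u)))`. Handles
#' ties through the 1/2-count convention. Feasible for
#' `nx + ny <= 12`; serves as the oracle for the asymptotic path used
#' at screen scale.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list with elements `U` and `p`.
#' @export
mann_whitney_exact <- function(x, y) {
  if (!length(x) || !length(y)) stopf("empty input")
  n <- length(x); m <- length(y); N <- n + m
  if (N > 12) stopf("exact enumeration limited to nx + ny <= 12")
  pool <- c(x, y)
  u_obs <- mw_u(x, y)
  combs <- utils::combn(N, n)
  us <- apply(combs, 2, function(ix) mw_u(pool[ix], pool[-ix]))
  eps <- 1e-9
  p <- min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
  list(U = u_obs, p = p)
}

#' Asymptotic Mann-Whitney test (normal approximation)
#'
#' Normal approximation with tie correction of the null variance and a
#' 0.5 continuity correction; the default path at screen scale, where
#' the control pool (~1000 hairpins) makes enumeration infeasible.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list with elements `U` and `p` (two-sided).
#' @export
mann_whitney_asymptotic <- function(x, y) {
  if (!length(x) || !length(y)) stopf("empty input")
  n <- length(x); m <- length(y); N <- n + m
  u <- mw_u(x, y)
  mu <- n * m / 2
  ties <- rle(sort(c(x, y)))$lengths
  sig2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(list(U = u, p = 1))
  z <- max(0, (abs(u - mu) - 0.5)) / sqrt(sig2)
  list(U = u, p = min(1, 2 * pnorm(-z)))
}

#' Gene-level Mann-Whitney scores against the control null
#'
#' For each gene and condition, the usable epsilon phenotypes of the
#' gene's hairpins are compared to the usable negative-control
#' phenotypes; `direction` is the sign of the gene's median epsilon and
#' the signed score is `s = direction * (-log10 p)`. Genes with fewer
#' usable hairpins than `min_shrnas` are flagged (`scored = FALSE`),
#' not silently dropped.
#'
#' @param phenotypes a `phenotype_table` from [compute_epsilon()].
#' @param library a `screen_library`.
#' @param min_shrnas minimum usable hairpins for scoring (default 2).
#' @param method `"asymptotic"` (default) or `"exact"` (only feasible
#'   for tiny control pools).
#' @param bh add a Benjamini-Hochberg adjusted column `p_bh`.
#' @return a data.frame of class `gene_score_table` with columns
#'   `gene_id`, `condition`, `n_shrnas`, `U`, `p`, `direction`, `s`,
#'   `scored`.
#' @export
gene_pvalues <- function(phenotypes, library, min_shrnas = 2,
                         method = c("asymptotic", "exact"), bh = FALSE) {
  method <- match.arg(method)
  is_ctrl <- library$is_control[match(phenotypes$shrna_id, library$shrna_id)]
  gene_of <- library$gene_id[match(phenotypes$shrna_id, library$shrna_id)]
  if (anyNA(is_ctrl)) stopf("phenotypes contain hairpins absent from library")
  genes <- setdiff(unique(gene_of), "CONTROL")
  res <- list()
  for (cond in unique(phenotypes$condition)) {
    i <- phenotypes$condition == cond & phenotypes$usable
    ctrl_eps <- phenotypes$epsilon[i & is_ctrl]
    if (length(ctrl_eps) < 2) stopf("need >= 2 usable negative controls")
    if (method == "asymptotic" && length(ctrl_eps) < 30) {
      stopf("asymptotic path requires >= 30 controls; use method = 'exact'")
    }
    eps_cond <- phenotypes$epsilon[i]
    gene_cond <- gene_of[i]
    split_eps <- split(eps_cond, gene_cond)
    rows <- lapply(genes, function(g) {
      x <- split_eps[[g]]
      if (is.null(x) || length(x) < min_shrnas) {
        return(data.frame(gene_id = g, condition = cond,
                          n_shrnas = length(x) %||% 0L, U = NA_real_,
                          p = NA_real_, direction = NA_real_, s = NA_real_,
                          scored = FALSE, stringsAsFactors = FALSE))
      }
      fit <- if (method == "exact") mann_whitney_exact(x, ctrl_eps)
             else mann_whitney_asymptotic(x, ctrl_eps)
      dir <- sign(median(x))
      data.frame(gene_id = g, condition = cond, n_shrnas = length(x),
                 U = fit$U, p = fit$p, direction = dir,
                 s = dir * (-log10(fit$p)), scored = TRUE,
                 stringsAsFactors = FALSE)
    })
    res[[cond]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (bh) {
    out$p_bh <- NA_real_
    for (cond in unique(out$condition)) {
      i <- out$condition == cond & out$scored
      out$p_bh[i] <- stats::p.adjust(out$p[i], method = "BH")
    }
  }
  class(out) <- c("gene_score_table", "data.frame")
  out
}

#' Classify drug-sensitivity modifier genes from two screen arms
#'
#' With signed scores `s = direction * (-log10 p)` in the stress-only
#' and stress + drug arms, a gene is a `reporter_modifier` if its
#' stress-arm score alone is strong (`|s_stress| >= tau_sel`), else
#' `resistance` if knocking it down pushes the drug arm up
#' (`s_drug >= tau_sel`) while leaving the stress arm quiet
#' (`|s_stress| < tau_base`), else `hypersensitizing` for the mirrored
#' geometry, else `none`.
#'
#' @param scores_stress,scores_drug `gene_score_table`s for the two
#'   arms, covering the same genes.
#' @param tau_sel selection threshold on `|s|` (default 3, i.e.
#'   p <= 1e-3).
#' @param tau_base quiet-baseline threshold on `|s_stress|` (default 2).
#' @return a data.frame of class `modifier_calls` with columns
#'   `gene_id`, `s_stress`, `s_drug`, `class`.
#' @export
classify_modifiers <- function(scores_stress, scores_drug,
                               tau_sel = 3, tau_base = 2) {
  a <- scores_stress[order(scores_stress$gene_id), ]
  b <- scores_drug[order(scores_drug$gene_id), ]
  if (!identical(a$gene_id, b$gene_id)) {
    stopf("the two score tables must cover the same genes")
  }
  cls <- rep("none", nrow(a))
  ss <- a$s
  sd_ <- b$s
  ok <- a$scored & b$scored
  cls[ok & abs(ss) >= tau_sel] <- "reporter_modifier"
  res <- ok & cls == "none" & sd_ >= tau_sel & abs(ss) < tau_base
  cls[res] <- "resistance"
  hyp <- ok & cls == "none" & sd_ <= -tau_sel & abs(ss) < tau_base
  cls[hyp] <- "hypersensitizing"
  out <- data.frame(gene_id = a$gene_id, s_stress = ss, s_drug = sd_,
                    class = cls, stringsAsFactors = FALSE)
  class(out) <- c("modifier_calls", "data.frame")
  out
}
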