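#' Simulate an HPA-like RNA/IHC/gene-set bundle with planted sets
#'
#' Generates the three inputs of the weighting pipeline -- an expression
#' table, an IHC table and a gene set collection -- with known
#' tissue-specific structure planted in, so the full pipeline can be
#' exercised and validated without any external download.
#'
#' Baseline expression is log-normal per (gene, tissue) -- FPKM-style
#' right-skewed values. Each planted set claims a disjoint block of genes
#' whose expression is multiplied by `fold` in its target tissue and whose
#' protein is always detected (level >= `Low`) there. All other IHC calls
#' are detected with probability `ihc_detect_prob`, by default tilted so
#' that higher-expressed genes within a tissue are more likely to be
#' detected (mirroring RNA-protein concordance); planted blocks are
#' disjoint from each other. Decoy sets of matched sizes are drawn
#' uniformly from the whole gene universe.
#'
#' @param n_genes Number of genes (default 2000).
#' @param tissues Character vector of tissue names (default 10 generic
#'   tissues).
#' @param planted Data frame with columns `size`, `tissue`, `fold`
#'   describing the planted tissue-specific sets; every `fold` must be > 1
#'   and every `tissue` must appear in `tissues`. `NULL` for a null
#'   simulation with no planted structure.
#' @param n_decoys Number of decoy sets (default 100).
#' @param meanlog,sdlog Baseline log-normal expression parameters
#'   (default 1 and 1).
#' @param ihc_detect_prob Marginal detection probability for unplanted
#'   (gene, tissue) calls (default 0.8).
#' @param ihc_mode `"rank"` ties detection probability to the expression
#'   rank within the tissue (default); `"independent"` uses a flat
#'   probability.
#' @param rna_missing_prob Probability that an expression cell is dropped
#'   from the table (missing, not zero); default 0.
#' @param seed Integer seed; the output is fully reproducible from it.
#' @return A list with elements `expression` ([expression_table()]),
#'   `ihc` ([ihc_table()]), `sets` ([gene_set_collection()]), and `truth`,
#'   a tibble with one row per generated set: `set`, `planted`, `tissue`
#'   (target, `NA` for decoys), `fold`, `size`.
#' @examples
#' sim <- simulate_hpa(
#'   n_genes = 200, tissues = paste0("t", 1:4),
#'   planted = data.frame(size = 10, tissue = "t1", fold = 5),
#'   n_decoys = 5, seed = 1
#' )
#' sim$truth
#' @export
simulate_hpa <- function(n_genes = 2000,
                         tissues = paste0("tissue", 1:10),
                         planted = NULL,
                         n_decoys = 100,
                         meanlog = 1, sdlog = 1,
                         ihc_detect_prob = 0.8,
                         ihc_mode = c("rank", "independent"),
                         rna_missing_prob = 0,
                         seed = 1L) {
  ihc_mode <- match.arg(ihc_mode)
  tissues <- as.character(tissues)
  stopifnot(n_genes >= 2, length(tissues) >= 2)
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    stopifnot(all(c("size", "tissue", "fold") %in% names(planted)))
    if (any(planted$fold <= 1)) {
      abort("planted fold multipliers must be > 1")
    }
    if (!all(planted$tissue %in% tissues)) {
      abort("planted target tissues must be among the simulated tissues")
    }
    if (sum(planted$size) > n_genes) {
      abort("planted set sizes exceed the number of genes")
    }
  } else {
    planted <- tibble(size = integer(0), tissue = character(0),
                      fold = numeric(0))
  }
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  n_t <- length(tissues)

  expr <- matrix(rlnorm(n_genes * n_t, meanlog = meanlog, sdlog = sdlog),
                 nrow = n_genes, dimnames = list(genes, tissues))

  # planted blocks: disjoint gene ranges from the front of the gene list
  planted_sets <- list()
  offset <- 0L
  for (j in seq_len(nrow(planted))) {
    idx <- offset + seq_len(planted$size[j])
    offset <- offset + planted$size[j]
    expr[idx, planted$tissue[j]] <- expr[idx, planted$tissue[j]] * planted$fold[j]
    planted_sets[[paste0("PLANTED_", toupper(planted$tissue[j]), "_", j)]] <-
      genes[idx]
  }

  # IHC detection probability per cell
  if (ihc_mode == "rank") {
    r <- apply(expr, 2, function(v) rank(v, ties.method = "average") / n_genes)
    p_det <- pmin(0.99, pmax(0.01, ihc_detect_prob + 0.3 * (r - 0.5)))
  } else {
    p_det <- matrix(ihc_detect_prob, nrow = n_genes, ncol = n_t)
  }
  detected <- matrix(rbinom(n_genes * n_t, 1, as.vector(p_det)),
                     nrow = n_genes, dimnames = list(genes, tissues))
  for (j in seq_len(nrow(planted))) {
    members <- planted_sets[[j]]
    detected[members, planted$tissue[j]] <- 1L
  }
  lvl <- matrix("Not detected", nrow = n_genes, ncol = n_t,
                dimnames = list(genes, tissues))
  n_pos <- sum(detected == 1)
  lvl[detected == 1] <- sample(c("Low", "Medium", "High"), n_pos,
                               replace = TRUE, prob = c(0.5, 0.3, 0.2))

  expr_long <- as_tibble(as.data.frame.table(expr, stringsAsFactors = FALSE)) |>
    setNames(c("gene", "tissue", "value"))
  if (rna_missing_prob > 0) {
    keep <- runif(nrow(expr_long)) >= rna_missing_prob
    expr_long <- expr_long[keep, ]
  }
  ihc_long <- as_tibble(as.data.frame.table(lvl, stringsAsFactors = FALSE)) |>
    setNames(c("gene", "tissue", "level"))

  decoy_sizes <- if (nrow(planted) > 0) {
    rep(planted$size, length.out = n_decoys)
  } else {
    sample(10:50, n_decoys, replace = TRUE)
  }
  decoy_sets <- lapply(decoy_sizes, function(s) sample(genes, s))
  names(decoy_sets) <- sprintf("DECOY_%03d", seq_len(n_decoys))

  all_sets <- c(planted_sets, decoy_sets)
  gsc <- gene_set_collection(all_sets)
  truth <- tibble(
    set = names(all_sets),
    is_planted = c(rep(TRUE, length(planted_sets)), rep(FALSE, n_decoys)),
    tissue = c(planted$tissue, rep(NA_character_, n_decoys)),
    fold = c(planted$fold, rep(NA_real_, n_decoys)),
    size = lengths(all_sets)
  ) |> rename(planted = "is_planted")

  list(
    expression = expression_table(expr_long, genes = genes, tissues = tissues),
    ihc = ihc_table(ihc_long),
    sets = gsc,
    truth = truth
  )
}

#' Simulate a gene set testing p-value study for weighted FDR evaluation
#'
#' Generates per-set p-values under a null/alternative mixture together
#' with raw hypothesis weights whose association with the truth labels is
#' controlled: `"independent"` weights are drawn without reference to the
#' labels (the setting under which weighted BH must keep FDR control),
#' `"favorable"` weights are boosted on truly alternative sets (the setting
#' where p-value weighting should gain power), and `"adverse"` weights are
#' boosted on null sets (the problematic setting where power is lost).
#'
#' @param g Number of gene sets (default 2000).
#' @param pi0 Proportion of null sets in (0, 1]; null p-values are
#'   Uniform(0, 1).
#' @param alt_shape1,alt_shape2 Beta parameters for alternative p-values
#'   (default Beta(0.1, 1), stochastically small).
#' @param weight_association One of `"independent"`, `"favorable"`,
#'   `"adverse"`.
#' @param weight_boost Multiplicative boost applied to the targeted group's
#'   weights (default 10).
#' @param seed Integer seed.
#' @return A list with `pvals` (tibble `set`, `p`), `weights` (tibble
#'   `set`, `weight`), and `truth` (tibble `set`, `null` logical).
#' @export
simulate_pvalue_study <- function(g = 2000, pi0 = 1,
                                  alt_shape1 = 0.1, alt_shape2 = 1,
                                  weight_association = c("independent",
                                                         "favorable",
                                                         "adverse"),
                                  weight_boost = 10,
                                  seed = 1L) {
  weight_association <- match.arg(weight_association)
  stopifnot(g >= 1, pi0 >= 0, pi0 <= 1)
  set.seed(seed)
  sets <- sprintf("SET_%04d", seq_len(g))
  n_alt <- round(g * (1 - pi0))
  is_null <- rep(TRUE, g)
  if (n_alt > 0) is_null[sample.int(g, n_alt)] <- FALSE
  p <- runif(g)
  if (n_alt > 0) p[!is_null] <- rbeta(n_alt, alt_shape1, alt_shape2)
  p <- pmax(p, .Machine$double.xmin) # keep strictly inside (0, 1]
  w <- rlnorm(g, meanlog = 0, sdlog = 1)
  if (weight_association == "favorable") {
    w[!is_null] <- w[!is_null] * weight_boost
  } else if (weight_association == "adverse") {
    w[is_null] <- w[is_null] * weight_boost
  }
  list(
    pvals = tibble(set = sets, p = p),
    weights = tibble(set = sets, weight = w),
    truth = tibble(set = sets, null = is_null)
  )
}
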