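#' Expression fold-change component of the gene weight
#'
#' For each gene and tissue, the expression value divided by the gene's mean
#' expression over *all* tissues in the table. Missing cells are treated as
#' "assume the gene is not expressed": they contribute 0 to the mean and get
#' fold-change 0 themselves. A gene with zero mean (all zero or all missing)
#' gets fold-change 0 everywhere.
#'
#' @param expr An [expression_table()] with at least two tissues.
#' @return Tibble with columns `gene`, `tissue`, `e` covering the full grid.
#' @examples
#' et <- expression_table(tibble::tibble(
#'   gene = "G1", tissue = c("a", "b", "c", "d", "e"),
#'   value = c(10, 0, 0, 0, 0)
#' ))
#' expression_fold_change(et) # e = 5 in tissue "a", 0 elsewhere
#' @export
expression_fold_change <- function(expr) {
  stopifnot(inherits(expr, "expr_table"))
  tissues <- expr_tissues(expr)
  if (length(tissues) < 2) {
    abort("fold-change needs >= 2 tissues in the expression table")
  }
  m <- expr_matrix(expr, missing_as = 0)
  mu <- rowMeans(m)
  e <- m / ifelse(mu > 0, mu, 1)
  e[mu == 0, ] <- 0
  as_tibble(as.data.frame.table(e, stringsAsFactors = FALSE)) |>
    setNames(c("gene", "tissue", "e"))
}

#' IHC activity indicator
#'
#' Collapses IHC detection calls to a binary per-(gene, tissue) activity
#' indicator: 1 if the protein was detected at `Low` or greater in any cell
#' type, 0 if every record says `Not detected`, and 1 when no IHC record
#' exists for the pair (absent protein evidence leaves the weight to the RNA
#' side alone).
#'
#' @param ihc An [ihc_table()].
#' @param genes,tissues Character vectors defining the output grid.
#' @param drop_uncertain Drop records whose reliability is `Uncertain`
#'   before collapsing. Default `FALSE`.
#' @return Tibble with columns `gene`, `tissue`, `a` (0/1) over the full grid.
#' @export
ihc_activity <- function(ihc, genes, tissues, drop_uncertain = FALSE) {
  stopifnot(inherits(ihc, "ihc_table"))
  if (drop_uncertain) {
    ihc <- ihc[is.na(ihc$reliability) |
                 tolower(ihc$reliability) != "uncertain", , drop = FALSE]
  }
  grid <- tidyr::expand_grid(gene = as.character(genes),
                             tissue = as.character(tissues))
  rec <- ihc |>
    filter(.data$gene %in% genes, .data$tissue %in% tissues) |>
    mutate(ord = match(.data$level, IHC_LEVELS))
  rec <- if (nrow(rec) == 0) {
    tibble(gene = character(), tissue = character(), max_ord = integer())
  } else {
    rec |>
      group_by(.data$gene, .data$tissue) |>
      summarise(max_ord = max(.data$ord), .groups = "drop")
  }
  grid |>
    left_join(rec, by = c("gene", "tissue")) |>
    mutate(a = ifelse(is.na(.data$max_ord), 1, as.numeric(.data$max_ord > 1))) |>
    select("gene", "tissue", "a")
}

#' Tissue-specific gene weights
#'
#' Combines RNA and protein evidence into the per-gene per-tissue weight
#' `w = e * a`: the expression fold-change gated by the binary IHC activity
#' indicator. A non-zero weight requires evidence at both levels; when both
#' are available its magnitude is the fold-change of the gene in the target
#' tissue relative to its mean across tissues.
#'
#' Tissues are reconciled by intersecting the tissue names of the two
#' inputs (mismatches are reported); an IHC table with no records at all
#' imposes no restriction.
#'
#' @param expr An [expression_table()].
#' @param ihc An [ihc_table()].
#' @param tissues Optional explicit tissue subset (overrides the
#'   intersection rule).
#' @param drop_uncertain Passed to [ihc_activity()].
#' @return A tibble of class `gene_weights` with columns `gene`, `tissue`,
#'   `e`, `a`, `weight`, and grid attributes `genes`, `tissues`.
#' @export
gene_weights <- function(expr, ihc, tissues = NULL, drop_uncertain = FALSE) {
  stopifnot(inherits(expr, "expr_table"), inherits(ihc, "ihc_table"))
  expr_t <- expr_tissues(expr)
  if (is.null(tissues)) {
    if (nrow(ihc) == 0) {
      tissues <- expr_t
    } else {
      tissues <- intersect(expr_t, unique(ihc$tissue))
      dropped <- setdiff(union(expr_t, unique(ihc$tissue)), tissues)
      if (length(dropped) > 0) {
        inform(paste0(
          "tissue(s) present in only one input dropped from the grid: ",
          paste(dropped, collapse = ", ")
        ))
      }
    }
  } else {
    tissues <- intersect(tissues, expr_t)
  }
  if (length(tissues) == 0) {
    abort("no tissues shared between the expression and IHC inputs")
  }
  genes <- expr_genes(expr)
  e <- expression_fold_change(expr) |> filter(.data$tissue %in% tissues)
  a <- ihc_activity(ihc, genes, tissues, drop_uncertain = drop_uncertain)
  out <- inner_join(e, a, by = c("gene", "tissue")) |>
    mutate(weight = .data$e * .data$a)
  structure(
    out,
    genes = genes,
    tissues = as.character(tissues),
    class = c("gene_weights", class(tibble()))
  )
}

#' Competitive one-sided two-sample t-test on gene weights
#'
#' Tests whether the mean weight of a set's member genes exceeds the mean
#' weight of the complement (all other genes in the universe), and returns
#' the set weight `-log(p)`. The tail probability is evaluated directly on
#' the log scale (`stats::pt(log.p = TRUE)`), so extremely small p-values
#' produce large finite weights rather than overflowing to infinity.
#'
#' @param member Numeric vector of member-gene weights (length >= 2).
#' @param complement Numeric vector of complement-gene weights (length >= 2).
#' @param var_equal Use the pooled-variance t-test instead of the default
#'   Welch (unequal variances, Welch-Satterthwaite df) test. Member and
#'   complement sizes are typically wildly unbalanced, hence the Welch
#'   default.
#' @param log_base Base of the logarithm for the weight scale. Default is
#'   the natural log; `10` rescales all weights by `1/log(10)`.
#' @return One-row tibble with columns `weight`, `log_p` (natural-log p),
#'   `t`, `df`, `n_member`, `n_complement`, `degenerate`. A degenerate test
#'   (either vector shorter than 2, or both variances zero) has `NA` weight
#'   and `degenerate = TRUE`.
#' @examples
#' set_weight(c(5, 6, 7), c(1, 2, 3))
#' set_weight(c(1, 2, 3), c(1, 2, 3)) # t = 0, p = 0.5, weight = log(2)
#' @export
set_weight <- function(member, complement, var_equal = FALSE,
                       log_base = exp(1)) {
  member <- as.numeric(member)
  complement <- as.numeric(complement)
  n1 <- length(member)
  n2 <- length(complement)
  degenerate <- function() {
    tibble(weight = NA_real_, log_p = NA_real_, t = NA_real_, df = NA_real_,
           n_member = n1, n_complement = n2, degenerate = TRUE)
  }
  if (n1 < 2 || n2 < 2) return(degenerate())
  v1 <- var(member)
  v2 <- var(complement)
  if (v1 == 0 && v2 == 0) return(degenerate())
  delta <- mean(member) - mean(complement)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- delta / se
  log_p <- pt(t, df, lower.tail = FALSE, log.p = TRUE)
  tibble(weight = -log_p / log(log_base), log_p = log_p, t = t, df = df,
         n_member = n1, n_complement = n2, degenerate = FALSE)
}

#' Tissue-specific gene set weights for a collection
#'
#' Applies the competitive test of [set_weight()] to every (set, tissue)
#' pair. The gene universe defaults to the collection's own universe: genes
#' in the collection but absent from the gene weight table receive weight 0
#' through the missing-data rules rather than being dropped
#' (`restrict_to_measured = TRUE` intersects instead).
#'
#' @param gw A `gene_weights` object from [gene_weights()], or a long data
#'   frame with columns `gene`, `tissue`, `weight`.
#' @param gsc A [gene_set_collection()].
#' @param min_set_size Minimum member count (after universe intersection)
#'   for a set to be testable; smaller sets get an undefined weight and a
#'   flag. Default 2, the minimum for a t-test.
#' @param tissues Optional tissue subset; default all tissues in `gw`.
#' @param var_equal,log_base Passed to [set_weight()].
#' @param restrict_to_measured Restrict the universe to genes present in
#'   `gw` instead of treating unmeasured genes as weight 0.
#' @return A tibble of class `set_weights` with columns `set`, `tissue`,
#'   `weight`, `log_p`, `t`, `df`, `n_used`, `degenerate`, plus `tissues`
#'   and `log_base` attributes.
#' @export
collection_weights <- function(gw, gsc, min_set_size = 2, tissues = NULL,
                               var_equal = FALSE, log_base = exp(1),
                               restrict_to_measured = FALSE) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  gw <- as_tibble(gw)
  if (!all(c("gene", "tissue", "weight") %in% names(gw))) {
    abort("gene weights must have columns gene, tissue, weight")
  }
  universe <- gs_universe(gsc)
  measured <- unique(gw$gene)
  if (length(intersect(universe, measured)) == 0) {
    abort("no overlap between the collection universe and the measured genes")
  }
  if (restrict_to_measured) universe <- intersect(universe, measured)
  tissues <- tissues %||% unique(gw$tissue)
  missing_t <- setdiff(tissues, unique(gw$tissue))
  if (length(missing_t) > 0) {
    abort(paste0("tissue(s) absent from the gene weights: ",
                 paste(missing_t, collapse = ", ")))
  }
  # universe x tissue weight matrix; unmeasured cells -> 0 (missing-data rule)
  wm <- matrix(0, nrow = length(universe), ncol = length(tissues),
               dimnames = list(universe, tissues))
  gw_sub <- gw[gw$gene %in% universe & gw$tissue %in% tissues, ]
  wm[cbind(gw_sub$gene, gw_sub$tissue)] <- gw_sub$weight

  member_idx <- lapply(gsc$genes, function(g) which(universe %in% g))
  res <- purrr::map_dfr(seq_len(nrow(gsc)), function(j) {
    idx <- member_idx[[j]]
    n_used <- length(idx)
    purrr::map_dfr(tissues, function(t) {
      if (n_used < min_set_size || n_used > length(universe) - 2) {
        row <- tibble(weight = NA_real_, log_p = NA_real_, t = NA_real_,
                      df = NA_real_, n_member = n_used,
                      n_complement = length(universe) - n_used,
                      degenerate = TRUE)
      } else {
        w <- wm[, t]
        row <- set_weight(w[idx], w[-idx], var_equal = var_equal,
                          log_base = log_base)
      }
      tibble(set = gsc$set[j], tissue = t, weight = row$weight,
             log_p = row$log_p, t = row$t, df = row$df, n_used = n_used,
             degenerate = row$degenerate)
    })
  })
  structure(
    res,
    tissues = as.character(tissues),
    log_base = log_base,
    class = c("set_weights", class(tibble()))
  )
}

#' Multi-tissue gene set weights
#'
#' Aggregates per-tissue set weights over a group of tissues. The default
#' aggregator is the minimum, which highly ranks sets with at least a basic
#' level of activity in *all* analyzed tissues (the choice found most
#' effective for systemic-disease profiling); mean and median are available
#' as alternatives. Sets with an undefined weight in any requested tissue
#' are excluded and reported.
#'
#' @param sw A `set_weights` object from [collection_weights()].
#' @param tissues Tissues to aggregate over; each must be present in `sw`.
#' @param aggregate One of `"min"` (default), `"mean"`, `"median"`.
#' @return A tibble of class `multi_tissue_weights` with columns `set`,
#'   `weight`, `n_tissues`; excluded set names are in the `excluded`
#'   attribute.
#' @export
multi_tissue_weight <- function(sw, tissues = NULL,
                                aggregate = c("min", "mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg_fun <- switch(aggregate, min = min, mean = mean, median = stats::median)
  sw <- as_tibble(sw)
  tissues <- tissues %||% unique(sw$tissue)
  absent <- setdiff(tissues, unique(sw$tissue))
  if (length(absent) > 0) {
    abort(paste0("tissue(s) absent from the set weights: ",
                 paste(absent, collapse = ", ")))
  }
  sub <- sw[sw$tissue %in% tissues, ]
  by_set <- sub |>
    group_by(.data$set) |>
    summarise(
      n_tissues = n(),
      n_defined = sum(!is.na(.data$weight)),
      weight = if (all(!is.na(.data$weight))) agg_fun(.data$weight) else NA_real_,
      .groups = "drop"
    )
  excluded <- by_set$set[by_set$n_defined < by_set$n_tissues]
  if (length(excluded) > 0) {
    inform(paste0(length(excluded),
                  " set(s) excluded from the multi-tissue weight ",
                  "(undefined in at least one requested tissue)"))
  }
  out <- by_set |>
    filter(!is.na(.data$weight)) |>
    select("set", "weight", "n_tissues")
  structure(
    out,
    tissues = as.character(tissues),
    aggregate = aggregate,
    excluded = excluded,
    class = c("multi_tissue_weights", class(tibble()))
  )
}
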