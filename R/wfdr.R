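#' Standardize hypothesis weights to mean 1
#'
#' Divides each weight by the mean weight over the collection, so the
#' average standardized weight is exactly 1 -- the first of the two
#' conditions (mean-1 weights, independence from the p-values under the
#' null) under which Benjamini-Hochberg applied to weighted p-values keeps
#' valid FDR control.
#'
#' @param w Non-negative numeric weight vector with at least one positive
#'   entry.
#' @return Numeric vector of standardized weights, mean 1.
#' @export
standardize_weights <- function(w) {
  w <- as.numeric(w)
  if (length(w) == 0) abort("cannot standardize an empty weight vector")
  if (anyNA(w)) abort("weights must not contain NA")
  if (any(w < 0)) abort("weights must be non-negative")
  if (all(w == 0)) abort("all weights are zero; standardization undefined")
  w / mean(w)
}

#' Weighted p-values
#'
#' Divides each raw p-value by its standardized weight, capping at 1 so the
#' result stays a valid p-value for step-up FDR procedures. A zero
#' standardized weight yields a weighted p-value of 1: a set with zero
#' prior weight can never be a discovery.
#'
#' @param p Numeric p-values in (0, 1].
#' @param w_star Standardized weights (non-negative, mean 1) of the same
#'   length.
#' @return Numeric vector of weighted p-values in (0, 1].
#' @export
weighted_pvalues <- function(p, w_star) {
  p <- as.numeric(p)
  w_star <- as.numeric(w_star)
  if (length(p) != length(w_star)) {
    abort("p-values and weights must have equal length")
  }
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  if (any(w_star < 0)) abort("standardized weights must be non-negative")
  ifelse(w_star == 0, 1, pmin(1, p / w_star))
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up BH adjusted p-values (cumulative-minimum enforced,
#' capped at 1), delegated to [stats::p.adjust()].
#'
#' @param p Numeric p-values in (0, 1]; an empty vector returns an empty
#'   vector.
#' @return Numeric q-values in (0, 1], same order as `p`.
#' @export
bh_qvalues <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Weighted FDR analysis of gene set testing p-values
#'
#' Chains weight standardization, p-value weighting, and BH across a table
#' of gene set testing p-values (from any external method), reporting the
#' weighted q-values alongside the plain unweighted BH q-values for a
#' side-by-side comparison of discoveries.
#'
#' @param pvals Data frame with columns `set` and `p` (extra columns are
#'   tolerated and ignored), one row per tested gene set.
#' @param weights Either a two-column data frame (`set`, `weight`) of raw
#'   tissue weights, or a `set_weights` object (then `tissue` selects the
#'   column).
#' @param tissue Tissue name, required when `weights` is a `set_weights`
#'   object.
#' @param unmatched What to do with sets in `pvals` that have no weight:
#'   `"error"` (default -- silent imputation would disturb the mean-1
#'   condition) or `"drop"` (drop with a warning reporting the count).
#' @param q_threshold Discovery threshold used by [glance()] and
#'   [autoplot()]; default 0.2.
#' @return A tibble of class `wfdr_result` with columns `set`, `p`,
#'   `weight`, `w_star`, `p_weighted`, `q_bh`, `q_wfdr`.
#' @examples
#' res <- wfdr_analysis(
#'   tibble::tibble(set = c("A", "B", "C"), p = c(0.004, 0.2, 0.9)),
#'   tibble::tibble(set = c("A", "B", "C"), weight = c(10, 1, 1))
#' )
#' glance(res)
#' @export
wfdr_analysis <- function(pvals, weights, tissue = NULL,
                          unmatched = c("error", "drop"), q_threshold = 0.2) {
  unmatched <- match.arg(unmatched)
  pvals <- as_tibble(pvals)
  if (!all(c("set", "p") %in% names(pvals))) {
    abort("pvals must have columns set and p")
  }
  if (anyDuplicated(pvals$set)) abort("duplicate set names in the p-value table")
  if (inherits(weights, "set_weights")) {
    if (is.null(tissue)) {
      abort("supply `tissue` to pick a column from a set_weights object")
    }
    weights <- as_tibble(weights) |>
      filter(.data$tissue == !!tissue, !is.na(.data$weight)) |>
      select("set", "weight")
  }
  weights <- as_tibble(weights)
  if (!all(c("set", "weight") %in% names(weights))) {
    abort("weights must have columns set and weight")
  }
  merged <- left_join(pvals[c("set", "p")], distinct(weights[c("set", "weight")]),
                      by = "set")
  n_unmatched <- sum(is.na(merged$weight))
  if (n_unmatched > 0) {
    if (unmatched == "error") {
      abort(paste0(
        n_unmatched, " set(s) in the p-value table have no weight ",
        "(e.g. ", merged$set[which(is.na(merged$weight))[1]],
        "); use unmatched = \"drop\" to discard them"
      ))
    }
    warn(paste0("dropping ", n_unmatched, " set(s) with no weight"))
    merged <- merged[!is.na(merged$weight), ]
  }
  if (nrow(merged) == 0) {
    abort("no sets shared between the p-value table and the weights")
  }
  out <- merged |>
    mutate(
      w_star = standardize_weights(.data$weight),
      p_weighted = weighted_pvalues(.data$p, .data$w_star),
      q_bh = bh_qvalues(.data$p),
      q_wfdr = bh_qvalues(.data$p_weighted)
    )
  structure(
    out,
    q_threshold = q_threshold,
    class = c("wfdr_result", class(tibble()))
  )
}

#' @rdname wfdr_analysis
#' @param x A `wfdr_result`.
#' @param ... Unused.
#' @method tidy wfdr_result
#' @export
tidy.wfdr_result <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @rdname wfdr_analysis
#' @method glance wfdr_result
#' @export
glance.wfdr_result <- function(x, ...) {
  q <- attr(x, "q_threshold")
  tibble(
    n_sets = nrow(x),
    q_threshold = q,
    weighted_discoveries = sum(x$q_wfdr <= q),
    unweighted_discoveries = sum(x$q_bh <= q)
  )
}

unclass_result <- function(x) {
  class(x) <- class(tibble())
  x
}

#' Write a weighted FDR result table
#'
#' @param x A `wfdr_result`.
#' @param path Output path for the tab-separated table.
#' @return `path`, invisibly.
#' @export
write_wfdr_table <- function(x, path) {
  readr::write_tsv(as_tibble(unclass_result(x)), path, progress = FALSE)
  invisible(path)
}

#' Read a table of gene set testing p-values
#'
#' Tab-separated with a header; needs columns for the set name and the
#' p-value, extra columns are tolerated.
#'
#' @param path Path to the file.
#' @param set_col,p_col Column names in the file.
#' @return Tibble with columns `set`, `p`.
#' @export
read_pvalue_table <- function(path, set_col = "set", p_col = "p") {
  df <- read_tsv_checked(path, c(set_col, p_col))
  tibble(set = as.character(df[[set_col]]), p = as.numeric(df[[p_col]]))
}
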