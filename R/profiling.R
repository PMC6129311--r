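#' Rank gene sets by their weight in one tissue
#'
#' Orders the sets of a collection by their tissue-specific weight for a
#' single tissue; the top of the ranking is expected to capture the primary
#' biological processes active in that tissue. Undefined weights are
#' excluded; ties are broken lexicographically by set name so the report is
#' fully reproducible.
#'
#' @param sw A `set_weights` object from [collection_weights()].
#' @param tissue Tissue name, must be present in `sw`.
#' @param k Number of top sets to keep (default 10); fewer are returned if
#'   fewer sets have defined weights, without padding.
#' @return A tibble of class `ranked_report` with columns `rank`, `set`,
#'   `weight` and a `tissue` attribute.
#' @export
rank_sets_for_tissue <- function(sw, tissue, k = 10) {
  stopifnot(k >= 1)
  sw <- as_tibble(sw)
  if (!tissue %in% unique(sw$tissue)) {
    abort(paste0("tissue not present in the set weights: ", tissue))
  }
  out <- sw |>
    filter(.data$tissue == !!tissue, !is.na(.data$weight)) |>
    arrange(desc(.data$weight), .data$set) |>
    head(k) |>
    mutate(rank = dplyr::row_number()) |>
    select("rank", "set", "weight")
  structure(
    out,
    tissue = tissue,
    class = c("ranked_report", class(tibble()))
  )
}

#' Rank gene sets by a multi-tissue aggregate weight
#'
#' Aggregates per-tissue weights over a tissue group (minimum by default,
#' see [multi_tissue_weight()]) and ranks the sets by the aggregate,
#' reporting the per-tissue component weights alongside for auditability.
#' With a single tissue the ranking is identical to
#' [rank_sets_for_tissue()].
#'
#' @param sw A `set_weights` object.
#' @param tissues Tissues to aggregate over.
#' @param k Number of top sets to keep (default 10).
#' @param aggregate Aggregator passed to [multi_tissue_weight()].
#' @return A tibble of class `ranked_report` with columns `rank`, `set`,
#'   `weight` (the aggregate), then one column per tissue with the
#'   component weights.
#' @export
multi_tissue_report <- function(sw, tissues, k = 10,
                                aggregate = c("min", "mean", "median")) {
  stopifnot(k >= 1)
  aggregate <- match.arg(aggregate)
  mt <- multi_tissue_weight(sw, tissues = tissues, aggregate = aggregate)
  components <- as_tibble(sw) |>
    filter(.data$tissue %in% tissues) |>
    select("set", "tissue", "weight") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "weight")
  out <- as_tibble(mt) |>
    select("set", "weight") |>
    arrange(desc(.data$weight), .data$set) |>
    head(k) |>
    mutate(rank = dplyr::row_number()) |>
    left_join(components, by = "set") |>
    select("rank", "set", "weight", dplyr::all_of(tissues))
  structure(
    out,
    tissue = paste(tissues, collapse = "+"),
    aggregate = aggregate,
    class = c("ranked_report", class(tibble()))
  )
}

#' Write a ranked report
#'
#' @param x A `ranked_report`.
#' @param path Output path for the tab-separated report.
#' @return `path`, invisibly.
#' @export
write_ranked_report <- function(x, path) {
  readr::write_tsv(as_tibble(unclass_result(x)), path, progress = FALSE)
  invisible(path)
}
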