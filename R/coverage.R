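#' Global median distance between components and comparator drugs
#'
#' The screening threshold of the similar-drug screen: the median over
#' all cross pairs (component, drug) of the fingerprint distance. Even
#' pair counts average the central two order statistics.
#'
#' @param D Distance matrix covering both id sets.
#' @param tcm_ids,wm_ids Disjoint, non-empty character vectors of
#'   component / drug ids present in `D`.
#' @return The median cross distance (scalar).
#' @export
global_median_threshold <- function(D, tcm_ids, wm_ids) {
  check_cross_ids(D, tcm_ids, wm_ids)
  median(D[tcm_ids, wm_ids, drop = FALSE])
}

check_cross_ids <- function(D, tcm_ids, wm_ids) {
  if (length(tcm_ids) == 0 || length(wm_ids) == 0) {
    stop("both id sets must be non-empty")
  }
  if (length(intersect(tcm_ids, wm_ids)) > 0) stop("id sets must be disjoint")
  missing <- setdiff(c(tcm_ids, wm_ids), rownames(D))
  if (length(missing) > 0) stop("ids absent from distance matrix: ",
                                paste(head(missing, 5), collapse = ", "))
  invisible(TRUE)
}

#' Screen comparator drugs similar to the preparation's components
#'
#' A drug counts as a "similar drug" when its distance to at least one
#' component is strictly below the threshold (a drug sitting exactly at
#' the threshold is excluded). The screen is evaluated once globally and
#' then intersected with each indication's drug set, so a drug similar
#' for one indication is similar wherever it appears.
#'
#' @param D Distance matrix.
#' @param tcm_ids Component ids.
#' @param indications Tibble with columns `indication_id`, `wm_id`.
#' @param threshold Distance threshold in \[0, 1\], typically
#'   [global_median_threshold()].
#' @return A list of class `cfp_screen`: `threshold`,
#'   `pairs_considered`, `similar_ids` (all similar drugs),
#'   `min_distance` (named vector), `by_indication` (tibble
#'   `indication_id`, list-column `similar_wm_ids`).
#' @export
screen_similar_drugs <- function(D, tcm_ids, indications, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  stopifnot(all(c("indication_id", "wm_id") %in% names(indications)))
  wm_ids <- sort(unique(indications$wm_id))
  check_cross_ids(D, tcm_ids, wm_ids)
  cross <- D[tcm_ids, wm_ids, drop = FALSE]
  min_d <- apply(cross, 2, min)
  similar <- names(min_d)[min_d < threshold]
  by_ind <- indications |>
    dplyr::distinct(.data$indication_id, .data$wm_id) |>
    dplyr::group_by(.data$indication_id) |>
    dplyr::summarise(
      similar_wm_ids = list(sort(intersect(.data$wm_id, similar))),
      .groups = "drop"
    )
  structure(
    list(
      threshold = threshold,
      pairs_considered = length(cross),
      similar_ids = sort(similar),
      min_distance = min_d,
      by_indication = by_ind
    ),
    class = "cfp_screen"
  )
}

#' @export
print.cfp_screen <- function(x, ...) {
  cat("<cfp_screen> threshold < ", format(x$threshold), ": ",
      length(x$similar_ids), " similar drug(s) from ",
      length(x$min_distance), " screened (", x$pairs_considered,
      " cross pairs)\n", sep = "")
  invisible(x)
}

coverage_pair <- function(predicted, reference, what) {
  if (length(reference) == 0) stop("reference ", what, " set is empty")
  n <- length(intersect(unique(predicted), unique(reference)))
  N <- length(unique(reference))
  list(covered = n, total = N, ratio = n / N)
}

#' ATC-code coverage of an indication
#'
#' n/N where N is the number of distinct ATC codes (truncated to
#' `level`) carried by the indication's drugs and n the number of those
#' codes also predicted for the preparation's components.
#'
#' @param predicted_atc Predicted ATC codes for the components.
#' @param indication_atc ATC codes of the indication's drugs (non-empty).
#' @param level ATC truncation level 1-5 applied to both sets before
#'   comparison (default 3, the pharmacological subgroup).
#' @return Tibble with columns `n`, `N`, `atc_coverage`.
#' @export
atc_coverage <- function(predicted_atc, indication_atc, level = 3) {
  cp <- coverage_pair(atc_truncate(predicted_atc, level),
                      atc_truncate(indication_atc, level), "ATC")
  tibble::tibble(n = cp$covered, N = cp$total, atc_coverage = cp$ratio)
}

#' GO-term coverage of an indication
#'
#' m/M where M is the number of distinct function terms reachable from
#' the indication's drugs and m the number of those also predicted for
#' the components.
#'
#' @param predicted_terms Predicted term ids for the components.
#' @param indication_terms Term ids of the indication's drugs (non-empty).
#' @return Tibble with columns `m`, `M`, `go_term_coverage`.
#' @export
go_term_coverage <- function(predicted_terms, indication_terms) {
  cp <- coverage_pair(predicted_terms, indication_terms, "GO term")
  tibble::tibble(m = cp$covered, M = cp$total, go_term_coverage = cp$ratio)
}

#' Drug coverage of an indication
#'
#' d/D: of the D drugs marketed for the indication, the fraction d that
#' screened as similar to the preparation's components.
#'
#' @param similar_for_indication Similar-drug ids for the indication
#'   (must be a subset of `all_for_indication`).
#' @param all_for_indication All drug ids for the indication (non-empty).
#' @return Tibble with columns `d`, `D`, `drug_coverage`.
#' @export
drug_coverage <- function(similar_for_indication, all_for_indication) {
  if (length(all_for_indication) == 0) stop("indication drug set is empty")
  similar <- unique(similar_for_indication)
  all_ids <- unique(all_for_indication)
  if (!all(similar %in% all_ids)) {
    stop("similar drugs must be a subset of the indication's drugs")
  }
  tibble::tibble(d = length(similar), D = length(all_ids),
                 drug_coverage = length(similar) / length(all_ids))
}

#' Cluster-group coverage of an indication
#'
#' g/G: the indication's drugs occupy G distinct cluster groups; g of
#' those groups contain at least one similar drug.
#'
#' @param assignment Tibble (`compound_id`, `group`) covering every drug
#'   of the indication.
#' @param indication_wm_ids All drug ids for the indication.
#' @param similar_set Similar-drug ids.
#' @return Tibble with columns `g`, `G`, `group_coverage`.
#' @export
group_coverage <- function(assignment, indication_wm_ids, similar_set) {
  indication_wm_ids <- unique(indication_wm_ids)
  missing <- setdiff(indication_wm_ids, assignment$compound_id)
  if (length(missing) > 0) {
    stop("unlabeled drug(s): ", paste(head(missing, 5), collapse = ", "))
  }
  grp <- setNames(assignment$group, assignment$compound_id)
  all_groups <- unique(grp[indication_wm_ids])
  sim_groups <- unique(grp[intersect(indication_wm_ids, similar_set)])
  tibble::tibble(g = length(sim_groups), G = length(all_groups),
                 group_coverage = length(sim_groups) / length(all_groups))
}

#' Combined coverage ratio
#'
#' The arithmetic mean of ATC-code coverage, GO-term coverage and drug
#' coverage — the auxiliary index summarizing the three evidence
#' sources.
#'
#' @param atc,go,drug Coverage ratios, each in \[0, 1\].
#' @return Scalar in \[0, 1\].
#' @export
combined_ratio <- function(atc, go, drug) {
  vals <- c(atc, go, drug)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("coverage ratios must lie in [0, 1]")
  }
  (atc + go + drug) / 3
}

#' Per-indication coverage report
#'
#' Assembles the four coverage statistics and the combined ratio for
#' every indication. Both the GO-term ratio m/M and the cluster-group
#' ratio g/G are reported side by side and clearly labeled; the combined
#' ratio uses m/M.
#'
#' @param net A `hetnet` (supplies drug ATC codes and term reach).
#' @param indications Tibble (`indication_id`, `wm_id`).
#' @param screen A `cfp_screen` from [screen_similar_drugs()].
#' @param assignment Tibble (`compound_id`, `group`) from [cut_tree()]
#'   covering the drugs.
#' @param predicted_atc Predicted ATC codes for the components (e.g.
#'   from [transfer_atc()], unioned).
#' @param predicted_terms Predicted term ids for the components (e.g.
#'   from [transfer_go_terms()], unioned).
#' @param atc_level ATC truncation level (default 3).
#' @return Tibble, one row per indication, with columns `indication_id`,
#'   `n`, `N`, `m`, `M`, `d`, `D`, `g`, `G`, the four ratios, and
#'   `combined_ratio`.
#' @export
coverage_report <- function(net, indications, screen, assignment,
                            predicted_atc, predicted_terms, atc_level = 3) {
  stopifnot(inherits(net, "hetnet"), inherits(screen, "cfp_screen"))
  wm_atc <- setNames(net$compounds$atc_codes, net$compounds$id)
  support <- fingerprint_support(net)
  sim_by_ind <- setNames(screen$by_indication$similar_wm_ids,
                         screen$by_indication$indication_id)
  indications |>
    dplyr::distinct(.data$indication_id, .data$wm_id) |>
    dplyr::group_by(.data$indication_id) |>
    dplyr::group_modify(function(rows, key) {
      wm <- rows$wm_id
      similar <- sim_by_ind[[key$indication_id]] %||% character(0)
      ind_atc <- unique(unlist(wm_atc[wm]))
      atc <- atc_coverage(predicted_atc, ind_atc, level = atc_level)
      ind_terms <- unique(unlist(support[wm]))
      go <- go_term_coverage(predicted_terms, ind_terms)
      dr <- drug_coverage(similar, wm)
      gr <- group_coverage(assignment, wm, similar)
      dplyr::bind_cols(atc, go, dr, gr) |>
        dplyr::mutate(combined_ratio = combined_ratio(
          .data$atc_coverage, .data$go_term_coverage, .data$drug_coverage))
    }) |>
    dplyr::ungroup() |>
    dplyr::select("indication_id", "n", "N", "m", "M", "d", "D", "g", "G",
                  "atc_coverage", "go_term_coverage", "drug_coverage",
                  "group_coverage", "combined_ratio")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
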