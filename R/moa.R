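#' Term reach (fingerprint support) per compound
#'
#' The set of function terms reachable from a compound through at least
#' one of its targets.
#'
#' @param net A `hetnet`.
#' @param sources Optional annotation-source filter (e.g. `"GO_BP"`).
#' @return Named list: compound id -> sorted character vector of term ids.
#' @export
fingerprint_support <- function(net, sources = NULL) {
  M <- path_count_matrix(net, mode = "binary", sources = sources)
  lapply(setNames(rownames(M), rownames(M)), function(cid) {
    colnames(M)[M[cid, ] > 0]
  })
}

#' Most similar comparator drug per component
#'
#' For each component, the comparator (western) drug with the maximal
#' fingerprint similarity, subject to a minimum-similarity floor;
#' components whose best match falls below the floor are omitted. Ties
#' resolve to the lexicographically smallest drug id.
#'
#' @param S Similarity matrix.
#' @param tcm_ids,wm_ids Disjoint non-empty id sets present in `S`.
#' @param floor Minimum similarity to report a match (default 0.5,
#'   the cutoff used when listing top component-drug pairs).
#' @return Tibble (`compound_id`, `wm_id`, `similarity`), sorted by
#'   decreasing similarity.
#' @export
nearest_wm <- function(S, tcm_ids, wm_ids, floor = 0.5) {
  check_cross_ids(S, tcm_ids, wm_ids)
  wm_sorted <- sort(wm_ids)
  cross <- S[tcm_ids, wm_sorted, drop = FALSE]
  best <- purrr::map_dfr(tcm_ids, function(cid) {
    sims <- cross[cid, ]
    j <- which.max(sims)  # first maximum = smallest wm id after sort
    tibble::tibble(compound_id = cid, wm_id = wm_sorted[j], similarity = unname(sims[j]))
  })
  best |>
    dplyr::filter(.data$similarity >= floor) |>
    dplyr::arrange(dplyr::desc(.data$similarity), .data$compound_id)
}

#' Transfer ATC codes from most-similar drugs
#'
#' Each component inherits the ATC code set of its most similar drug,
#' truncated to the configured level. The union over components is the
#' predicted ATC set used by [atc_coverage()].
#'
#' @param nmap Tibble from [nearest_wm()].
#' @param wm_atc Named list: drug id -> character vector of ATC codes.
#' @param level ATC truncation level (default 3).
#' @return Tibble (`compound_id`, `wm_id`, list-column `atc_codes`);
#'   attribute `predicted_union` holds the unioned code set.
#' @export
transfer_atc <- function(nmap, wm_atc, level = 3) {
  out <- nmap |>
    dplyr::mutate(atc_codes = purrr::map(.data$wm_id, function(w) {
      codes <- wm_atc[[w]] %||% character(0)
      if (length(codes) == 0) {
        warning("nearest drug ", w, " carries no ATC codes")
        return(character(0))
      }
      sort(unique(atc_truncate(codes, level)))
    }))
  attr(out, "predicted_union") <- sort(unique(unlist(out$atc_codes)))
  out
}

#' Terms shared between a component and a drug
#'
#' The function terms reachable (via any target) from both the component
#' and the drug — the intersection of their fingerprint supports, i.e.
#' the terms joined to both ends of a compound-target-term-target-
#' compound meta-path. Symmetric in its two arguments.
#'
#' @param compound_id,wm_id Compound ids present in the network.
#' @param net A `hetnet`.
#' @param sources Optional annotation-source filter.
#' @return Sorted character vector of shared term ids.
#' @export
transfer_go_terms <- function(compound_id, wm_id, net, sources = NULL) {
  support <- fingerprint_support(net, sources = sources)
  for (id in c(compound_id, wm_id)) {
    if (!id %in% names(support)) stop("unknown compound id: ", id)
  }
  sort(intersect(support[[compound_id]], support[[wm_id]]))
}

#' Common biological processes of similar drugs and components
#'
#' Terms (by default GO biological processes) reachable from at least
#' one similar drug AND at least one component: the processes both ends
#' of the comparison can intervene in.
#'
#' @param similar_wm_ids,tcm_ids Non-empty id sets.
#' @param net A `hetnet`.
#' @param sources Annotation sources to consider (default `"GO_BP"`).
#' @return Sorted character vector of term ids.
#' @export
common_processes <- function(similar_wm_ids, tcm_ids, net, sources = "GO_BP") {
  if (length(similar_wm_ids) == 0 || length(tcm_ids) == 0) {
    stop("both id sets must be non-empty")
  }
  support <- fingerprint_support(net, sources = sources)
  wm_reach <- unique(unlist(support[intersect(similar_wm_ids, names(support))]))
  tcm_reach <- unique(unlist(support[intersect(tcm_ids, names(support))]))
  sort(intersect(wm_reach, tcm_reach))
}

#' Read drug expression signatures
#'
#' @param path TSV with columns drug_id, gene, z (LINCS-style gene-level
#'   z-scores).
#' @return Tibble (`drug_id`, `gene`, `z`).
#' @export
read_signatures <- function(path) {
  sig <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    drug_id = readr::col_character(), gene = readr::col_character(),
    z = readr::col_double()
  ), progress = FALSE)
  if (any(!is.finite(sig$z))) stop("non-finite z-scores in signature file")
  sig
}

#' Regulation score of a drug on a term
#'
#' Mean signature z-score over the term's genes present in the
#' signature. Below `min_overlap` shared genes the score is a no-call
#' (`NA`), which is distinct from a flat call.
#'
#' @param sig Named numeric vector (gene -> z) or a two-column tibble
#'   (`gene`, `z`) for one drug.
#' @param term_genes Character vector of the term's genes.
#' @param min_overlap Minimum genes in common to score (default 3).
#' @return Scalar score, or `NA_real_` (no-call) with attribute
#'   `n_overlap` in both cases.
#' @export
regulation_score <- function(sig, term_genes, min_overlap = 3) {
  if (is.data.frame(sig)) sig <- setNames(sig$z, sig$gene)
  shared <- intersect(names(sig), unique(term_genes))
  score <- if (length(shared) < min_overlap) NA_real_ else mean(sig[shared])
  structure(score, n_overlap = length(shared))
}

#' Direction call from a regulation score
#'
#' `"up"` if score > tau, `"down"` if score < -tau, `"flat"` otherwise;
#' `NA` scores (no-calls) propagate as `"no_call"`.
#'
#' @param score Numeric score(s).
#' @param tau Positive call threshold on the mean z (default 0.5).
#' @return Character vector in `{"up", "down", "flat", "no_call"}`.
#' @export
regulation_call <- function(score, tau = 0.5) {
  stopifnot(is.numeric(tau), tau > 0)
  dplyr::case_when(
    is.na(score) ~ "no_call",
    score > tau ~ "up",
    score < -tau ~ "down",
    .default = "flat"
  )
}

#' Overall direction of a drug group on a term
#'
#' The mean of the member drugs' regulation scores, thresholded at the
#' same tau: the group is called up (down) when the mean clears +tau
#' (-tau), flat otherwise. No-call members are excluded from the mean.
#'
#' @param scores Numeric vector of member scores (>= 1 non-NA).
#' @param tau Call threshold (default 0.5).
#' @return One of `"up"`, `"down"`, `"flat"`.
#' @export
group_direction <- function(scores, tau = 0.5) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) stop("no scorable members in group")
  regulation_call(mean(scores), tau = tau)
}

#' Per-drug and per-group direction report over common processes
#'
#' Scores every (drug, term) pair from the signatures, calls directions,
#' and summarizes each cluster group's overall direction per term.
#'
#' @param signatures Tibble (`drug_id`, `gene`, `z`).
#' @param terms Character vector of term ids to score.
#' @param net A `hetnet` (supplies term gene sets via its annotations).
#' @param groups Tibble (`compound_id`, `group`) assigning drugs to
#'   cluster groups.
#' @param tau Call threshold (default 0.5).
#' @param min_overlap Minimum gene overlap to score (default 3).
#' @return List with tibbles `drug_calls` (`drug_id`, `term_id`,
#'   `n_overlap`, `score`, `direction`) and `group_calls` (`group`,
#'   `term_id`, `n_drugs`, `mean_score`, `direction`).
#' @export
direction_report <- function(signatures, terms, net, groups, tau = 0.5, min_overlap = 3) {
  term_genes <- net$tp_edges |>
    dplyr::filter(.data$term_id %in% terms) |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(genes = list(.data$target_id), .groups = "drop")
  gene_sets <- setNames(term_genes$genes, term_genes$term_id)
  sig_split <- split(signatures, signatures$drug_id)
  drug_calls <- purrr::map_dfr(names(sig_split), function(d) {
    sig <- setNames(sig_split[[d]]$z, sig_split[[d]]$gene)
    purrr::map_dfr(terms, function(t) {
      s <- regulation_score(sig, gene_sets[[t]] %||% character(0), min_overlap)
      tibble::tibble(drug_id = d, term_id = t,
                     n_overlap = attr(s, "n_overlap"), score = as.numeric(s))
    })
  }) |>
    dplyr::mutate(direction = regulation_call(.data$score, tau = tau))
  group_calls <- drug_calls |>
    dplyr::inner_join(groups, by = c(drug_id = "compound_id")) |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::group_by(.data$group, .data$term_id) |>
    dplyr::summarise(
      n_drugs = dplyr::n(),
      mean_score = mean(.data$score),
      .groups = "drop"
    ) |>
    dplyr::mutate(direction = regulation_call(.data$mean_score, tau = tau))
  list(drug_calls = drug_calls, group_calls = group_calls)
}
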