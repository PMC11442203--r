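#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Knobs that published
#' analyses leave ambiguous (target-score cutoff 10 vs 20, linkage,
#' fingerprint mode, ATC level, call threshold) all surface here so a
#' variant analysis is a configuration choice, not a code edit.
#'
#' @param score_threshold Strict confidence cutoff on compound-target
#'   edges (default 20).
#' @param fingerprint_mode `"count"` or `"binary"` fingerprints.
#' @param linkage Clustering linkage (default `"complete"`).
#' @param k_main Groups to cut the full compound tree into.
#' @param k_filter Groups for the drug-library consistency filter
#'   (`NULL` skips the filter).
#' @param min_cosize Minimum group size surviving the filter.
#' @param atc_level ATC truncation level 1-5 (default 3).
#' @param threshold_mode `"global_median"` or `"fixed"`.
#' @param fixed_threshold Distance threshold when `threshold_mode =
#'   "fixed"`.
#' @param similarity_floor Minimum similarity for a nearest-drug match.
#' @param tau Direction-call threshold on mean z (default 0.5).
#' @param min_overlap Minimum signature/term gene overlap (default 3).
#' @param sources Annotation sources for common processes (default
#'   `"GO_BP"`).
#' @param seed Integer seed recorded in the manifest.
#' @return List of class `cfp_run_config`.
#' @export
pipeline_config <- function(score_threshold = 20, fingerprint_mode = "count",
                            linkage = "complete", k_main = 16, k_filter = NULL,
                            min_cosize = 2, atc_level = 3,
                            threshold_mode = c("global_median", "fixed"),
                            fixed_threshold = NULL, similarity_floor = 0.5,
                            tau = 0.5, min_overlap = 3, sources = "GO_BP",
                            seed = 1) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed" &&
      (is.null(fixed_threshold) || fixed_threshold < 0 || fixed_threshold > 1)) {
    stop("fixed threshold mode needs fixed_threshold in [0, 1]")
  }
  stopifnot(atc_level %in% 1:5, tau > 0, min_overlap >= 1,
            score_threshold >= 0, similarity_floor >= 0, similarity_floor <= 1)
  structure(
    list(score_threshold = score_threshold, fingerprint_mode = fingerprint_mode,
         linkage = linkage, k_main = k_main, k_filter = k_filter,
         min_cosize = min_cosize, atc_level = atc_level,
         threshold_mode = threshold_mode, fixed_threshold = fixed_threshold,
         similarity_floor = similarity_floor, tau = tau,
         min_overlap = min_overlap, sources = sources, seed = as.integer(seed)),
    class = "cfp_run_config"
  )
}

#' Run the full similarity-to-coverage pipeline
#'
#' Orchestrates: fingerprint similarity on the network, optional
#' drug-library consistency filter, hierarchical clustering and cut,
#' median (or fixed) distance screen, per-indication coverage report,
#' ATC/GO mechanism transfer from most-similar drugs, and (when
#' signatures are supplied) direction calls on the common biological
#' processes. Every stage is a pure function of (inputs, config), so
#' identical inputs give identical outputs; when `out_dir` is given the
#' stage outputs and a manifest are also written to disk.
#'
#' @param net A `hetnet`.
#' @param indications Tibble (`indication_id`, `wm_id`).
#' @param cfg A `cfp_run_config`.
#' @param signatures Optional tibble (`drug_id`, `gene`, `z`).
#' @param out_dir Optional output directory.
#' @return List of class `cfp_run`: `similarity`, `distance`,
#'   `dendrogram`, `assignment`, `retained_wm`, `threshold`, `screen`,
#'   `nearest`, `transfer`, `predicted_atc`, `predicted_terms`,
#'   `coverage`, `common_terms`, `direction` (or `NULL`), `config`.
#' @export
run_pipeline <- function(net, indications, cfg = pipeline_config(),
                         signatures = NULL, out_dir = NULL) {
  stopifnot(inherits(net, "hetnet"), inherits(cfg, "cfp_run_config"))
  validate_network(net)
  tcm_ids <- compound_ids(net, "tcm_component")
  wm_ids <- compound_ids(net, "western_drug")
  if (length(tcm_ids) == 0 || length(wm_ids) == 0) {
    stop("stage similarity: network must contain both compound roles")
  }
  message("similarity: ", length(tcm_ids), " components vs ", length(wm_ids), " drugs")

  M <- path_count_matrix(net, mode = cfg$fingerprint_mode)
  S <- pathsim(M)
  D <- to_distance(S)

  retained_wm <- wm_ids
  if (!is.null(cfg$k_filter)) {
    retained_wm <- consistency_filter(D[wm_ids, wm_ids, drop = FALSE],
                                      k = cfg$k_filter,
                                      min_cosize = cfg$min_cosize,
                                      linkage = cfg$linkage)
    indications <- dplyr::filter(indications, .data$wm_id %in% retained_wm)
    if (nrow(indications) == 0) stop("stage filter: no indication drugs survive")
  }
  keep <- c(tcm_ids, retained_wm)
  Dk <- D[keep, keep, drop = FALSE]

  dend <- hcluster(Dk, linkage = cfg$linkage)
  assignment <- cut_tree(dend, k = cfg$k_main)

  threshold <- if (cfg$threshold_mode == "fixed") cfg$fixed_threshold else
    global_median_threshold(Dk, tcm_ids, retained_wm)
  message("screen: threshold ", format(round(threshold, 4)))
  screen <- screen_similar_drugs(Dk, tcm_ids, indications, threshold)
  message("screen: ", length(screen$similar_ids), " of ",
          length(screen$min_distance), " drugs similar")

  nmap <- nearest_wm(S[keep, keep, drop = FALSE], tcm_ids, retained_wm,
                     floor = cfg$similarity_floor)
  wm_atc <- setNames(net$compounds$atc_codes, net$compounds$id)
  transfer <- transfer_atc(nmap, wm_atc, level = cfg$atc_level)
  predicted_atc <- attr(transfer, "predicted_union")
  predicted_terms <- sort(unique(unlist(
    purrr::map2(nmap$compound_id, nmap$wm_id, transfer_go_terms, net = net)
  )))
  coverage <- coverage_report(net, indications, screen, assignment,
                              predicted_atc, predicted_terms,
                              atc_level = cfg$atc_level)

  common_terms <- if (length(screen$similar_ids) > 0) {
    common_processes(screen$similar_ids, tcm_ids, net, sources = cfg$sources)
  } else character(0)
  direction <- NULL
  if (!is.null(signatures) && length(common_terms) > 0) {
    direction <- direction_report(signatures, common_terms, net, assignment,
                                  tau = cfg$tau, min_overlap = cfg$min_overlap)
  }

  run <- structure(
    list(similarity = S, distance = D, dendrogram = dend,
         assignment = assignment, retained_wm = retained_wm,
         threshold = threshold, screen = screen, nearest = nmap,
         transfer = transfer, predicted_atc = predicted_atc,
         predicted_terms = predicted_terms, coverage = coverage,
         common_terms = common_terms, direction = direction, config = cfg),
    class = "cfp_run"
  )
  if (!is.null(out_dir)) write_run(run, net, out_dir)
  run
}

write_run <- function(run, net, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_matrix_csv(run$similarity, file.path(out_dir, "similarity.csv"))
  write_matrix_csv(run$distance, file.path(out_dir, "distance.csv"))
  readr::write_tsv(matrix_to_long(run$similarity, "similarity", upper_only = TRUE),
                   file.path(out_dir, "similarity_long.tsv"))
  write_newick(run$dendrogram, file.path(out_dir, "dendrogram.nwk"))
  readr::write_tsv(run$assignment, file.path(out_dir, "assignment.tsv"))
  readr::write_tsv(run$coverage, file.path(out_dir, "coverage.tsv"))
  jsonlite::write_json(run$coverage, file.path(out_dir, "coverage.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  readr::write_tsv(
    dplyr::mutate(run$transfer,
                  atc_codes = purrr::map_chr(.data$atc_codes, paste, collapse = ";")),
    file.path(out_dir, "moa_transfer.tsv")
  )
  if (!is.null(run$direction)) {
    readr::write_tsv(run$direction$group_calls, file.path(out_dir, "direction.tsv"))
  }
  manifest <- list(
    package = "cellfp",
    package_version = as.character(utils::packageVersion("cellfp")),
    r_version = as.character(getRversion()),
    seed = run$config$seed,
    config = unclass(run$config),
    config_hash = rlang::hash(unclass(run$config)),
    network = list(compounds = nrow(net$compounds), targets = nrow(net$targets),
                   terms = nrow(net$terms)),
    threshold = run$threshold,
    n_similar = length(run$screen$similar_ids)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.cfp_run <- function(x, ...) {
  cat("<cfp_run> fingerprint similarity pipeline\n")
  cat("  compounds clustered:", nrow(x$assignment),
      "into", max(x$assignment$group), "groups\n")
  cat("  screening threshold:", format(round(x$threshold, 4)),
      "->", length(x$screen$similar_ids), "similar drugs\n")
  cat("  indications covered:", nrow(x$coverage), "\n")
  if (!is.null(x$direction)) {
    cat("  direction calls:", nrow(x$direction$group_calls), "group-term pairs\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cfp_run <- function(x, ...) x$coverage

#' @exportS3Method generics::glance
glance.cfp_run <- function(x, ...) {
  tibble::tibble(
    n_compounds = nrow(x$assignment),
    n_groups = max(x$assignment$group),
    threshold = x$threshold,
    n_similar = length(x$screen$similar_ids),
    n_indications = nrow(x$coverage),
    mean_combined_ratio = mean(x$coverage$combined_ratio)
  )
}
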