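#' Read a scored compound-target edge table
#'
#' Reads a tab-separated table of predicted compound-target interactions
#' (the shape produced by structure-based target-prediction services such
#' as BATMAN-TCM) and applies a strict confidence-score cutoff: only rows
#' with `score > score_threshold` are kept, and duplicated
#' (compound, target) pairs collapse to their maximum score.
#'
#' @param path Path to a TSV with columns compound_id, target_id, score
#'   (extra columns are ignored). Lines starting with `#` are skipped.
#' @param score_threshold Non-negative confidence cutoff; rows must
#'   exceed it strictly. Default 20; prediction exports sometimes warrant
#'   a looser cutoff such as 10 for broader target inclusion.
#' @param header Logical; does the file carry a header row?
#' @return A tibble with columns `compound_id`, `target_id`, `score`.
#' @export
read_compound_target_table <- function(path, score_threshold = 20, header = TRUE) {
  stopifnot(is.numeric(score_threshold), score_threshold >= 0)
  raw <- readr::read_tsv(
    path,
    comment = "#",
    col_names = if (header) TRUE else c("compound_id", "target_id", "score"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(raw) < 3) {
    stop("compound-target table needs >= 3 columns, got ", ncol(raw))
  }
  raw <- raw[, 1:3]
  names(raw) <- c("compound_id", "target_id", "score")
  score_num <- suppressWarnings(as.numeric(raw$score))
  bad <- which(is.na(score_num) & !is.na(raw$score))
  if (length(bad) > 0) {
    line <- bad[1] + if (header) 1L else 0L
    stop("non-numeric score at data line ", line, ": '", raw$score[bad[1]], "'")
  }
  edges <- raw |>
    dplyr::mutate(score = score_num) |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::group_by(.data$compound_id, .data$target_id) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::filter(.data$score > score_threshold) |>
    dplyr::arrange(.data$compound_id, .data$target_id)
  if (nrow(edges) == 0) {
    warning("no compound-target edges exceed score threshold ", score_threshold)
  }
  edges
}

#' Read target-term annotations from a GMT gene-set file
#'
#' Standard GMT: one term per line, `term_id<TAB>description<TAB>gene1<TAB>...`.
#' Returns one row per (gene, term) pair, deduplicated, with the term
#' registered under the given annotation source.
#'
#' @param path Path to a GMT file.
#' @param source Annotation source, one of `"GO_BP"`, `"Reactome"`,
#'   `"KEGG"`, `"Wiki"`.
#' @return A tibble with columns `target_id`, `term_id`, `source`,
#'   `term_name`.
#' @export
read_term_annotations_gmt <- function(path, source = c("GO_BP", "Reactome", "KEGG", "Wiki")) {
  source <- match.arg(source)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields")
  }
  rows <- purrr::map_dfr(fields, function(f) {
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(trimws(genes))]
    if (length(genes) == 0) {
      warning("GMT term '", f[1], "' has no genes; skipped")
      return(tibble::tibble())
    }
    tibble::tibble(target_id = genes, term_id = f[1], term_name = f[2])
  })
  rows |>
    dplyr::mutate(source = source) |>
    dplyr::distinct(.data$target_id, .data$term_id, .keep_all = TRUE) |>
    dplyr::select("target_id", "term_id", "source", "term_name")
}

#' Read a compound metadata table
#'
#' @param path TSV with columns id, name, role, atc_codes
#'   (semicolon-separated, may be empty), indications
#'   (semicolon-separated, may be empty).
#' @return Tibble with `id`, `name`, `role` and list-columns
#'   `atc_codes`, `indication_ids`.
#' @export
read_compound_metadata <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("id", "name", "role", "atc_codes", "indications")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) stop("metadata missing columns: ", paste(missing, collapse = ", "))
  split_semi <- function(x) {
    purrr::map(x, function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else unique(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  compound_meta(
    id = raw$id, name = raw$name, role = raw$role,
    atc_codes = split_semi(raw$atc_codes),
    indication_ids = split_semi(raw$indications)
  )
}

#' Construct a compound metadata tibble
#'
#' @param id,name,role Character vectors (role is `"tcm_component"` or
#'   `"western_drug"`).
#' @param atc_codes,indication_ids Lists of character vectors (recycled
#'   from empty if omitted).
#' @return Validated tibble of compound metadata.
#' @export
compound_meta <- function(id, name = id, role, atc_codes = NULL, indication_ids = NULL) {
  n <- length(id)
  if (is.null(atc_codes)) atc_codes <- rep(list(character(0)), n)
  if (is.null(indication_ids)) indication_ids <- rep(list(character(0)), n)
  meta <- tibble::tibble(
    id = as.character(id), name = as.character(name), role = as.character(role),
    atc_codes = atc_codes, indication_ids = indication_ids
  )
  if (anyDuplicated(meta$id)) {
    stop("duplicate compound ids: ", paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  }
  bad_role <- setdiff(unique(meta$role), c("tcm_component", "western_drug"))
  if (length(bad_role) > 0) stop("unknown compound role(s): ", paste(bad_role, collapse = ", "))
  codes <- unique(unlist(meta$atc_codes))
  if (length(codes) > 0 && !all(atc_valid(codes))) {
    stop("malformed ATC code(s): ", paste(codes[!atc_valid(codes)], collapse = ", "))
  }
  meta
}

#' Build the compound-target-pathway heterogeneous network
#'
#' Assembles the tripartite network of compounds, target genes and
#' function terms. Compounds present in the metadata but with no
#' surviving compound-target edge (e.g. all predictions fell below the
#' score cutoff upstream) are dropped with a warning, mirroring the
#' screening of compounds by target score. Term annotations pointing at
#' targets absent from the edge table are dropped with a warning (or
#' rejected when `strict = TRUE`).
#'
#' @param ct_edges Tibble from [read_compound_target_table()].
#' @param tp_pairs Tibble from [read_term_annotations_gmt()] (several
#'   sources may be row-bound).
#' @param compound_meta Tibble from [compound_meta()] /
#'   [read_compound_metadata()] covering every compound in `ct_edges`.
#' @param score_threshold The cutoff already applied to `ct_edges`;
#'   recorded on the network (edges at or below it are rejected).
#' @param strict Error instead of warn on annotations of unknown targets.
#' @return An object of class `hetnet`: a list with tibbles `compounds`,
#'   `targets`, `terms`, `ct_edges`, `tp_edges` and the scalar
#'   `score_threshold`.
#' @export
build_network <- function(ct_edges, tp_pairs, compound_meta, score_threshold = 20,
                          strict = FALSE) {
  stopifnot(all(c("compound_id", "target_id", "score") %in% names(ct_edges)))
  if (any(ct_edges$score <= score_threshold)) {
    stop("ct_edges contains scores at or below the declared threshold ", score_threshold)
  }
  if (anyDuplicated(ct_edges[c("compound_id", "target_id")])) {
    stop("duplicate (compound_id, target_id) pairs in ct_edges")
  }
  unknown_compounds <- setdiff(unique(ct_edges$compound_id), compound_meta$id)
  if (length(unknown_compounds) > 0) {
    stop("edges reference compounds missing from metadata: ",
         paste(head(unknown_compounds, 5), collapse = ", "))
  }
  dropped <- setdiff(compound_meta$id, unique(ct_edges$compound_id))
  if (length(dropped) > 0) {
    warning(length(dropped), " compound(s) with no surviving target edge dropped: ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  compounds <- compound_meta |> dplyr::filter(.data$id %in% ct_edges$compound_id)
  targets <- tibble::tibble(id = sort(unique(ct_edges$target_id)))

  tp <- tp_pairs
  if (!"term_name" %in% names(tp)) tp$term_name <- tp$term_id
  orphan <- !(tp$target_id %in% targets$id)
  if (any(orphan)) {
    msg <- paste0(sum(orphan), " annotation(s) reference targets absent from the network")
    if (strict) stop(msg)
    warning(msg, "; dropped")
    tp <- tp[!orphan, ]
  }
  tp <- tp |>
    dplyr::distinct(.data$target_id, .data$term_id, .data$source, .keep_all = TRUE) |>
    dplyr::arrange(.data$target_id, .data$term_id)
  terms <- tp |>
    dplyr::distinct(.data$term_id, .data$source, .data$term_name) |>
    dplyr::rename(id = "term_id", name = "term_name") |>
    dplyr::arrange(.data$id)
  if (anyDuplicated(terms[c("id", "source")])) {
    stop("term ids duplicated within a source")
  }

  structure(
    list(
      compounds = compounds,
      targets = targets,
      terms = terms,
      ct_edges = dplyr::arrange(ct_edges, .data$compound_id, .data$target_id),
      tp_edges = dplyr::select(tp, "target_id", "term_id"),
      score_threshold = score_threshold
    ),
    class = "hetnet"
  )
}

#' @export
print.hetnet <- function(x, ...) {
  roles <- table(factor(x$compounds$role, levels = c("tcm_component", "western_drug")))
  cat("<hetnet> compound-target-pathway heterogeneous network\n")
  cat("  compounds: ", nrow(x$compounds),
      " (", roles[["tcm_component"]], " tcm_component, ",
      roles[["western_drug"]], " western_drug)\n", sep = "")
  cat("  targets:   ", nrow(x$targets), "\n", sep = "")
  cat("  terms:     ", nrow(x$terms), " (",
      paste(names(table(x$terms$source)), collapse = "/"), ")\n", sep = "")
  cat("  edges:     ", nrow(x$ct_edges), " compound-target, ",
      nrow(x$tp_edges), " target-term\n", sep = "")
  cat("  score threshold applied: >", x$score_threshold, "\n", sep = "")
  invisible(x)
}

#' Serialize / restore a heterogeneous network as JSON
#'
#' Node and edge sets are written with stable key order so identical
#' networks produce identical documents; `read_network_json()` is its
#' exact inverse.
#'
#' @param net A `hetnet`.
#' @param path Output (input) file path.
#' @return `write_network_json()` returns `path` invisibly;
#'   `read_network_json()` returns a `hetnet`.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "hetnet"))
  doc <- list(
    compounds = dplyr::mutate(
      net$compounds,
      atc_codes = purrr::map_chr(.data$atc_codes, paste, collapse = ";"),
      indication_ids = purrr::map_chr(.data$indication_ids, paste, collapse = ";")
    ),
    targets = net$targets,
    terms = net$terms,
    ct_edges = net$ct_edges,
    tp_edges = net$tp_edges,
    score_threshold = net$score_threshold
  )
  jsonlite::write_json(doc, path, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  resplit <- function(x) purrr::map(x, ~ if (nzchar(.x)) strsplit(.x, ";", fixed = TRUE)[[1]] else character(0))
  meta <- compound_meta(
    id = doc$compounds$id, name = doc$compounds$name, role = doc$compounds$role,
    atc_codes = resplit(doc$compounds$atc_codes),
    indication_ids = resplit(doc$compounds$indication_ids)
  )
  tp <- tibble::as_tibble(doc$tp_edges)
  terms <- tibble::as_tibble(doc$terms)
  tp_full <- dplyr::left_join(tp, dplyr::rename(terms, term_id = "id"), by = "term_id") |>
    dplyr::rename(term_name = "name")
  build_network(
    ct_edges = tibble::as_tibble(doc$ct_edges),
    tp_pairs = tp_full,
    compound_meta = meta,
    score_threshold = doc$score_threshold
  )
}

#' Audit the structural invariants of a heterogeneous network
#'
#' Checks referential integrity, score strictness, uniqueness and role
#' constraints; errors on the first violation.
#'
#' @param net A `hetnet`.
#' @return `TRUE` invisibly if all invariants hold.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "hetnet"))
  with(net, {
    if (anyDuplicated(compounds$id)) stop("duplicate compound ids")
    if (anyDuplicated(targets$id)) stop("duplicate target ids")
    if (anyDuplicated(terms[c("id", "source")])) stop("duplicate (term, source)")
    if (!all(ct_edges$compound_id %in% compounds$id)) stop("dangling edge compound")
    if (!all(ct_edges$target_id %in% targets$id)) stop("dangling edge target")
    if (!all(tp_edges$target_id %in% targets$id)) stop("dangling annotation target")
    if (!all(tp_edges$term_id %in% terms$id)) stop("dangling annotation term")
    if (any(ct_edges$score <= score_threshold)) stop("edge at or below score threshold")
    if (anyDuplicated(ct_edges[c("compound_id", "target_id")])) stop("duplicate ct edge")
    if (anyDuplicated(tp_edges)) stop("duplicate tp edge")
    if (!all(compounds$id %in% ct_edges$compound_id)) stop("compound with no edges retained")
  })
  invisible(TRUE)
}

#' Compound ids by role
#'
#' @param net A `hetnet`.
#' @param role `"tcm_component"` or `"western_drug"`.
#' @return Character vector of compound ids.
#' @export
compound_ids <- function(net, role = NULL) {
  ids <- net$compounds$id
  if (!is.null(role)) ids <- ids[net$compounds$role == role]
  ids
}
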