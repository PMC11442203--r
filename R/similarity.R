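#' Compound-by-term meta-path count matrix
#'
#' Counts, for every compound c and function term p, the number of
#' distinct targets t such that c-t is a scored edge and t is annotated
#' to p: the instances of the meta-path compound -> target -> term. The
#' rows are a compound's "cellular function fingerprint". `mode =
#' "binary"` reduces each count to presence/absence, reading the
#' fingerprint as a term set rather than a path profile.
#'
#' @param net A `hetnet`.
#' @param mode `"count"` (path counts, default) or `"binary"`.
#' @param sources Optional character vector restricting the annotation
#'   sources used (default: all sources pooled into one fingerprint).
#' @return Integer matrix, rownames = compound ids, colnames = term ids.
#' @export
path_count_matrix <- function(net, mode = c("count", "binary"), sources = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "hetnet"))
  terms <- net$terms
  tp <- net$tp_edges
  if (!is.null(sources)) {
    keep <- terms$id[terms$source %in% sources]
    tp <- tp[tp$term_id %in% keep, ]
    terms <- terms[terms$source %in% sources, ]
  }
  compounds <- net$compounds$id
  term_ids <- sort(unique(terms$id))
  M <- matrix(0L, nrow = length(compounds), ncol = length(term_ids),
              dimnames = list(compounds, term_ids))
  if (length(term_ids) > 0 && nrow(tp) > 0) {
    chains <- dplyr::inner_join(net$ct_edges[, c("compound_id", "target_id")],
                                tp, by = "target_id",
                                relationship = "many-to-many") |>
      dplyr::count(.data$compound_id, .data$term_id)
    M[cbind(chains$compound_id, chains$term_id)] <- chains$n
  }
  if (mode == "binary") M[] <- as.integer(M > 0)
  attr(M, "fingerprint_mode") <- mode
  M
}

#' PathSim similarity between all compounds
#'
#' PathSim along the symmetric meta-path compound -> target -> term ->
#' target -> compound: with P = M %*% t(M) the matrix of meta-path
#' instance counts between compounds,
#' s(x, y) = 2 P\[x,y\] / (P\[x,x\] + P\[y,y\]).
#' A compound with no compound-target-term path at all (P\[x,x\] = 0) gets
#' similarity 0 to everything, including itself, and is reported in a
#' message; such path-less compounds carry no fingerprint information.
#'
#' @param M A path-count matrix from [path_count_matrix()].
#' @return Symmetric numeric matrix of similarities in \[0, 1\] with unit
#'   diagonal for path-bearing compounds; attribute `pathless` lists
#'   path-less compound ids.
#' @export
pathsim <- function(M) {
  stopifnot(is.matrix(M), !is.null(rownames(M)))
  P <- M %*% t(M)
  diagP <- diag(P)
  denom <- outer(diagP, diagP, `+`)
  S <- ifelse(denom > 0, 2 * P / denom, 0)
  dimnames(S) <- list(rownames(M), rownames(M))
  pathless <- rownames(M)[diagP == 0]
  if (length(pathless) > 0) {
    message(length(pathless), " path-less compound(s) assigned similarity 0: ",
            paste(head(pathless, 5), collapse = ", "))
  }
  attr(S, "pathless") <- pathless
  S
}

#' Distance matrix from a similarity matrix
#'
#' Element-wise d = 1 - s; the distance between two compounds lies in
#' \[0, 1\] and smaller distance means higher fingerprint similarity.
#'
#' @param S Similarity matrix from [pathsim()].
#' @return Numeric distance matrix.
#' @export
to_distance <- function(S) {
  stopifnot(is.matrix(S))
  if (any(S < -1e-12 | S > 1 + 1e-12)) stop("similarity values outside [0, 1]")
  D <- 1 - S
  attr(D, "pathless") <- attr(S, "pathless")
  D
}

#' Long-format view of a square similarity or distance matrix
#'
#' @param m Square matrix with dimnames.
#' @param value Name for the value column.
#' @param upper_only Keep only pairs with x < y (drop diagonal and
#'   mirror duplicates).
#' @return Tibble with columns `x`, `y` and the value column.
#' @export
matrix_to_long <- function(m, value = "value", upper_only = FALSE) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  out <- tibble::as_tibble(m, rownames = "x") |>
    tidyr::pivot_longer(-"x", names_to = "y", values_to = value)
  if (upper_only) out <- dplyr::filter(out, .data$x < .data$y)
  out
}

#' Write / read a square matrix as CSV with an id header column
#'
#' @param m Square numeric matrix with dimnames.
#' @param path File path.
#' @return `write_matrix_csv()` returns `path` invisibly;
#'   `read_matrix_csv()` the matrix.
#' @export
write_matrix_csv <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "id")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$id
  m
}
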