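#' Configuration for the synthetic network generator
#'
#' Defines the planted structure the generator emulates: K latent
#' mechanism groups of compounds whose targets annotate to
#' group-specific term pools, with a tunable fraction of noise
#' annotations landing on out-of-group terms; comparator (western)
#' drugs carry group-aligned ATC level-3 codes; indications are drug
#' sets spanning several groups; drug signatures shift group-term genes
#' by a signed amount.
#'
#' Defaults describe a compact but realistic benchmark: 4 mechanism
#' groups of 8 compounds (3 preparation components + 5 comparator
#' drugs), 8 predicted targets per compound with 2 annotations each over
#' a 10-term group pool, 10% annotation noise, and signatures with a
#' 2-sigma planted shift on standardized (z-score) expression.
#'
#' @param K Number of mechanism groups.
#' @param n_tcm_per_group,n_wm_per_group Components / drugs per group.
#' @param n_targets_per_compound Predicted targets per compound.
#' @param terms_per_group Group-specific function terms.
#' @param shared_term_pool Background terms reachable only through noise
#'   annotations.
#' @param noise_rate Fraction of annotations landing outside the
#'   compound's group pool, in \[0, 1\].
#' @param annotations_per_target Terms each target annotates to.
#' @param n_indications Number of indications to emit.
#' @param groups_per_indication Groups each indication spans.
#' @param signature_shift Planted |z| shift on group-term genes (delta).
#' @param signature_noise_sd SD of the Gaussian baseline z-scores.
#' @param score_range Range of compound-target confidence scores
#'   (uniform), kept above the default score cutoff of 20.
#' @param seed Integer RNG seed; the generator is deterministic given it.
#' @return A validated list of class `cfp_config`.
#' @export
synthetic_config <- function(K = 4, n_tcm_per_group = 3, n_wm_per_group = 5,
                             n_targets_per_compound = 8, terms_per_group = 10,
                             shared_term_pool = 5, noise_rate = 0.1,
                             annotations_per_target = 2,
                             n_indications = 3, groups_per_indication = 2,
                             signature_shift = 2, signature_noise_sd = 1,
                             score_range = c(21, 40), seed = 1) {
  cfg <- list(
    K = K, n_tcm_per_group = n_tcm_per_group, n_wm_per_group = n_wm_per_group,
    n_targets_per_compound = n_targets_per_compound,
    terms_per_group = terms_per_group, shared_term_pool = shared_term_pool,
    noise_rate = noise_rate, annotations_per_target = annotations_per_target,
    n_indications = n_indications, groups_per_indication = groups_per_indication,
    signature_shift = signature_shift, signature_noise_sd = signature_noise_sd,
    score_range = score_range, seed = as.integer(seed)
  )
  counts <- cfg[c("K", "n_tcm_per_group", "n_wm_per_group",
                  "n_targets_per_compound", "terms_per_group",
                  "annotations_per_target", "n_indications",
                  "groups_per_indication")]
  if (any(unlist(counts) < 1)) stop("all counts must be >= 1")
  if (cfg$noise_rate < 0 || cfg$noise_rate > 1) stop("noise_rate must lie in [0, 1]")
  if (cfg$groups_per_indication > cfg$K) stop("groups_per_indication exceeds K")
  if (cfg$shared_term_pool < 0) stop("shared_term_pool must be >= 0")
  if (cfg$K < 2 && cfg$noise_rate > 0) {
    stop("noise annotations need at least 2 groups to land outside of")
  }
  structure(cfg, class = "cfp_config")
}

#' Generate a synthetic heterogeneous network with planted structure
#'
#' Emits a `hetnet`, an indication table, a signature table and the
#' ground truth used to validate every pipeline stage: compound group
#' membership, group term pools, indication-group spans and planted
#' signature directions per (group, term). Each target annotates to
#' in-group terms with probability `1 - noise_rate`, else to a uniformly
#' random out-of-group (or background) term. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A `cfp_config` from [synthetic_config()].
#' @return List of class `cfp_synthetic` with elements `network`,
#'   `indications` (tibble `indication_id`, `wm_id`), `signatures`
#'   (tibble `drug_id`, `gene`, `z`) and `truth` (list:
#'   `compound_group`, `group_terms`, `indication_groups`,
#'   `direction` tibble (`group`, `term_id`, `direction`)).
#' @export
generate_synthetic <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "cfp_config"))
  set.seed(cfg$seed)

  group_terms <- lapply(seq_len(cfg$K), function(g) {
    sprintf("G%02dT%02d", g, seq_len(cfg$terms_per_group))
  })
  shared_terms <- if (cfg$shared_term_pool > 0) {
    sprintf("SHT%02d", seq_len(cfg$shared_term_pool))
  } else character(0)
  all_terms <- c(unlist(group_terms), shared_terms)

  compounds <- purrr::map_dfr(seq_len(cfg$K), function(g) {
    tibble::tibble(
      id = c(sprintf("TCM_g%d_%02d", g, seq_len(cfg$n_tcm_per_group)),
             sprintf("WM_g%d_%02d", g, seq_len(cfg$n_wm_per_group))),
      role = rep(c("tcm_component", "western_drug"),
                 c(cfg$n_tcm_per_group, cfg$n_wm_per_group)),
      group = g
    )
  })
  group_atc <- sprintf("%s%02dA", LETTERS[((seq_len(cfg$K) - 1) %% 26) + 1],
                       seq_len(cfg$K))

  ct <- list(); tp <- list()
  for (i in seq_len(nrow(compounds))) {
    cid <- compounds$id[i]; g <- compounds$group[i]
    tg <- sprintf("%s_tg%02d", cid, seq_len(cfg$n_targets_per_compound))
    ct[[i]] <- tibble::tibble(
      compound_id = cid, target_id = tg,
      score = runif(length(tg), cfg$score_range[1], cfg$score_range[2])
    )
    own <- group_terms[[g]]
    other <- setdiff(all_terms, own)
    n_ann <- length(tg) * cfg$annotations_per_target
    from_own <- runif(n_ann) >= cfg$noise_rate
    terms_drawn <- character(n_ann)
    terms_drawn[from_own] <- sample(own, sum(from_own), replace = TRUE)
    if (any(!from_own)) {
      terms_drawn[!from_own] <- sample(other, sum(!from_own), replace = TRUE)
    }
    tp[[i]] <- tibble::tibble(
      target_id = rep(tg, each = cfg$annotations_per_target),
      term_id = terms_drawn
    )
  }
  ct_edges <- dplyr::bind_rows(ct)
  tp_pairs <- dplyr::bind_rows(tp) |>
    dplyr::distinct() |>
    dplyr::mutate(source = "GO_BP", term_name = .data$term_id)

  meta <- compound_meta(
    id = compounds$id, role = compounds$role,
    atc_codes = purrr::map2(compounds$role, compounds$group, function(r, g) {
      if (r == "western_drug") group_atc[g] else character(0)
    })
  )
  net <- suppressWarnings(build_network(ct_edges, tp_pairs, meta, score_threshold = 20))

  ind_groups <- lapply(seq_len(cfg$n_indications), function(i) {
    sort(sample(cfg$K, cfg$groups_per_indication))
  })
  indications <- purrr::map_dfr(seq_len(cfg$n_indications), function(i) {
    wm <- compounds$id[compounds$role == "western_drug" &
                         compounds$group %in% ind_groups[[i]]]
    tibble::tibble(indication_id = sprintf("IND%02d", i), wm_id = wm)
  })

  direction <- purrr::map_dfr(seq_len(cfg$K), function(g) {
    tibble::tibble(
      group = g, term_id = group_terms[[g]],
      direction = sample(c("up", "down"), cfg$terms_per_group, replace = TRUE)
    )
  })
  term_gene_sets <- split(net$tp_edges$target_id, net$tp_edges$term_id)
  all_genes <- net$targets$id
  wm_rows <- compounds[compounds$role == "western_drug", ]
  signatures <- purrr::map_dfr(seq_len(nrow(wm_rows)), function(i) {
    wid <- wm_rows$id[i]; g <- wm_rows$group[i]
    z <- rnorm(length(all_genes), 0, cfg$signature_noise_sd)
    names(z) <- all_genes
    dirs <- direction[direction$group == g, ]
    for (j in seq_len(nrow(dirs))) {
      genes <- term_gene_sets[[dirs$term_id[j]]]
      if (!is.null(genes)) {
        sgn <- if (dirs$direction[j] == "up") 1 else -1
        z[genes] <- z[genes] + sgn * cfg$signature_shift
      }
    }
    tibble::tibble(drug_id = wid, gene = names(z), z = unname(z))
  })

  structure(
    list(
      network = net,
      indications = indications,
      signatures = signatures,
      truth = list(
        compound_group = setNames(compounds$group, compounds$id),
        group_terms = group_terms,
        indication_groups = setNames(ind_groups, sprintf("IND%02d", seq_len(cfg$n_indications))),
        direction = direction
      ),
      config = cfg
    ),
    class = "cfp_synthetic"
  )
}

#' Write a synthetic bundle to the file formats the readers consume
#'
#' Emits the compound-target TSV, the GMT annotation file, the compound
#' metadata TSV, the indication TSV, the signature TSV and a
#' ground-truth JSON into `dir`.
#'
#' @param bundle A `cfp_synthetic` from [generate_synthetic()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_synthetic <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cfp_synthetic"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  net <- bundle$network
  paths <- c(
    ct = file.path(dir, "compound_target.tsv"),
    gmt = file.path(dir, "annotations.gmt"),
    meta = file.path(dir, "compounds.tsv"),
    ind = file.path(dir, "indications.tsv"),
    sig = file.path(dir, "signatures.tsv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_tsv(net$ct_edges, paths[["ct"]])
  gmt_lines <- net$tp_edges |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(line = paste(c(.data$term_id[1], .data$term_id[1],
                                    sort(.data$target_id)), collapse = "\t"),
                     .groups = "drop")
  writeLines(gmt_lines$line, paths[["gmt"]])
  meta_tsv <- net$compounds |>
    dplyr::transmute(
      id = .data$id, name = .data$name, role = .data$role,
      atc_codes = purrr::map_chr(.data$atc_codes, paste, collapse = ";"),
      indications = purrr::map_chr(.data$indication_ids, paste, collapse = ";")
    )
  readr::write_tsv(meta_tsv, paths[["meta"]])
  readr::write_tsv(bundle$indications, paths[["ind"]])
  readr::write_tsv(bundle$signatures, paths[["sig"]])
  jsonlite::write_json(
    list(
      compound_group = as.list(bundle$truth$compound_group),
      group_terms = bundle$truth$group_terms,
      indication_groups = bundle$truth$indication_groups,
      direction = bundle$truth$direction
    ),
    paths[["truth"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Deterministic worked-example fixture (lumbar-disc-herniation style)
#'
#' Builds a small fully deterministic network whose screening stage
#' reproduces the canonical worked example end-to-end: one indication
#' with 32 comparator drugs spread over 7 cluster groups, of which 23
#' fall strictly below the 0.53 screening distance to at least one
#' component (drug coverage 23/32 = 0.72) and every one of the 7 groups
#' contains a similar drug (group coverage 7/7 = 1).
#'
#' Construction: 7 mechanism groups with 6 core terms each (one core
#' target per term). Components and "similar" drugs in a group reach all
#' 6 core terms; similar drugs add 1 private term (distance to the
#' component 1/13, about 0.08), "dissimilar" drugs add 30 private terms
#' (distance 30/42, about 0.71, above the 0.53 screen but still closer
#' to their own group than to any other, so they co-cluster).
#'
#' @return List of class `cfp_fixture`: `network`, `indications`,
#'   `threshold` (0.53), `k` (7), `tcm_ids`, and `expected` counts
#'   (d = 23, D = 32, g = 7, G = 7).
#' @export
worked_example_fixture <- function() {
  n_similar <- c(4, 4, 4, 3, 3, 3, 2)     # 23 similar drugs
  n_dissimilar <- c(2, 2, 1, 1, 1, 1, 1)  # 9 non-similar drugs
  n_core <- 6
  n_private_dissim <- 30
  group_atc <- sprintf("%s%02dA", LETTERS[1:7], 1:7)

  ct <- list(); tp <- list(); ids <- list(); roles <- list(); atcs <- list()
  add_compound <- function(cid, g, role, n_private) {
    core_tg <- sprintf("g%d_core_t%02d", g, seq_len(n_core))
    tg <- core_tg
    ann <- tibble::tibble(target_id = core_tg,
                          term_id = sprintf("g%d_term%02d", g, seq_len(n_core)))
    if (n_private > 0) {
      priv_tg <- sprintf("%s_priv_t%02d", cid, seq_len(n_private))
      tg <- c(tg, priv_tg)
      ann <- dplyr::bind_rows(ann, tibble::tibble(
        target_id = priv_tg, term_id = sprintf("%s_priv_p%02d", cid, seq_len(n_private))
      ))
    }
    ct[[length(ct) + 1]] <<- tibble::tibble(compound_id = cid, target_id = tg, score = 30)
    tp[[length(tp) + 1]] <<- ann
    ids[[length(ids) + 1]] <<- cid
    roles[[length(roles) + 1]] <<- role
    atcs[[length(atcs) + 1]] <<- if (role == "western_drug") group_atc[g] else character(0)
  }

  for (g in 1:7) {
    add_compound(sprintf("TCM%02d", g), g, "tcm_component", 0)
    for (i in seq_len(n_similar[g])) {
      add_compound(sprintf("WM_sim_g%d_%02d", g, i), g, "western_drug", 1)
    }
    for (i in seq_len(n_dissimilar[g])) {
      add_compound(sprintf("WM_far_g%d_%02d", g, i), g, "western_drug", n_private_dissim)
    }
  }
  ct_edges <- dplyr::bind_rows(ct)
  tp_pairs <- dplyr::bind_rows(tp) |>
    dplyr::distinct() |>
    dplyr::mutate(source = "GO_BP", term_name = .data$term_id)
  meta <- compound_meta(id = unlist(ids), role = unlist(roles), atc_codes = atcs)
  net <- build_network(ct_edges, tp_pairs, meta, score_threshold = 20)
  wm_ids <- compound_ids(net, "western_drug")
  structure(
    list(
      network = net,
      indications = tibble::tibble(indication_id = "LDH", wm_id = wm_ids),
      threshold = 0.53,
      k = 7,
      tcm_ids = compound_ids(net, "tcm_component"),
      expected = list(d = 23, D = 32, g = 7, G = 7)
    ),
    class = "cfp_fixture"
  )
}
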