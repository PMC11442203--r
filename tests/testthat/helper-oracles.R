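# Independent oracles, kept deliberately naive so they share no code path
# with the implementation they check.

# Random small tripartite network: every compound keeps >= 1 edge above
# the score threshold so build_network retains all of them.
random_toy_network <- function(n_compounds = 8, n_targets = 10, n_terms = 6,
                               edge_prob = 0.4, ann_prob = 0.4) {
  cids <- sprintf("c%02d", seq_len(n_compounds))
  tids <- sprintf("t%02d", seq_len(n_targets))
  pids <- sprintf("p%02d", seq_len(n_terms))
  ct <- expand.grid(compound_id = cids, target_id = tids,
                    stringsAsFactors = FALSE)
  ct <- ct[runif(nrow(ct)) < edge_prob, ]
  # guarantee an edge per compound
  for (cid in setdiff(cids, unique(ct$compound_id))) {
    ct <- rbind(ct, data.frame(compound_id = cid,
                               target_id = sample(tids, 1)))
  }
  ct <- tibble::tibble(compound_id = ct$compound_id, target_id = ct$target_id,
                       score = runif(nrow(ct), 21, 40))
  tp <- expand.grid(target_id = tids, term_id = pids,
                    stringsAsFactors = FALSE)
  tp <- tp[runif(nrow(tp)) < ann_prob, ]
  tp <- tibble::tibble(target_id = tp$target_id, term_id = tp$term_id,
                       source = "GO_BP", term_name = tp$term_id)
  roles <- rep(c("tcm_component", "western_drug"), length.out = n_compounds)
  meta <- compound_meta(id = cids, role = roles)
  suppressWarnings(suppressMessages(
    build_network(tibble::as_tibble(ct), tibble::as_tibble(tp), meta,
                  score_threshold = 20)
  ))
}

# Brute-force PathSim: enumerate every compound->target->term->target->
# compound chain with explicit loops over the edge lists, in integer
# arithmetic, then normalize. No matrix algebra.
oracle_pathsim <- function(net) {
  cids <- net$compounds$id
  ct <- net$ct_edges
  tp <- net$tp_edges
  n <- length(cids)
  P <- matrix(0L, n, n, dimnames = list(cids, cids))
  for (x in cids) {
    for (y in cids) {
      count <- 0L
      tx <- ct$target_id[ct$compound_id == x]
      ty <- ct$target_id[ct$compound_id == y]
      for (t1 in tx) {
        terms1 <- tp$term_id[tp$target_id == t1]
        for (p in terms1) {
          for (t2 in ty) {
            if (any(tp$target_id == t2 & tp$term_id == p)) count <- count + 1L
          }
        }
      }
      P[x, y] <- count
    }
  }
  S <- matrix(0, n, n, dimnames = list(cids, cids))
  for (x in cids) {
    for (y in cids) {
      denom <- P[x, x] + P[y, y]
      S[x, y] <- if (denom > 0) 2 * P[x, y] / denom else 0
    }
  }
  S
}

# Naive O(n^3) complete-linkage agglomeration: returns merge heights and
# the partition after each merge.
oracle_complete_linkage <- function(D) {
  clusters <- as.list(rownames(D))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, j, i)
      }
    }
    i <- best[3]; j <- best[2]
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    clusters[[j]] <- merged
    clusters[[i]] <- NULL
    heights <- c(heights, best[1])
    partitions[[length(partitions) + 1]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# Partition-as-canonical-string, for comparing clusterings ignoring labels.
partition_signature <- function(ids, labels) {
  groups <- split(ids, labels)
  paste(sort(vapply(groups, function(g) paste(sort(g), collapse = ","), "")),
        collapse = "|")
}
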