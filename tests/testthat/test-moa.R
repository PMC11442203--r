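sim_matrix <- function(tcm, wm, values) {
  ids <- c(tcm, wm)
  S <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  S[tcm, wm] <- values
  S[wm, tcm] <- t(values)
  diag(S) <- 1
  S
}

test_that("nearest drug is the argmax above the floor, ties to smallest id", {
  S <- sim_matrix("c1", c("wmA", "wmB"), matrix(c(0.9, 0.4), 1))
  nm <- nearest_wm(S, "c1", c("wmA", "wmB"), floor = 0.5)
  expect_equal(nm$wm_id, "wmA")
  expect_equal(nm$similarity, 0.9)

  low <- sim_matrix("c1", c("wmA", "wmB"), matrix(c(0.3, 0.4), 1))
  expect_equal(nrow(nearest_wm(low, "c1", c("wmA", "wmB"), floor = 0.5)), 0)

  tie <- sim_matrix("c1", c("wmB", "wmA"), matrix(c(0.8, 0.8), 1))
  expect_equal(nearest_wm(tie, "c1", c("wmB", "wmA"), 0.5)$wm_id, "wmA")
})

test_that("nearest drug matches an exhaustive argmax scan", {
  withr::local_seed(61)
  tcm <- sprintf("c%d", 1:6)
  wm <- sprintf("w%02d", 1:12)
  vals <- matrix(runif(72), 6)
  S <- sim_matrix(tcm, wm, vals)
  nm <- nearest_wm(S, tcm, wm, floor = 0.5)
  for (i in seq_along(tcm)) {
    best_sim <- max(vals[i, ])
    if (best_sim >= 0.5) {
      row <- nm[nm$compound_id == tcm[i], ]
      expect_equal(row$similarity, best_sim)
      expect_equal(row$wm_id, wm[which.max(vals[i, ])])
    } else {
      expect_false(tcm[i] %in% nm$compound_id)
    }
  }
})

test_that("ATC transfer inherits and truncates the nearest drug's codes", {
  nmap <- tibble::tibble(compound_id = "c1", wm_id = "wmA", similarity = 0.9)
  out <- transfer_atc(nmap, list(wmA = "M01AB05"), level = 3)
  expect_equal(out$atc_codes[[1]], "M01A")
  expect_equal(attr(out, "predicted_union"), "M01A")
  expect_warning(
    none <- transfer_atc(nmap, list(wmA = character(0)), level = 3),
    "no ATC codes")
  expect_length(none$atc_codes[[1]], 0)

  withr::local_seed(67)
  nmap2 <- tibble::tibble(compound_id = sprintf("c%d", 1:5),
                          wm_id = sprintf("w%d", 1:5), similarity = 0.9)
  wm_atc <- lapply(setNames(1:5, sprintf("w%d", 1:5)),
                   function(i) sample(c("M01AB05", "N02BA01", "A07EC01"), 2))
  out2 <- transfer_atc(nmap2, wm_atc, level = 3)
  manual <- sort(unique(unlist(lapply(wm_atc, substr, 1, 4))))
  expect_equal(attr(out2, "predicted_union"), manual)
})

test_that("GO-term transfer is the symmetric support intersection", {
  withr::local_seed(71)
  net <- random_toy_network()
  ids <- net$compounds$id
  ab <- transfer_go_terms(ids[1], ids[2], net)
  ba <- transfer_go_terms(ids[2], ids[1], net)
  expect_identical(ab, ba)
  support <- fingerprint_support(net)
  expect_true(all(ab %in% support[[ids[1]]]))
  expect_true(all(ab %in% support[[ids[2]]]))
  # per-node BFS oracle: walk compound -> targets -> terms by hand
  reach <- function(cid) {
    tg <- net$ct_edges$target_id[net$ct_edges$compound_id == cid]
    unique(net$tp_edges$term_id[net$tp_edges$target_id %in% tg])
  }
  expect_setequal(ab, intersect(reach(ids[1]), reach(ids[2])))
  expect_error(transfer_go_terms("nope", ids[1], net), "unknown compound")
})

test_that("identical and disjoint target sets give full and empty transfers", {
  ct <- tibble::tibble(compound_id = c("a", "a", "b", "b", "c"),
                       target_id = c("t1", "t2", "t1", "t2", "t3"),
                       score = 30)
  tp <- tibble::tibble(target_id = c("t1", "t2", "t3"),
                       term_id = c("p1", "p2", "p3"), source = "GO_BP")
  net <- build_network(ct, tp, compound_meta(
    id = c("a", "b", "c"), role = c("tcm_component", "western_drug", "western_drug")), 20)
  expect_setequal(transfer_go_terms("a", "b", net), c("p1", "p2"))
  expect_length(transfer_go_terms("a", "c", net), 0)
})

test_that("common processes are terms reachable from both drug and component sides", {
  syn <- generate_synthetic(synthetic_config(K = 2, noise_rate = 0, seed = 17))
  net <- syn$network
  tcm <- compound_ids(net, "tcm_component")
  wm <- compound_ids(net, "western_drug")
  got <- common_processes(wm, tcm, net)
  support <- fingerprint_support(net, sources = "GO_BP")
  expected <- intersect(unique(unlist(support[wm])), unique(unlist(support[tcm])))
  expect_setequal(got, expected)
  # with zero noise every common process is a planted group term
  expect_true(all(got %in% unlist(syn$truth$group_terms)))
  expect_error(common_processes(character(0), tcm, net), "non-empty")
})

test_that("regulation scores average term genes and honor min_overlap", {
  sig <- c(g1 = 2, g2 = 2, g3 = -1, g4 = 0)
  expect_equal(as.numeric(regulation_score(sig, c("g1", "g2", "g3"))), 1)
  expect_equal(as.numeric(regulation_score(c(a = 2, b = 2, c = 2), c("a", "b", "c"))), 2)
  expect_equal(as.numeric(regulation_score(c(a = 0, b = 0, c = 0), c("a", "b", "c"))), 0)
  nocall <- regulation_score(sig, c("g1", "g2"), min_overlap = 3)
  expect_true(is.na(nocall))
  expect_equal(attr(nocall, "n_overlap"), 2)
  df <- tibble::tibble(gene = c("g1", "g2", "g3"), z = c(2, 2, -1))
  expect_equal(as.numeric(regulation_score(df, c("g1", "g2", "g3"))), 1)
})

test_that("direction calls threshold at tau and distinguish no-calls", {
  expect_equal(regulation_call(2), "up")
  expect_equal(regulation_call(-2), "down")
  expect_equal(regulation_call(0.3), "flat")
  expect_equal(regulation_call(NA_real_), "no_call")
  expect_equal(regulation_call(c(0.6, -0.6, 0.5), tau = 0.5),
               c("up", "down", "flat"))
  expect_error(regulation_call(1, tau = 0), "tau")
})

test_that("negating every z-score swaps up and down and fixes flat", {
  withr::local_seed(73)
  genes <- sprintf("g%d", 1:20)
  for (i in 1:20) {
    sig <- setNames(rnorm(20, sample(c(-2, 0, 2), 1)), genes)
    s_pos <- as.numeric(regulation_score(sig, genes))
    s_neg <- as.numeric(regulation_score(-sig, genes))
    expect_equal(s_neg, -s_pos)
    swap <- c(up = "down", down = "up", flat = "flat")
    expect_equal(regulation_call(s_neg), unname(swap[regulation_call(s_pos)]))
  }
})

test_that("group direction is the thresholded mean of member scores", {
  expect_equal(group_direction(c(2, 1.5, 1)), "up")
  expect_equal(group_direction(c(2, -2)), "flat")
  expect_equal(group_direction(c(-2, -1, NA)), "down")
  expect_error(group_direction(c(NA_real_, NA_real_)), "no scorable")
  withr::local_seed(79)
  for (i in 1:20) {
    scores <- rnorm(5)
    expect_equal(group_direction(scores), regulation_call(mean(scores)))
  }
})
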