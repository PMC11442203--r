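write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("compound-target reader applies a strict threshold and keeps max score", {
  path <- write_tsv_lines(c(
    "compound_id\ttarget_id\tscore",
    "c1\tt1\t25", "c1\tt2\t15", "c2\tt1\t21"
  ))
  edges <- read_compound_target_table(path, score_threshold = 20)
  expect_equal(nrow(edges), 2)
  expect_setequal(paste(edges$compound_id, edges$target_id), c("c1 t1", "c2 t1"))

  dup <- write_tsv_lines(c("c1\tt1\t25", "c1\tt1\t30"))
  edges <- read_compound_target_table(dup, score_threshold = 20, header = FALSE)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$score, 30)
})

test_that("reader errors name the offending line and warn on empty output", {
  bad <- write_tsv_lines(c("c1\tt1\t25", "c2\tt2\tnot_a_number"))
  expect_error(read_compound_target_table(bad, header = FALSE), "line 2")
  low <- write_tsv_lines(c("c1\tt1\t5"))
  expect_warning(out <- read_compound_target_table(low, header = FALSE), "no compound-target")
  expect_equal(nrow(out), 0)
})

test_that("reader matches a brute-force re-scan on random rows", {
  withr::local_seed(42)
  rows <- data.frame(
    compound_id = sample(sprintf("c%d", 1:6), 100, replace = TRUE),
    target_id = sample(sprintf("t%d", 1:8), 100, replace = TRUE),
    score = round(runif(100, 0, 40), 3)
  )
  path <- write_tsv_lines(apply(rows, 1, paste, collapse = "\t"))
  got <- suppressWarnings(read_compound_target_table(path, 20, header = FALSE))
  # oracle: scan row by row, keep max per pair, then filter
  best <- list()
  for (i in seq_len(nrow(rows))) {
    key <- paste(rows$compound_id[i], rows$target_id[i])
    best[[key]] <- max(best[[key]], rows$score[i])
  }
  expected <- sum(unlist(best) > 20)
  expect_equal(nrow(got), expected)
  expect_true(all(got$score > 20))
})

test_that("GMT reader emits deduplicated (gene, term) pairs per line", {
  path <- write_tsv_lines(c("P1\tdesc\tT1\tT2", "P2\tdesc\tT1\tT3"))
  pairs <- read_term_annotations_gmt(path, source = "GO_BP")
  expect_setequal(paste(pairs$target_id, pairs$term_id),
                  c("T1 P1", "T2 P1", "T1 P2", "T3 P2"))
  expect_true(all(pairs$source == "GO_BP"))

  expect_error(read_term_annotations_gmt(write_tsv_lines(c("P1\tdesc")), "GO_BP"),
               "fewer than 3 fields")
  expect_warning(
    skipped <- read_term_annotations_gmt(write_tsv_lines(c("P1\tdesc\t\t", "P2\td\tT1")), "GO_BP"),
    "no genes")
  expect_equal(skipped$term_id, "P2")
})

test_that("GMT pair count matches a line-by-line recount on a random fixture", {
  withr::local_seed(7)
  lines <- vapply(1:20, function(i) {
    genes <- sample(sprintf("G%d", 1:30), sample(1:8, 1))
    paste(c(sprintf("TERM%d", i), "desc", genes), collapse = "\t")
  }, "")
  pairs <- read_term_annotations_gmt(write_tsv_lines(lines), "Reactome")
  recount <- sum(vapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    length(unique(f[-(1:2)]))
  }, 0))
  expect_equal(nrow(pairs), recount)
})

test_that("build_network drops edge-less compounds and audits invariants", {
  ct <- tibble::tibble(compound_id = c("c1", "c2"), target_id = c("t1", "t1"),
                       score = c(25, 21))
  tp <- tibble::tibble(target_id = "t1", term_id = "p1", source = "GO_BP",
                       term_name = "p1")
  meta <- compound_meta(id = c("c1", "c2", "c3"),
                        role = c("tcm_component", "western_drug", "western_drug"))
  expect_warning(net <- build_network(ct, tp, meta, 20), "c3")
  expect_false("c3" %in% net$compounds$id)
  expect_true(validate_network(net))

  orphan <- tibble::tibble(target_id = "t_unknown", term_id = "p9",
                           source = "GO_BP", term_name = "p9")
  expect_error(build_network(ct, rbind(tp, orphan), meta[1:2, ], 20, strict = TRUE),
               "absent from the network")
  expect_warning(net2 <- build_network(ct, rbind(tp, orphan), meta[1:2, ], 20),
                 "absent from the network")
  expect_false("p9" %in% net2$terms$id)
})

test_that("random networks pass a full independent invariant audit", {
  withr::local_seed(11)
  for (i in 1:10) {
    net <- random_toy_network()
    # independent walker: re-derive every referential fact from the tibbles
    expect_true(all(net$ct_edges$compound_id %in% net$compounds$id))
    expect_true(all(net$ct_edges$target_id %in% net$targets$id))
    expect_true(all(net$tp_edges$target_id %in% net$targets$id))
    expect_true(all(net$tp_edges$term_id %in% net$terms$id))
    expect_true(all(net$ct_edges$score > net$score_threshold))
    expect_equal(anyDuplicated(net$ct_edges[, c("compound_id", "target_id")]), 0)
    expect_equal(anyDuplicated(net$tp_edges), 0)
    expect_setequal(unique(net$ct_edges$compound_id), net$compounds$id)
  }
})

test_that("JSON dump round-trips node and edge sets exactly", {
  withr::local_seed(3)
  net <- random_toy_network()
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- suppressWarnings(read_network_json(path))
  expect_equal(back$compounds, net$compounds)
  expect_equal(back$targets, net$targets)
  expect_equal(back$terms, net$terms)
  expect_equal(back$ct_edges, net$ct_edges)
  expect_equal(back$tp_edges, net$tp_edges)
  expect_equal(back$score_threshold, net$score_threshold)
})

test_that("compound metadata enforces roles and the ATC grammar", {
  expect_error(compound_meta(id = "a", role = "potion"), "unknown compound role")
  expect_error(compound_meta(id = c("a", "a"), role = rep("western_drug", 2)),
               "duplicate")
  expect_error(compound_meta(id = "a", role = "western_drug",
                             atc_codes = list("m01ab05")), "malformed ATC")
  ok <- compound_meta(id = "a", role = "western_drug",
                      atc_codes = list(c("M01AB05", "N02B")))
  expect_equal(ok$atc_codes[[1]], c("M01AB05", "N02B"))

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tname\trole\tatc_codes\tindications",
               "c1\tcompound one\ttcm_component\t\t",
               "w1\tdrug one\twestern_drug\tM01AB05;N02BA01\tLDH"), path)
  meta <- read_compound_metadata(path)
  expect_equal(meta$atc_codes[[2]], c("M01AB05", "N02BA01"))
  expect_equal(meta$indication_ids[[2]], "LDH")
  expect_length(meta$atc_codes[[1]], 0)
})

test_that("ATC truncation follows the 5-level grammar", {
  expect_equal(atc_truncate("M01AB05", 1), "M")
  expect_equal(atc_truncate("M01AB05", 2), "M01")
  expect_equal(atc_truncate("M01AB05", 3), "M01A")
  expect_equal(atc_truncate("M01AB05", 4), "M01AB")
  expect_equal(atc_truncate("M01AB05", 5), "M01AB05")
  expect_true(all(atc_valid(c("M01", "M01A", "M01AB", "M01AB05"))))
  expect_false(any(atc_valid(c("M", "1M0", "M01AB051", "m01"))))
})
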