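ref_two_junction <- function() {
  list(R1 = tm("R1", "G1", "c", "+", c(100, 300, 500), c(200, 400, 600)))
}

test_that("reference index collects chains, sites, junctions and footprints", {
  idx <- build_reference_index(ref_two_junction())
  g <- idx$genes$G1
  expect_equal(g$donors, c(200, 400))
  expect_equal(g$acceptors, c(300, 500))
  expect_length(g$chains, 1L)
  # a second transcript sharing a junction does not duplicate it
  refs <- c(ref_two_junction(),
            list(R2 = tm("R2", "G1", "c", "+", c(100, 300), c(200, 400))))
  idx2 <- build_reference_index(refs)
  expect_length(idx2$genes$G1$junction_keys, 2L)
  expect_length(build_reference_index(list())$genes, 0L)
})

test_that("gene assignment picks maximal same-strand overlap, ties lexicographic", {
  refs <- list(A = tm("A1", "gB", "c", "+", 100, 400),
               B = tm("B1", "gA", "c", "+", 600, 900))
  idx <- build_reference_index(refs)
  expect_equal(assign_gene(tm("q", NA, "c", "+", 150, 250), idx), "gB")
  expect_true(is.na(assign_gene(tm("q", NA, "c", "+", 1000, 1100), idx)))
  expect_true(is.na(assign_gene(tm("q", NA, "c", "-", 150, 250), idx)))
  # exact tie: both genes overlap 50 bp -> lexicographically smaller id
  refs2 <- list(A = tm("A1", "gB", "c", "+", 100, 200),
                B = tm("B1", "gA", "c", "+", 300, 400))
  idx2 <- build_reference_index(refs2)
  expect_message(
    got <- assign_gene(tm("q", NA, "c", "+", c(150, 300), c(200, 350)), idx2),
    "tie")
  expect_equal(got, "gA")
})

test_that("structural categories follow the FSM/ISM/NNC/NIC rule order", {
  idx <- build_reference_index(ref_two_junction())
  q_fsm <- tm("q1", NA, "c", "+", c(110, 300, 500), c(200, 400, 590))
  expect_equal(classify_transcript(q_fsm, idx)$category, "FSM")
  expect_equal(classify_transcript(q_fsm, idx)$matched_reference_id, "R1")
  q_ism <- tm("q2", NA, "c", "+", c(320, 500), c(400, 580))
  expect_equal(classify_transcript(q_ism, idx)$category, "ISM")
  refs <- list(R1 = tm("R1", "G1", "c", "+", c(100, 300, 500), c(200, 400, 600)),
               R2 = tm("R2", "G1", "c", "+", c(100, 350), c(200, 500)))
  idx2 <- build_reference_index(refs)
  q_nic <- tm("q3", NA, "c", "+", c(100, 350, 500), c(200, 400, 600))
  expect_equal(classify_transcript(q_nic, idx2)$category, "NIC")
  q_nnc <- tm("q4", NA, "c", "+", c(100, 310, 500), c(200, 400, 600))
  expect_equal(classify_transcript(q_nnc, idx2)$category, "NNC")
  expect_equal(classify_transcript(tm("q5", NA, "c", "+", 5000, 5100),
                                   idx2)$category, "other")
  expect_error(classify_transcript(q_fsm, build_reference_index(list())),
               "empty")
})

test_that("mono-exonic queries are FSM within end slack, else other", {
  refs <- list(M = tm("M1", "G1", "c", "+", 100, 500))
  idx <- build_reference_index(refs)
  expect_equal(classify_transcript(tm("q", NA, "c", "+", 80, 520), idx)$category,
               "FSM")
  expect_equal(classify_transcript(tm("q", NA, "c", "+", 20, 520), idx)$category,
               "other")
})

test_that("classification agrees with the sub-chain/site-set oracle on random queries", {
  set.seed(71)
  for (rep in 1:40) {
    strand <- sample(c("+", "-"), 1L)
    pool <- sort(sample(seq(100, 4000, by = 10), 24))
    n_chains <- sample(1:3, 1L)
    chains <- lapply(seq_len(n_chains), function(i) {
      random_chain(pool, sample(2:5, 1L))
    })
    refs <- lapply(seq_along(chains), function(i) {
      e <- exons_from_chain(chains[[i]])
      tm(paste0("R", i), "G1", "c", strand, e$starts, e$ends)
    })
    idx <- build_reference_index(refs)
    for (qrep in 1:25) {
      mode <- sample(3, 1L)
      qj <- if (mode == 1L) {
        chains[[sample(n_chains, 1L)]]
      } else if (mode == 2L) {
        ch <- chains[[sample(n_chains, 1L)]]
        i <- sample.int(nrow(ch), 1L)
        j <- i + sample.int(nrow(ch) - i + 1L, 1L) - 1L
        ch[i:j, , drop = FALSE]
      } else {
        random_chain(sort(c(pool, sample(seq(105, 4005, by = 10), 10))),
                     sample(1:5, 1L))
      }
      e <- exons_from_chain(qj)
      q <- tm("q", NA, "c", strand, e$starts, e$ends)
      got <- classify_transcript(q, idx)$category
      # brute-force per-base overlap decides gene assignment first
      lo <- 0; hi <- 5000
      ref_mem <- Reduce(`|`, lapply(refs, exon_membership, lo, hi))
      overlap <- sum(ref_mem & exon_membership(q, lo, hi))
      want <- if (overlap == 0) "other" else {
        oracle_classify(tx_junctions(q), chains, strand)
      }
      expect_equal(got, want)
    }
  }
})

test_that("adding reference transcripts never makes a query less known", {
  set.seed(73)
  rank_of <- c(other = 0, NNC = 1, NIC = 2, ISM = 3, FSM = 4)
  for (rep in 1:30) {
    pool <- sort(sample(seq(100, 3000, by = 10), 20))
    chains <- lapply(1:3, function(i) random_chain(pool, sample(2:4, 1L)))
    refs <- lapply(seq_along(chains), function(i) {
      e <- exons_from_chain(chains[[i]])
      tm(paste0("R", i), "G1", "c", "+", e$starts, e$ends)
    })
    idx_small <- build_reference_index(refs[1:2])
    idx_full <- build_reference_index(refs)
    qj <- random_chain(sort(c(pool, sample(seq(105, 3005, by = 10), 6))),
                       sample(1:4, 1L))
    e <- exons_from_chain(qj)
    q <- tm("q", NA, "c", "+", e$starts, e$ends)
    c1 <- classify_transcript(q, idx_small)$category
    c2 <- classify_transcript(q, idx_full)$category
    expect_gte(rank_of[[c2]], rank_of[[c1]])
  }
})

test_that("canonical splice dinucleotides are strand-resolved", {
  # + strand: GT..AG intron at [3, 11)
  g <- toy_genome(c1 = "AAAGTTTTCAGAAA")
  expect_true(canonical_status("c1", 3, 11, "+", g))
  expect_false(canonical_status("c1", 3, 11, "-", g))
  # - strand: genomic CT..AC reads GT..AG on the minus strand
  g2 <- toy_genome(c1 = "AAACTTTTTACAAA")
  expect_true(canonical_status("c1", 3, 11, "-", g2))
  expect_false(canonical_status("c1", 3, 11, "+", g2))
  # GG..AG is non-canonical
  g3 <- toy_genome(c1 = "AAAGGTTTCAGAAA")
  expect_false(canonical_status("c1", 3, 11, "+", g3))
  expect_error(canonical_status("c1", 3, 100, "+", g), "range")
})

test_that("quality filters remove intra-priming and unsupported novel junctions, rescuing FSM", {
  # gene on +: reference with a non-canonical junction at (200, 300)
  seq <- paste(sample(c("C", "G", "T"), 700, replace = TRUE), collapse = "")
  gchars <- strsplit(seq, "")[[1L]]
  gchars[201:202] <- c("G", "G"); gchars[299:300] <- c("A", "G")  # non-canonical ref junction
  gchars[401:402] <- c("G", "T"); gchars[499:500] <- c("A", "G")  # canonical
  gchars[421:422] <- c("G", "G"); gchars[441:460] <- "A"          # novel site + A-window
  g <- toy_genome(c1 = paste(gchars, collapse = ""))
  refs <- list(R1 = tm("R1", "G1", "c1", "+", c(100, 300, 500), c(200, 400, 600)))
  idx <- build_reference_index(refs)
  queries <- list(
    FSM = tm("FSM", "G1", "c1", "+", c(100, 300, 500), c(200, 400, 590)),
    # NNC with novel non-canonical junction (420, 500), unsupported
    NNC = tm("NNC", "G1", "c1", "+", c(100, 300, 500), c(200, 420, 600)),
    # ISM ending at 440 with a 20-mer of A downstream (intra-priming)
    ISM = tm("ISM", "G1", "c1", "+", c(300), c(440)))
  queries <- suppressMessages(classify_transcripts(queries, idx))
  sj <- data.frame(chrom = "c1", start = c(200, 400, 420),
                   end = c(300, 500, 500), strand = "+",
                   unique_reads = c(0L, 50L, 2L), multi_reads = 0L,
                   sample_id = "s1")
  rep <- apply_quality_filters(queries, sj, g, idx)
  expect_equal(rep$kept[rep$transcript_id == "FSM"], TRUE)
  expect_equal(rep$rescue_applied[rep$transcript_id == "FSM"], TRUE)
  expect_match(rep$removal_reasons[rep$transcript_id == "FSM"],
               "nc_junction_support")
  expect_false(rep$kept[rep$transcript_id == "NNC"])
  expect_match(rep$removal_reasons[rep$transcript_id == "NNC"],
               "nc_junction_support")
  expect_false(rep$kept[rep$transcript_id == "ISM"])
  expect_match(rep$removal_reasons[rep$transcript_id == "ISM"], "intra_priming")
  # determinism under input reordering
  rep2 <- apply_quality_filters(rev(queries), sj, g, idx)
  expect_equal(rep[order(rep$transcript_id), ],
               rep2[order(rep2$transcript_id), ], ignore_attr = TRUE)
})

test_that("junction concordance counts supported junctions", {
  jx <- data.frame(chrom = "c", start = seq(0, 90, 10), end = seq(5, 95, 10))
  sj <- data.frame(chrom = "c", start = seq(0, 90, 10), end = seq(5, 95, 10),
                   strand = "+", unique_reads = c(rep(5L, 8), 1L, 0L),
                   multi_reads = 0L, sample_id = "s1")
  expect_equal(junction_concordance(jx, sj, min_unique = 3), 0.8)
  expect_equal(junction_concordance(jx, sj, min_unique = 0), 1.0)
  expect_equal(junction_concordance(jx, sj, min_unique = 1), 0.9)
  expect_error(junction_concordance(jx[0, ], sj), "empty")
  per <- junction_concordance(jx, sj, min_unique = 3, per_sample = TRUE)
  expect_equal(unname(per["s1"]), 0.8)
})
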