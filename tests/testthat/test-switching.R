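toy_counts <- function(mat, lens = NULL) {
  if (is.null(lens)) lens <- stats::setNames(rep(500, nrow(mat)), rownames(mat))
  count_matrix(mat, lens)
}

test_that("isoform fractions, missing totals and dIF arithmetic", {
  m <- rbind(iso1 = c(80, 20, 0), iso2 = c(20, 80, 0))
  colnames(m) <- c("s1", "s2", "s3")
  des <- sample_design(c("s1", "s2", "s3"), c("a", "b", "b"), c(0, 6, 6), c(1, 1, 2))
  gm <- c(iso1 = "g1", iso2 = "g1")
  # s3 is all-zero, so the internal TPM step warns as documented
  expect_warning(ift <- isoform_fractions(toy_counts(m), des, gm), "all-zero")
  expect_equal(unname(ift$IF["iso1", c("s1", "s2")]), c(0.8, 0.2))
  expect_true(all(is.na(ift$IF[, "s3"])))
  dif <- isoform_dif(ift, c("a", "b"))
  expect_equal(dif$dIF[dif$isoform_id == "iso1"], -0.6)
  # per-gene dIF sums to zero when all isoforms retained
  expect_equal(sum(dif$dIF), 0, tolerance = 1e-12)
  expect_error(isoform_fractions(toy_counts(m), des, c(iso1 = "g1")),
               "without gene")
})

test_that("identical replicate fractions give p = 1 and no significance", {
  m <- rbind(iso1 = c(60, 60, 60, 60), iso2 = c(40, 40, 40, 40))
  colnames(m) <- paste0("s", 1:4)
  des <- sample_design(paste0("s", 1:4), rep(c("a", "b"), each = 2),
                       c(0, 0, 6, 6), c(1, 2, 1, 2))
  gm <- c(iso1 = "g1", iso2 = "g1")
  res <- test_switch(toy_counts(m), des, gm, c("a", "b"))
  expect_true(all(res$p_value == 1))
  expect_true(all(res$dIF == 0))
  expect_false(any(res$significant))
  expect_error(test_switch(toy_counts(m), des[-1, ], gm, c("a", "b")),
               "replicates")
})

test_that("top switch pair picks extreme dIFs with q then id tie-breaks", {
  sw <- data.frame(isoform_id = c("i1", "i2", "i3"), gene_id = "g",
                   dIF = c(0.4, -0.3, -0.1), p_value = 0.01,
                   q_value = c(0.01, 0.02, 0.03), significant = TRUE)
  pair <- top_switch_pair("g", sw)
  expect_equal(pair$up, "i1"); expect_equal(pair$down, "i2")
  sw0 <- sw; sw0$dIF <- 0
  expect_null(top_switch_pair("g", sw0))
  tie <- data.frame(isoform_id = c("a", "b", "c"), gene_id = "g",
                    dIF = c(0.4, 0.4, -0.4), p_value = 0.01,
                    q_value = c(0.04, 0.01, 0.01), significant = TRUE)
  expect_message(pt <- top_switch_pair("g", tie), "tie")
  expect_equal(pt$up, "b")
})

test_that("longest ATG-initiated ORF is found with 5'-most tie-break", {
  orf <- predict_orf("ATGAAATAG", min_len = 0)
  expect_equal(c(orf$orf_start, orf$orf_end), c(0, 9))
  expect_equal(orf$protein, "MK")
  expect_null(predict_orf("ATGAAATAG"))  # below the 30 nt default
  expect_null(predict_orf("CCCCCCCCCCCC"))
  # two equal-length ORFs in different frames: the most 5' start wins
  seq <- paste0("ATGAAAAAATAG", "C", "ATGCCCCCCTAA")
  orf2 <- predict_orf(seq, min_len = 0)
  expect_equal(orf2$orf_start, 0)
  # brute-force check across all frames
  brute <- function(s) {
    best <- NULL
    for (st in seq_len(nchar(s) - 2)) {
      if (substr(s, st, st + 2) != "ATG") next
      en <- st
      while (en + 2 <= nchar(s) &&
             !substr(s, en, en + 2) %in% c("TAA", "TAG", "TGA")) en <- en + 3
      if (en + 2 > nchar(s)) next
      len <- en + 3 - st
      if (is.null(best) || len > best[2] - best[1]) best <- c(st - 1, en + 2)
    }
    best
  }
  set.seed(9)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
    b <- brute(s)
    o <- predict_orf(s, min_len = 0)
    if (is.null(b)) {
      expect_true(is.null(o) || o$incomplete)
    } else if (!o$incomplete) {
      expect_equal(o$orf_end - o$orf_start, b[2] - b[1])
    }
  }
  expect_error(predict_orf("ATGXXX"), "A/C/G/T/N")
})

test_that("the 50-nt junction rule decides NMD sensitivity strictly", {
  # + strand, exons of 200/100/300 nt: junctions at 200 and 300 in tx coords
  tx <- tm("t", "g", "c", "+", c(0, 300, 500), c(200, 400, 800))
  expect_true(nmd_status(tx, orf_end_tx_coord = 180))   # 120 nt upstream
  expect_false(nmd_status(tx, orf_end_tx_coord = 310))  # stop in last exon
  expect_false(nmd_status(tx, orf_end_tx_coord = 250))  # exactly 50: strict >
  expect_true(nmd_status(tx, orf_end_tx_coord = 249))
  expect_false(nmd_status(tm("m", "g", "c", "+", 0, 900), 100))  # mono-exonic
})

test_that("switch consequences report UTR, NMD, domain and AS changes and flip with the pair", {
  # genome: one contig; up transcript has a long ORF ending early (long 3'UTR)
  set.seed(13)
  backbone <- paste(sample(c("C", "G", "T"), 2000, replace = TRUE), collapse = "")
  ch <- strsplit(backbone, "")[[1L]]
  # ORF: ATG at 101..., stop before 200
  orf_seq <- c("A", "T", "G", rep(c("G", "C", "T"), 30), "T", "A", "A")
  ch[101:(100 + length(orf_seq))] <- orf_seq
  g <- toy_genome(c1 = paste(ch, collapse = ""))
  up <- tm("U", "g1", "c1", "+", 100, 400)
  down <- tm("D", "g1", "c1", "+", c(100, 700), c(400, 1600))
  doms <- data.frame(isoform_id = c("D"), domain_name = "Pkinase",
                     tx_start = 10, tx_end = 70)
  cons <- switch_consequences(up, down, g, doms)
  expect_true("utr3_shorter" %in% cons$consequence_type)
  expect_true("domain_loss" %in% cons$consequence_type)
  expect_true(any(grepl("^as_", cons$consequence_type)))
  flipped <- switch_consequences(down, up, g, doms)
  expect_true("utr3_longer" %in% flipped$consequence_type)
  expect_true("domain_gain" %in% flipped$consequence_type)
  # identical isoforms produce nothing
  none <- switch_consequences(up, tm("U2", "g1", "c1", "+", 100, 400), g)
  expect_equal(nrow(none), 0L)
})

test_that("consequence enrichment applies the exact binomial per opposing pair", {
  mk <- function(n, type) data.frame(
    gene_id = paste0("g", seq_len(n), "_", type), up_isoform = "u",
    down_isoform = "d", consequence_type = type, magnitude = 1)
  cons <- rbind(mk(60, "utr3_shorter"), mk(40, "utr3_longer"),
                mk(5, "nmd_gain"), mk(5, "nmd_loss"))
  res <- consequence_enrichment(cons)
  utr <- res[grepl("utr3", res$pair), ]
  expect_equal(utr$proportion, 0.6)
  expect_equal(utr$p_value, binom.test(60, 100, 0.5)$p.value)
  expect_equal(res$p_value[grepl("nmd", res$pair)], 1)
  one <- consequence_enrichment(mk(1, "utr3_shorter"))
  expect_equal(one$p_value, 1)
})

test_that("estimated dIF tracks planted dIF and the per-gene sum is zero", {
  s <- small_sim(seed = 55, n_genes = 40, fraction_switch_genes = 0.5,
                 fraction_ir_genes = 0, timepoints = c(0, 72))
  ift <- isoform_fractions(s$sim$counts, s$sim$design, s$gene_map)
  dif <- isoform_dif(ift, c("h0", "h72"))
  sums <- tapply(dif$dIF, dif$gene_id, sum)
  expect_true(all(abs(sums) < 1e-9))
  planted <- s$sim$truth_dif[dif$isoform_id]
  expect_lt(mean(abs(dif$dIF - planted)), 0.05)
})
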