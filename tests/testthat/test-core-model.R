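test_that("GTF coordinates convert to 0-based half-open and round-trip", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t301\t400\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'),
    gtf)
  txs <- read_gtf(gtf)
  expect_length(txs, 1L)
  expect_equal(unname(txs$T1$exons),
               cbind(c(100, 300), c(200, 400)), ignore_attr = TRUE)
  out <- tempfile(fileext = ".gtf")
  write_gtf(txs, out)
  again <- read_gtf(out)
  expect_equal(again$T1$exons, txs$T1$exons)
  expect_equal(again$T1$gene_id, "G1")
})

test_that("empty GTF gives an empty collection and shuffled rows the same model", {
  empty <- tempfile(fileext = ".gtf")
  writeLines(character(0), empty)
  expect_length(read_gtf(empty), 0L)

  lines <- c(
    'chr1\tx\texon\t301\t400\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t501\t600\t.\t+\t.\tgene_id "G1"; transcript_id "T1";')
  f1 <- tempfile(); writeLines(lines, f1)
  f2 <- tempfile(); writeLines(lines[c(3, 1, 2)], f2)
  expect_equal(read_gtf(f1)$T1$exons, read_gtf(f2)$T1$exons)
})

test_that("malformed GTF lines are reported with their line number", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t301'), bad)
  expect_error(read_gtf(bad), "line 2")
  overlapping <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t150\t300\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'),
    overlapping)
  expect_error(read_gtf(overlapping), "overlapping")
})

test_that("read_gtf agrees with rtracklayer on a mixed fixture", {
  skip_if_not_installed("rtracklayer")
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t11\t60\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t101\t140\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr2\tx\texon\t21\t90\t.\t-\t.\tgene_id "G2"; transcript_id "T2";'),
    gtf)
  mine <- read_gtf(gtf)
  gr <- rtracklayer::import(gtf, format = "gtf")
  for (id in names(mine)) {
    sub <- gr[gr$transcript_id == id]
    expect_equal(unname(mine[[id]]$exons[, "start"]),
                 sort(GenomicRanges::start(sub)) - 1)
    expect_equal(unname(mine[[id]]$exons[, "end"]),
                 sort(GenomicRanges::end(sub)))
  }
})

test_that("transcript_sequence splices and reverse-complements", {
  g <- toy_genome(ctg = "AAATTTGGG")
  plus <- tm("p", "G", "ctg", "+", c(0, 6), c(3, 9))
  minus <- tm("m", "G", "ctg", "-", c(0, 6), c(3, 9))
  expect_equal(transcript_sequence(plus, g), "AAAGGG")
  expect_equal(transcript_sequence(minus, g), "CCCTTT")
  whole <- tm("w", "G", "ctg", "+", 0, 9)
  expect_equal(transcript_sequence(whole, g), "AAATTTGGG")
  off <- tm("o", "G", "bad", "+", 0, 3)
  expect_error(transcript_sequence(off, g), "chromosome")
  out_of_range <- tm("r", "G", "ctg", "+", 0, 50)
  expect_error(transcript_sequence(out_of_range, g), "contig")
})

test_that("map_tx_to_genome matches the stated spans", {
  plus <- tm("p", "G", "c", "+", c(100, 300), c(200, 400))
  expect_equal(unname(map_tx_to_genome(plus, 50, 150)),
               cbind(c(150, 300), c(200, 350)), ignore_attr = TRUE)
  expect_equal(unname(map_tx_to_genome(plus, 0, 100)),
               cbind(100, 200), ignore_attr = TRUE)
  minus <- tm("m", "G", "c", "-", c(100, 300), c(200, 400))
  expect_equal(unname(map_tx_to_genome(minus, 0, 50)),
               cbind(350, 400), ignore_attr = TRUE)
  expect_error(map_tx_to_genome(plus, 100, 300), "out of range")
})

test_that("map_tx_to_genome agrees with the per-base oracle on random transcripts", {
  set.seed(61)
  for (i in 1:1000) {
    n_ex <- sample(1:5, 1L)
    lens <- sample(3:20, n_ex, replace = TRUE)
    gaps <- sample(2:30, n_ex, replace = TRUE)
    starts <- cumsum(gaps + c(0, lens[-n_ex]))
    tx <- tm("t", "G", "c", sample(c("+", "-"), 1L), starts, starts + lens)
    L <- tx_length(tx)
    q <- sort(sample(0:L, 2L))
    if (q[1L] == q[2L]) next
    got <- map_tx_to_genome(tx, q[1L], q[2L])
    pos <- oracle_tx_positions(tx)[(q[1L] + 1):q[2L]]
    expect_setequal(unlist(lapply(seq_len(nrow(got)), function(r) {
      seq(got[r, 1L], got[r, 2L] - 1)
    })), pos)
    expect_equal(sum(got[, 2L] - got[, 1L]), q[2L] - q[1L])
  }
})

test_that("CPM and TPM normalization follow the closed formulas", {
  cm <- count_matrix(matrix(c(1, 3), ncol = 1,
                            dimnames = list(c("a", "b"), "s1")),
                     c(a = 100, b = 100))
  expect_equal(unname(normalize_counts(cm, "TPM")[, 1L]), c(250000, 750000))
  cm2 <- count_matrix(matrix(c(1, 3), ncol = 1,
                             dimnames = list(c("a", "b"), "s1")),
                      c(a = 100, b = 300))
  expect_equal(unname(normalize_counts(cm2, "TPM")[, 1L]), c(500000, 500000))
  # equal counts and lengths give equal TPM; columns sum to 1e6
  set.seed(5)
  m <- matrix(rpois(60, 40) + 1, nrow = 6,
              dimnames = list(paste0("i", 1:6), paste0("s", 1:10)))
  cm3 <- count_matrix(m, stats::setNames(sample(100:900, 6), rownames(m)))
  tpm <- normalize_counts(cm3, "TPM")
  expect_equal(unname(colSums(tpm)), rep(1e6, 10), tolerance = 1e-9)
  cpm <- normalize_counts(cm3, "CPM")
  expect_equal(unname(colSums(cpm)), rep(1e6, 10), tolerance = 1e-9)
  # all-zero sample returns zeros with a warning
  m0 <- m; m0[, 2] <- 0
  cm0 <- count_matrix(m0, cm3$isoform_lengths)
  expect_warning(tpm0 <- normalize_counts(cm0, "TPM"), "all-zero")
  expect_equal(unname(tpm0[, 2]), rep(0, 6))
})

test_that("SJ tables round-trip through the STAR dialect", {
  sj <- data.frame(chrom = "chr1", start = c(199, 399), end = c(300, 500),
                   strand = "+", unique_reads = c(7L, 2L),
                   multi_reads = c(1L, 0L), sample_id = "s1")
  f <- tempfile(fileext = ".tsv")
  write_sj_table(sj, f)
  back <- read_sj_table(f, sample_id = "s1")
  expect_equal(back$start, sj$start)
  expect_equal(back$end, sj$end)
  expect_equal(back$unique_reads, sj$unique_reads)
})
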