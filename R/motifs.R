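IUPAC_CLASSES <- c(A = "A", C = "C", G = "G", T = "T",
                   R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                   B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Scan a sequence for exact IUPAC-consensus motif matches
#'
#' All (possibly overlapping) start positions where the IUPAC pattern
#' matches on the given sequence. `N` in the sequence never matches any
#' motif symbol; the scan is on the sense strand of the region only.
#'
#' @param seq Nucleotide string over A/C/G/T/N.
#' @param iupac IUPAC consensus string (symbols ACGTRYSWKMBDHVN).
#' @return Integer vector of 0-based match start positions.
#' @export
scan_motif <- function(seq, iupac) {
  iupac <- toupper(iupac)
  syms <- strsplit(iupac, "")[[1L]]
  bad <- setdiff(syms, names(IUPAC_CLASSES))
  if (length(bad)) stop("invalid IUPAC symbol(s): ", paste(bad, collapse = ", "))
  seq <- toupper(seq)
  # overlapping matches via a zero-width lookahead
  pat <- paste0("(?=", paste0("[", IUPAC_CLASSES[syms], "]", collapse = ""), ")")
  hits <- gregexpr(pat, seq, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' Classify gene regions by intron-retention involvement
#'
#' Distinct introns across the gene's isoforms and distinct exons are
#' deduplicated by coordinates and labeled: an intron equal to a
#' retained-intron span is `IR_intron`; the exons immediately flanking
#' an IR intron in a spliced isoform are `IR_exon`; everything else is
#' `nonIR_intron` / `nonIR_exon`.
#'
#' @param transcripts Named list of the gene's [transcript_model()]s.
#' @param ir_spans Matrix of retained-intron intervals for the gene
#'   (pooled [find_retained_introns()] output).
#' @return A data.frame: `chrom`, `start`, `end`, `strand`,
#'   `region_class`.
#' @export
classify_regions <- function(transcripts, ir_spans) {
  chrom <- transcripts[[1L]]$chrom
  strand <- transcripts[[1L]]$strand
  introns <- list(); exons <- list()
  for (tx in transcripts) {
    j <- tx_junctions(tx)
    for (i in seq_len(nrow(j))) introns[[length(introns) + 1L]] <- j[i, ]
    for (i in seq_len(nrow(tx$exons))) {
      exons[[length(exons) + 1L]] <- tx$exons[i, ]
    }
  }
  dedup <- function(lst) {
    if (length(lst) == 0L) return(matrix(numeric(0), ncol = 2))
    unique(do.call(rbind, lst))
  }
  introns <- dedup(introns); exons <- dedup(exons)
  ir_key <- if (nrow(ir_spans) > 0L) paste(ir_spans[, 1L], ir_spans[, 2L]) else character(0)
  rows <- list()
  flank_key <- character(0)
  if (nrow(introns) > 0L) {
    ikey <- paste(introns[, 1L], introns[, 2L])
    is_ir <- ikey %in% ir_key
    for (i in seq_len(nrow(introns))) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = introns[i, 1L], end = introns[i, 2L],
        strand = strand,
        region_class = if (is_ir[i]) "IR_intron" else "nonIR_intron",
        stringsAsFactors = FALSE)
    }
    # exons flanking an IR intron in the spliced isoforms
    for (i in which(is_ir)) {
      flank_key <- c(flank_key,
                     paste("end", introns[i, 1L]), paste("start", introns[i, 2L]))
    }
  }
  if (nrow(exons) > 0L) {
    for (i in seq_len(nrow(exons))) {
      fl <- paste("end", exons[i, 2L]) %in% flank_key ||
        paste("start", exons[i, 1L]) %in% flank_key
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = exons[i, 1L], end = exons[i, 2L],
        strand = strand,
        region_class = if (fl) "IR_exon" else "nonIR_exon",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Motif density in 10 relative bins along a region
#'
#' The region is divided into `n_bins` equal-width bins (the last bin
#' absorbs the remainder); a match is counted in the bin holding its
#' start offset, and the density is matches per bp of bin width. Bins
#' are ordered 5' to 3' — reversed relative to genomic order on the
#' minus strand.
#'
#' @param region_length Region length (bp), at least `n_bins`.
#' @param positions 0-based match start offsets within the region
#'   (genomic orientation).
#' @param strand `"+"` or `"-"`.
#' @param n_bins Number of bins (default 10).
#' @return Numeric vector of length `n_bins` (sites per bp), or `NULL`
#'   with a message when the region is shorter than `n_bins`.
#' @export
bin_density <- function(region_length, positions, strand = "+", n_bins = 10L) {
  if (region_length < n_bins) {
    message("region shorter than ", n_bins, " bp skipped")
    return(NULL)
  }
  w <- region_length %/% n_bins
  widths <- rep(w, n_bins)
  widths[n_bins] <- region_length - w * (n_bins - 1L)
  bin <- pmin(positions %/% w + 1L, n_bins)
  cnt <- tabulate(bin, nbins = n_bins)
  dens <- cnt / widths
  if (strand == "-") dens <- rev(dens)
  dens
}

#' Per-region binned motif densities for a set of classified regions
#'
#' Runs [scan_motif()] on each region's genomic sense sequence and
#' [bin_density()] on the match offsets.
#'
#' @param regions Data.frame from [classify_regions()] (possibly pooled
#'   over genes).
#' @param genome A `DNAStringSet`.
#' @param iupac Motif consensus.
#' @param n_bins Number of bins.
#' @return A list: `density` (region x bin matrix), `region_class`
#'   (vector aligned to rows); regions shorter than `n_bins` are
#'   dropped.
#' @export
region_bin_densities <- function(regions, genome, iupac, n_bins = 10L) {
  dens <- list(); cls <- character(0)
  for (i in seq_len(nrow(regions))) {
    contig <- genome[[regions$chrom[i]]]
    s <- as.character(Biostrings::subseq(contig, regions$start[i] + 1L,
                                         regions$end[i]))
    if (regions$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      # scan on the sense strand; offsets are then already 5'->3'
      pos <- scan_motif(s, iupac)
      d <- bin_density(nchar(s), pos, strand = "+", n_bins = n_bins)
    } else {
      pos <- scan_motif(s, iupac)
      d <- bin_density(nchar(s), pos, strand = "+", n_bins = n_bins)
    }
    if (is.null(d)) next
    dens[[length(dens) + 1L]] <- d
    cls <- c(cls, regions$region_class[i])
  }
  list(density = do.call(rbind, dens), region_class = cls)
}

#' Per-bin one-sided enrichment between two region classes
#'
#' For each bin, a one-sided rank-sum test compares the motif densities
#' of class-1 regions against class-2 regions; BH correction across the
#' bins of the motif.
#'
#' @param bd Output of [region_bin_densities()].
#' @param class_pair `c(class1, class2)`, e.g.
#'   `c("IR_intron", "nonIR_intron")`.
#' @param alternative `"greater"` tests class1 > class2 per bin.
#' @return A data.frame: `bin`, `n_1`, `n_2`, `statistic`, `p_value`,
#'   `q_value`.
#' @export
per_bin_enrichment <- function(bd, class_pair,
                               alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  i1 <- bd$region_class == class_pair[1L]
  i2 <- bd$region_class == class_pair[2L]
  if (sum(i1) < 3L || sum(i2) < 3L) {
    stop("need >= 3 regions per class (have ", sum(i1), " and ", sum(i2), ")")
  }
  n_bins <- ncol(bd$density)
  rows <- lapply(seq_len(n_bins), function(b) {
    w <- wilcoxon_rank_sum(bd$density[i2, b], bd$density[i1, b],
                           alternative = alternative)
    data.frame(bin = b, n_1 = sum(i1), n_2 = sum(i2),
               statistic = w$statistic, p_value = w$p_value)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out
}
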