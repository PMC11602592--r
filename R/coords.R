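#' Spliced transcript sequence from a genome
#'
#' Concatenates the exon sequences in transcript (5' to 3') order;
#' reverse-complemented for minus-strand transcripts.
#'
#' @param tx A [transcript_model()].
#' @param genome A `DNAStringSet` from [read_genome()].
#' @return A character scalar of length `tx_length(tx)`.
#' @export
transcript_sequence <- function(tx, genome) {
  if (!tx$chrom %in% names(genome)) {
    stop("chromosome not in genome: ", tx$chrom)
  }
  contig <- genome[[tx$chrom]]
  if (any(tx$exons[, "end"] > length(contig))) {
    stop("transcript ", tx$transcript_id, ": exon beyond end of contig ",
         tx$chrom, " (length ", length(contig), ")")
  }
  pieces <- Biostrings::DNAStringSet(
    lapply(seq_len(nrow(tx$exons)), function(i) {
      Biostrings::subseq(contig, tx$exons[i, "start"] + 1L, tx$exons[i, "end"])
    }))
  seq <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  if (tx$strand == "-") seq <- Biostrings::reverseComplement(seq)
  as.character(seq)
}

#' Map a transcript-coordinate span to genomic intervals
#'
#' Transcript coordinates count along the mature mRNA 5' to 3' (0-based
#' half-open). The returned genomic intervals partition the queried span,
#' never cross an intron, total `tx_end - tx_start` bp, and are returned
#' in genomic order.
#'
#' @param tx A [transcript_model()].
#' @param tx_start,tx_end Transcript coordinates, `0 <= tx_start < tx_end
#'   <= tx_length(tx)`.
#' @return A numeric matrix with columns `start`, `end`.
#' @export
map_tx_to_genome <- function(tx, tx_start, tx_end) {
  L <- tx_length(tx)
  if (!(tx_start >= 0 && tx_start < tx_end && tx_end <= L)) {
    stop("transcript coordinates out of range: [", tx_start, ",", tx_end,
         ") for length ", L)
  }
  ex <- tx$exons
  ord <- if (tx$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  pos <- 0
  out <- list()
  for (i in ord) {
    len <- ex[i, "end"] - ex[i, "start"]
    lo <- max(tx_start, pos)
    hi <- min(tx_end, pos + len)
    if (lo < hi) {
      if (tx$strand == "+") {
        g0 <- ex[i, "start"] + (lo - pos)
        g1 <- ex[i, "start"] + (hi - pos)
      } else {
        g1 <- ex[i, "end"] - (lo - pos)
        g0 <- ex[i, "end"] - (hi - pos)
      }
      out[[length(out) + 1L]] <- c(g0, g1)
    }
    pos <- pos + len
    if (pos >= tx_end) break
  }
  m <- do.call(rbind, out)
  m <- m[order(m[, 1L]), , drop = FALSE]
  colnames(m) <- c("start", "end")
  m
}

#' Genomic-coordinate to transcript-coordinate lookup
#'
#' Inverse of [map_tx_to_genome()] for a single exonic genomic position.
#' @param tx A [transcript_model()].
#' @param gpos Genomic position (0-based) that must fall inside an exon.
#' @return The transcript coordinate (0-based).
#' @export
map_genome_to_tx <- function(tx, gpos) {
  ex <- tx$exons
  ord <- if (tx$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  pos <- 0
  for (i in ord) {
    len <- ex[i, "end"] - ex[i, "start"]
    if (gpos >= ex[i, "start"] && gpos < ex[i, "end"]) {
      off <- if (tx$strand == "+") gpos - ex[i, "start"] else ex[i, "end"] - 1 - gpos
      return(pos + off)
    }
    pos <- pos + len
  }
  stop("genomic position ", gpos, " not exonic in ", tx$transcript_id)
}
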