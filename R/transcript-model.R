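#' Construct a transcript model
#'
#' A transcript model is an ordered chain of exons on one chromosome and
#' strand, with a gene assignment and (optionally) a structural category
#' relative to a reference annotation. All coordinates are 0-based,
#' half-open; exons are stored in genomic order and must be separated by
#' at least 1 bp (the introns).
#'
#' @param transcript_id Transcript identifier.
#' @param gene_id Gene identifier (may be `NA` before gene assignment).
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of exon boundaries
#'   (0-based half-open), one entry per exon, in any order.
#' @param category One of `"FSM"`, `"ISM"`, `"NIC"`, `"NNC"`, `"other"`,
#'   `"unclassified"`.
#' @param matched_reference_id Reference transcript matched by an FSM/ISM
#'   call, or `NA`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exon_starts, exon_ends,
                             category = "unclassified",
                             matched_reference_id = NA_character_) {
  stopifnot(length(transcript_id) == 1L, length(chrom) == 1L)
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-', got: ", strand)
  }
  if (length(exon_starts) != length(exon_ends) || length(exon_starts) < 1L) {
    stop("transcript ", transcript_id, ": need >= 1 exon with matching starts/ends")
  }
  o <- order(exon_starts)
  exons <- cbind(start = as.numeric(exon_starts[o]), end = as.numeric(exon_ends[o]))
  if (any(exons[, "start"] < 0) || any(exons[, "end"] <= exons[, "start"])) {
    stop("transcript ", transcript_id, ": invalid exon interval (need 0 <= start < end)")
  }
  n <- nrow(exons)
  if (n > 1L && any(exons[-1L, "start"] - exons[-n, "end"] < 1)) {
    stop("transcript ", transcript_id, ": overlapping or abutting exons")
  }
  category <- match.arg(category,
                        c("unclassified", "FSM", "ISM", "NIC", "NNC", "other"))
  structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         chrom = as.character(chrom),
         strand = strand,
         exons = exons,
         category = category,
         matched_reference_id = matched_reference_id),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s %d exon(s) [%s]\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$category))
  invisible(x)
}

#' Splice junctions of a transcript
#'
#' Junctions are the gaps between consecutive exons, as a two-column
#' matrix (`start` = end of the upstream exon = genomic start of the
#' intron; `end` = start of the downstream exon). Coordinates are genomic;
#' the 5'/3' donor/acceptor roles are strand-resolved by
#' [junction_donor_sites()] / [junction_acceptor_sites()].
#'
#' @param tx A `transcript_model`.
#' @return A numeric matrix with 0 or more rows and columns `start`, `end`.
#' @export
tx_junctions <- function(tx) {
  ex <- tx$exons
  n <- nrow(ex)
  if (n < 2L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = ex[-n, "end"], end = ex[-1L, "start"])
}

#' @rdname tx_junctions
#' @param junctions A junction matrix as returned by [tx_junctions()].
#' @param strand `"+"` or `"-"`.
#' @export
junction_donor_sites <- function(junctions, strand) {
  if (strand == "+") junctions[, "start"] else junctions[, "end"]
}

#' @rdname tx_junctions
#' @export
junction_acceptor_sites <- function(junctions, strand) {
  if (strand == "+") junctions[, "end"] else junctions[, "start"]
}

#' Total exonic length of a transcript (nt)
#' @param tx A `transcript_model`.
#' @export
tx_length <- function(tx) sum(tx$exons[, "end"] - tx$exons[, "start"])

#' Strand-resolved transcription start / termination coordinates
#'
#' The TSS is the genomic coordinate where transcription begins (leftmost
#' exon start on `+`, rightmost exon end on `-`); the TTS is the opposite
#' end.
#' @param tx A `transcript_model`.
#' @export
tx_tss <- function(tx) {
  if (tx$strand == "+") tx$exons[1L, "start"] else tx$exons[nrow(tx$exons), "end"]
}

#' @rdname tx_tss
#' @export
tx_tts <- function(tx) {
  if (tx$strand == "+") tx$exons[nrow(tx$exons), "end"] else tx$exons[1L, "start"]
}

# key string for a junction row, used for set membership
junction_keys <- function(chrom, junctions) {
  if (nrow(junctions) == 0L) return(character(0))
  paste0(chrom, ":", junctions[, "start"], "-", junctions[, "end"])
}

# chain key: full junction chain as one string (exact chain identity)
chain_key <- function(junctions) {
  paste(junctions[, "start"], junctions[, "end"], sep = "-", collapse = ";")
}

# total overlap (bp) between two sets of half-open intervals given as
# 2-col matrices; both assumed sorted, non-overlapping within each set
interval_overlap_bp <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1L], b[, 1L])
    hi <- pmin(a[i, 2L], b[, 2L])
    tot <- tot + sum(pmax(0, hi - lo))
  }
  tot
}

# union of half-open intervals (2-col matrix) -> merged sorted matrix
interval_union <- function(m) {
  if (nrow(m) == 0L) return(m)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  out <- list(m[1L, ])
  for (i in seq_len(nrow(m))[-1L]) {
    last <- out[[length(out)]]
    if (m[i, 1L] <= last[2L]) {
      last[2L] <- max(last[2L], m[i, 2L])
      out[[length(out)]] <- last
    } else {
      out[[length(out) + 1L]] <- m[i, ]
    }
  }
  res <- do.call(rbind, out)
  colnames(res) <- c("start", "end")
  res
}

#' Construct a count matrix with isoform lengths
#'
#' @param counts Numeric matrix, isoforms in rows (rownames = isoform ids),
#'   samples in columns (colnames = sample ids). All values must be >= 0.
#' @param isoform_lengths Named numeric vector of isoform lengths (nt),
#'   covering every row of `counts`; all >= 1.
#' @return An object of class `count_matrix` with elements `counts` and
#'   `isoform_lengths`.
#' @export
count_matrix <- function(counts, isoform_lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry isoform rownames and sample colnames")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  miss <- setdiff(rownames(counts), names(isoform_lengths))
  if (length(miss)) stop("isoform_lengths missing for: ", paste(utils::head(miss), collapse = ", "))
  len <- isoform_lengths[rownames(counts)]
  if (any(len < 1)) stop("isoform lengths must be >= 1")
  structure(list(counts = counts, isoform_lengths = len), class = "count_matrix")
}

#' Construct a sample design table
#'
#' @param sample_id Unique sample identifiers.
#' @param condition Condition labels (e.g. `"h0"`, `"h72"`).
#' @param timepoint_h Timepoint in hours.
#' @param replicate Integer replicate index within condition.
#' @return A data.frame with one row per sample.
#' @export
sample_design <- function(sample_id, condition, timepoint_h, replicate) {
  if (anyDuplicated(sample_id)) stop("sample_id values must be unique")
  data.frame(sample_id = as.character(sample_id),
             condition = as.character(condition),
             timepoint_h = as.numeric(timepoint_h),
             replicate = as.integer(replicate),
             stringsAsFactors = FALSE)
}
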