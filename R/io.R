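#' Read transcript models from a GTF file
#'
#' Parses `exon` features carrying `transcript_id` and `gene_id`
#' attributes. GTF 1-based closed coordinates are converted to the
#' package's internal 0-based half-open convention; exons are grouped per
#' transcript and sorted genomically. `write_gtf(read_gtf(x))` preserves
#' coordinates bit-exactly.
#'
#' @param path Path to a GTF file.
#' @return A named list of [transcript_model()] objects.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(structure(list(), names = character(0)))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    bad <- idx[which(nf < 9L)[1L]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated fields, got ",
         nf[which(nf < 9L)[1L]])
  }
  m <- do.call(rbind, fields)
  feat <- m[, 3L]
  sel <- feat == "exon"
  if (!any(sel)) return(structure(list(), names = character(0)))
  m <- m[sel, , drop = FALSE]
  lineno <- idx[sel]
  start1 <- suppressWarnings(as.numeric(m[, 4L]))
  end1 <- suppressWarnings(as.numeric(m[, 5L]))
  if (anyNA(start1) || anyNA(end1)) {
    bad <- lineno[which(is.na(start1) | is.na(end1))[1L]]
    stop("malformed GTF line ", bad, ": non-numeric start/end")
  }
  attr_field <- m[, 9L]
  get_attr <- function(key) {
    pat <- paste0(key, '\\s+"([^"]*)"')
    mm <- regmatches(attr_field, regexec(pat, attr_field))
    vapply(mm, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
  }
  tx <- get_attr("transcript_id")
  gene <- get_attr("gene_id")
  if (anyNA(tx) || anyNA(gene)) {
    bad <- lineno[which(is.na(tx) | is.na(gene))[1L]]
    stop("malformed GTF line ", bad, ": missing transcript_id or gene_id attribute")
  }
  df <- data.frame(chrom = m[, 1L], start = start1 - 1, end = end1,
                   strand = m[, 7L], tx = tx, gene = gene,
                   stringsAsFactors = FALSE)
  out <- lapply(split(df, factor(df$tx, levels = unique(df$tx))), function(d) {
    if (length(unique(d$chrom)) > 1L || length(unique(d$strand)) > 1L) {
      stop("transcript ", d$tx[1L], ": exons on multiple chromosomes/strands")
    }
    transcript_model(d$tx[1L], d$gene[1L], d$chrom[1L], d$strand[1L],
                     d$start, d$end)
  })
  out
}

#' Write transcript models to a GTF file
#'
#' Emits one `transcript` and per-exon `exon` features, converting the
#' internal 0-based half-open coordinates back to GTF 1-based closed.
#'
#' @param transcripts Named list of [transcript_model()] objects.
#' @param path Output file path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path, source = "spliceshift") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (tx in transcripts) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', tx$gene_id, tx$transcript_id)
    ex <- tx$exons
    writeLines(sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       tx$chrom, source, as.integer(ex[1L, "start"]) + 1L,
                       as.integer(ex[nrow(ex), "end"]), tx$strand, attrs), con)
    writeLines(sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                       tx$chrom, source, as.integer(ex[, "start"]) + 1L,
                       as.integer(ex[, "end"]), tx$strand, attrs), con)
  }
  invisible(path)
}

#' Read a genome FASTA into a DNAStringSet handle
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A `Biostrings::DNAStringSet`, names truncated at first whitespace.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read a splice-junction support table (STAR SJ.out.tab dialect)
#'
#' Columns: chrom, 1-based intron start, 1-based intron end, strand code
#' (0 undefined / 1 `+` / 2 `-`), motif code, annotated flag, unique
#' reads, multi reads, overhang. Coordinates are converted to 0-based
#' half-open intron intervals. Several per-sample files may be combined
#' with [combine_sj_tables()].
#'
#' @param path Path to an SJ.out.tab-style TSV.
#' @param sample_id Sample label to attach.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `unique_reads`, `multi_reads`, `sample_id` (intron coordinates
#'   0-based half-open).
#' @export
read_sj_table <- function(path, sample_id = basename(path)) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 8L) stop("SJ table needs >= 8 columns, got ", ncol(d))
  strand <- c("0" = "*", "1" = "+", "2" = "-")[as.character(d[[4L]])]
  out <- data.frame(chrom = as.character(d[[1L]]),
                    start = d[[2L]] - 1, end = d[[3L]],
                    strand = unname(strand),
                    unique_reads = d[[7L]], multi_reads = d[[8L]],
                    sample_id = sample_id, stringsAsFactors = FALSE)
  if (any(out$unique_reads < 0) || any(out$multi_reads < 0)) {
    stop("junction read counts must be non-negative")
  }
  out
}

#' @rdname read_sj_table
#' @param tables List of data.frames from [read_sj_table()] (or built in
#'   code with the same columns).
#' @export
combine_sj_tables <- function(tables) {
  do.call(rbind, tables)
}

#' Write a junction-support table in the STAR SJ.out.tab dialect
#'
#' One file per sample; introns written 1-based closed.
#' @param sj Data.frame as produced by [read_sj_table()] (single sample).
#' @param path Output path.
#' @export
write_sj_table <- function(sj, path) {
  code <- c("*" = 0L, "+" = 1L, "-" = 2L)[sj$strand]
  utils::write.table(
    data.frame(sj$chrom, as.integer(sj$start) + 1L, as.integer(sj$end),
               unname(code), 0L, 0L, sj$unique_reads, sj$multi_reads, 20L),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an isoform count matrix from TSV
#'
#' First column is the isoform id; remaining columns are samples. Lengths
#' are supplied separately (or taken from a `length` column if present).
#'
#' @param path Path to a TSV file.
#' @param isoform_lengths Optional named vector of isoform lengths; if
#'   `NULL`, a `length` column is required in the file.
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(path, isoform_lengths = NULL) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  ids <- d[[1L]]
  d <- d[, -1L, drop = FALSE]
  if (is.null(isoform_lengths)) {
    if (!"length" %in% colnames(d)) stop("no isoform_lengths given and no 'length' column")
    isoform_lengths <- stats::setNames(d[["length"]], ids)
    d <- d[, setdiff(colnames(d), "length"), drop = FALSE]
  }
  m <- as.matrix(d)
  rownames(m) <- ids
  count_matrix(m, isoform_lengths)
}

#' Read a sample design TSV (sample_id, condition, timepoint_h, replicate)
#' @param path Path to a TSV file with a header.
#' @return A data.frame as from [sample_design()].
#' @export
read_design_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  sample_design(d$sample_id, d$condition, d$timepoint_h, d$replicate)
}

#' Read a per-isoform protein-domain table
#'
#' TSV columns: `isoform_id`, `domain_name`, `tx_start`, `tx_end`
#' (0-based half-open transcript coordinates, 5' to 3').
#' @param path Path to the TSV.
#' @return A data.frame with those columns.
#' @export
read_domains_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("isoform_id", "domain_name", "tx_start", "tx_end")
  if (!all(need %in% colnames(d))) {
    stop("domain table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(d$tx_start >= d$tx_end)) stop("domain table: need tx_start < tx_end")
  d[need]
}

#' Read domain hits from an hmmscan --domtblout file
#'
#' Extracts the envelope coordinates (columns 20-21, 1-based closed amino
#' acid positions) and converts them to 0-based half-open nucleotide
#' transcript coordinates relative to the ORF start.
#'
#' @param path Path to an hmmscan domtblout file.
#' @param orf_starts Named vector: transcript coordinate (nt) of the ORF
#'   start per isoform (query name).
#' @return A data.frame in the [read_domains_tsv()] layout.
#' @export
read_domtblout <- function(path, orf_starts) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(isoform_id = character(0), domain_name = character(0),
                      tx_start = numeric(0), tx_end = numeric(0)))
  }
  f <- strsplit(lines, "\\s+")
  dom <- vapply(f, `[`, "", 1L)
  qry <- vapply(f, `[`, "", 4L)
  env_from <- as.numeric(vapply(f, `[`, "", 20L))
  env_to <- as.numeric(vapply(f, `[`, "", 21L))
  off <- orf_starts[qry]
  if (anyNA(off)) stop("orf_starts missing for: ",
                       paste(unique(qry[is.na(off)]), collapse = ", "))
  data.frame(isoform_id = qry, domain_name = dom,
             tx_start = unname(off) + (env_from - 1) * 3,
             tx_end = unname(off) + env_to * 3,
             stringsAsFactors = FALSE)
}

#' Read motif definitions (TSV: name, iupac)
#' @param path Path to the TSV.
#' @return A data.frame with columns `name`, `iupac`.
#' @export
read_motifs_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (!all(c("name", "iupac") %in% colnames(d))) {
    stop("motif table needs columns: name, iupac")
  }
  d
}

#' Read a gene-set list (plain text, one gene id per line)
#' @param path Path to the text file.
#' @return Character vector of gene ids.
#' @export
read_geneset <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}
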