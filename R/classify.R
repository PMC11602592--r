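#' Build a reference index for structural classification
#'
#' Per gene the index stores every reference transcript's full junction
#' chain, the union of known donor and acceptor coordinates
#' (strand-resolved), the set of known junctions, the exonic footprint
#' (union of exons), and the spans of any mono-exonic reference
#' transcripts.
#'
#' @param reference Named list of [transcript_model()]s carrying gene ids.
#' @return An object of class `reference_index`.
#' @export
build_reference_index <- function(reference) {
  genes <- list()
  for (tx in reference) {
    g <- tx$gene_id
    if (is.null(genes[[g]])) {
      genes[[g]] <- list(gene_id = g, chrom = tx$chrom, strand = tx$strand,
                         chains = list(), chain_tx = character(0),
                         donors = numeric(0), acceptors = numeric(0),
                         junction_keys = character(0),
                         footprint = matrix(numeric(0), ncol = 2),
                         mono_spans = matrix(numeric(0), ncol = 2),
                         mono_tx = character(0))
    }
    gi <- genes[[g]]
    if (gi$chrom != tx$chrom || gi$strand != tx$strand) {
      stop("gene ", g, ": reference transcripts on different chrom/strand")
    }
    j <- tx_junctions(tx)
    if (nrow(j) > 0L) {
      gi$chains[[length(gi$chains) + 1L]] <- j
      gi$chain_tx <- c(gi$chain_tx, tx$transcript_id)
      gi$donors <- union(gi$donors, junction_donor_sites(j, tx$strand))
      gi$acceptors <- union(gi$acceptors, junction_acceptor_sites(j, tx$strand))
      gi$junction_keys <- union(gi$junction_keys, junction_keys(tx$chrom, j))
    } else {
      gi$mono_spans <- rbind(gi$mono_spans, tx$exons)
      gi$mono_tx <- c(gi$mono_tx, tx$transcript_id)
    }
    gi$footprint <- rbind(gi$footprint, tx$exons)
    genes[[g]] <- gi
  }
  for (g in names(genes)) {
    genes[[g]]$footprint <- interval_union(genes[[g]]$footprint)
  }
  all_j <- unique(unlist(lapply(genes, `[[`, "junction_keys"), use.names = FALSE))
  structure(list(genes = genes, all_junction_keys = all_j),
            class = "reference_index")
}

#' Assign a query transcript to the reference gene with maximal overlap
#'
#' The gene with the largest same-strand exonic overlap (bp) wins; ties
#' are broken by the lexicographically smallest gene id (logged as a
#' message). No overlap returns `NA`.
#'
#' @param query A [transcript_model()].
#' @param index A `reference_index`.
#' @return A gene id or `NA_character_`.
#' @export
assign_gene <- function(query, index) {
  gene_ids <- names(index$genes)
  bp <- vapply(gene_ids, function(g) {
    gi <- index$genes[[g]]
    if (gi$chrom != query$chrom || gi$strand != query$strand) return(0)
    interval_overlap_bp(query$exons, gi$footprint)
  }, numeric(1))
  if (length(bp) == 0L || max(bp) == 0) return(NA_character_)
  top <- gene_ids[bp == max(bp)]
  if (length(top) > 1L) {
    top <- sort(top)
    message("assign_gene: overlap tie for ", query$transcript_id,
            "; keeping ", top[1L])
  }
  top[1L]
}

# is `sub` (k x 2) a consecutive sub-chain of `chain` (m x 2)?
is_consecutive_subchain <- function(sub, chain) {
  k <- nrow(sub); m <- nrow(chain)
  if (k > m) return(FALSE)
  for (off in 0:(m - k)) {
    if (all(chain[(off + 1):(off + k), ] == sub)) return(TRUE)
  }
  FALSE
}

#' Structural classification of a query isoform
#'
#' Within its assigned gene, a multi-exonic query is called, in order:
#' FSM when its junction chain equals a reference chain; ISM when the
#' chain is a consecutive sub-chain of a reference chain; NNC when any
#' donor or acceptor coordinate is absent from the gene's known-site
#' sets; otherwise NIC (all sites known but the chain is neither a full
#' match nor a consecutive sub-chain). Queries overlapping no gene are
#' `other`. Mono-exonic queries are FSM when a same-gene mono-exonic
#' reference contains them within `mono_end_slack` nt at each end,
#' otherwise `other`.
#'
#' @param query A [transcript_model()].
#' @param index A `reference_index`.
#' @param mono_end_slack End slack (nt) for mono-exonic FSM calls.
#' @return A list with `category` and `matched_reference_id`.
#' @export
classify_transcript <- function(query, index, mono_end_slack = 50) {
  if (length(index$genes) == 0L) stop("empty reference index")
  g <- assign_gene(query, index)
  if (is.na(g)) return(list(category = "other", matched_reference_id = NA_character_))
  gi <- index$genes[[g]]
  qj <- tx_junctions(query)
  if (nrow(qj) == 0L) {
    if (nrow(gi$mono_spans) > 0L) {
      span <- c(query$exons[1L, "start"], query$exons[1L, "end"])
      hit <- which(gi$mono_spans[, 1L] - mono_end_slack <= span[1L] &
                   gi$mono_spans[, 2L] + mono_end_slack >= span[2L])
      if (length(hit)) {
        return(list(category = "FSM", matched_reference_id = gi$mono_tx[hit[1L]]))
      }
    }
    return(list(category = "other", matched_reference_id = NA_character_))
  }
  qkey <- chain_key(qj)
  for (i in seq_along(gi$chains)) {
    if (nrow(gi$chains[[i]]) == nrow(qj) && chain_key(gi$chains[[i]]) == qkey) {
      return(list(category = "FSM", matched_reference_id = gi$chain_tx[i]))
    }
  }
  for (i in seq_along(gi$chains)) {
    if (is_consecutive_subchain(qj, gi$chains[[i]])) {
      return(list(category = "ISM", matched_reference_id = gi$chain_tx[i]))
    }
  }
  don <- junction_donor_sites(qj, query$strand)
  acc <- junction_acceptor_sites(qj, query$strand)
  if (!all(don %in% gi$donors) || !all(acc %in% gi$acceptors)) {
    return(list(category = "NNC", matched_reference_id = NA_character_))
  }
  list(category = "NIC", matched_reference_id = NA_character_)
}

#' Classify a set of query transcripts
#'
#' Vectorised driver over [classify_transcript()]: returns the queries
#' with `gene_id`, `category` and `matched_reference_id` filled in.
#' @param queries Named list of [transcript_model()]s.
#' @param index A `reference_index`.
#' @param mono_end_slack See [classify_transcript()].
#' @return The annotated list of transcripts.
#' @export
classify_transcripts <- function(queries, index, mono_end_slack = 50) {
  for (i in seq_along(queries)) {
    g <- assign_gene(queries[[i]], index)
    res <- classify_transcript(queries[[i]], index, mono_end_slack)
    queries[[i]]$gene_id <- if (is.na(g)) queries[[i]]$gene_id else g
    queries[[i]]$category <- res$category
    queries[[i]]$matched_reference_id <- res$matched_reference_id
  }
  queries
}

#' Canonical status of a splice junction
#'
#' TRUE when the strand-oriented intron terminal dinucleotides are one of
#' GT..AG, GC..AG or AT..AC.
#'
#' @param chrom,start,end Intron interval (0-based half-open, genomic).
#' @param strand `"+"` or `"-"`.
#' @param genome A `DNAStringSet`.
#' @return Logical scalar.
#' @export
canonical_status <- function(chrom, start, end, strand, genome) {
  if (end - start < 4) stop("intron shorter than 4 nt")
  contig <- genome[[chrom]]
  if (start < 0 || end > length(contig)) {
    stop("intron out of range on ", chrom)
  }
  left <- as.character(Biostrings::subseq(contig, start + 1L, start + 2L))
  right <- as.character(Biostrings::subseq(contig, end - 1L, end))
  if (strand == "+") {
    donor <- left; acceptor <- right
  } else {
    rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    donor <- rc(right); acceptor <- rc(left)
  }
  paste0(donor, "..", acceptor) %in% c("GT..AG", "GC..AG", "AT..AC")
}

# max unique-read support per junction key over all samples
.sj_max_support <- function(sj) {
  key <- paste0(sj$chrom, ":", sj$start, "-", sj$end)
  tapply(sj$unique_reads, key, max)
}

#' Apply the isoform quality filters
#'
#' Two removal rules plus an FSM rescue:
#' \describe{
#'   \item{intra_priming}{the genomic window of `window_nt` bases
#'     immediately downstream of the transcript 3' end (read in the
#'     transcript's sense) is at least `a_fraction` adenine — the
#'     oligo-dT mispriming signature.}
#'   \item{nc_junction_support}{for non-FSM isoforms, a junction that is
#'     novel (absent from the reference junction set), non-canonical and
#'     supported by fewer than `min_unique` uniquely mapped reads in
#'     every sample; FSM isoforms are evaluated on any non-canonical
#'     unsupported junction (novel or annotated) but always retained,
#'     with `rescue_applied = TRUE`.}
#' }
#' Removal reasons are reported even for rescued isoforms.
#'
#' @param queries Named list of classified [transcript_model()]s.
#' @param sj Junction-support data.frame (see [read_sj_table()]).
#' @param genome A `DNAStringSet`.
#' @param index The `reference_index` used for classification.
#' @param window_nt Intra-priming window size (default 20).
#' @param a_fraction Adenine fraction threshold (default 0.6).
#' @param min_unique Minimum unique-read junction support (default 3).
#' @return A data.frame (`filter_report`): transcript_id, gene_id,
#'   category, kept, removal_reasons (comma-joined), rescue_applied.
#' @export
apply_quality_filters <- function(queries, sj, genome, index,
                                  window_nt = 20L, a_fraction = 0.6,
                                  min_unique = 3L) {
  support <- .sj_max_support(sj)
  rows <- lapply(queries, function(tx) {
    reasons <- character(0)
    # (a) intra-priming: downstream-of-TTS adenine content in sense
    contig <- genome[[tx$chrom]]
    if (tx$strand == "+") {
      w0 <- tx_tts(tx); w1 <- min(w0 + window_nt, length(contig))
      win <- if (w1 > w0) as.character(Biostrings::subseq(contig, w0 + 1L, w1)) else ""
      a_base <- "A"
    } else {
      w1 <- tx_tts(tx); w0 <- max(w1 - window_nt, 0)
      win <- if (w1 > w0) as.character(Biostrings::subseq(contig, w0 + 1L, w1)) else ""
      a_base <- "T"  # adenine on the minus-strand sense
    }
    if (nchar(win) < window_nt) {
      message("intra-priming window truncated at contig end for ",
              tx$transcript_id)
    }
    if (nchar(win) > 0) {
      frac_a <- sum(strsplit(win, "")[[1L]] == a_base) / nchar(win)
      if (frac_a >= a_fraction) reasons <- c(reasons, "intra_priming")
    }
    # (b) junction support for non-canonical junctions
    j <- tx_junctions(tx)
    nc_hit <- FALSE
    if (nrow(j) > 0L) {
      keys <- junction_keys(tx$chrom, j)
      for (i in seq_len(nrow(j))) {
        novel <- !(keys[i] %in% index$all_junction_keys)
        if (!novel && tx$category != "FSM") next
        if (canonical_status(tx$chrom, j[i, "start"], j[i, "end"],
                             tx$strand, genome)) next
        supp <- support[keys[i]]
        if (is.na(supp)) supp <- 0
        if (supp < min_unique) { nc_hit <- TRUE; break }
      }
    }
    if (nc_hit) reasons <- c(reasons, "nc_junction_support")
    rescue <- tx$category == "FSM" && "nc_junction_support" %in% reasons
    kept <- length(reasons) == 0L ||
      (rescue && identical(reasons, "nc_junction_support"))
    data.frame(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
               category = tx$category, kept = kept,
               removal_reasons = paste(reasons, collapse = ","),
               rescue_applied = rescue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of junctions with short-read support
#'
#' The fraction of `junctions` having at least `min_unique` uniquely
#' mapped reads, either per sample or pooled (supported in at least one
#' sample). The reverse direction (coverage of the short-read junctions
#' by an annotation set) is obtained by swapping the roles of the
#' arguments at the membership level.
#'
#' @param junctions Data.frame with columns `chrom`, `start`, `end`
#'   (intron intervals, 0-based half-open).
#' @param sj Junction-support data.frame.
#' @param min_unique Support threshold.
#' @param per_sample If TRUE, return a named vector of fractions per
#'   sample; otherwise a single pooled fraction.
#' @return Fraction(s) in `[0, 1]`.
#' @export
junction_concordance <- function(junctions, sj, min_unique = 3L,
                                 per_sample = FALSE) {
  if (nrow(junctions) == 0L) stop("empty junction set")
  keys <- unique(paste0(junctions$chrom, ":", junctions$start, "-", junctions$end))
  if (min_unique <= 0) {
    if (per_sample) {
      smp <- unique(sj$sample_id)
      return(stats::setNames(rep(1, length(smp)), smp))
    }
    return(1)
  }
  if (per_sample) {
    vapply(split(sj, sj$sample_id), function(d) {
      skey <- paste0(d$chrom, ":", d$start, "-", d$end)
      ok <- skey[d$unique_reads >= min_unique]
      mean(keys %in% ok)
    }, numeric(1))
  } else {
    supp <- .sj_max_support(sj)
    ok <- names(supp)[supp >= min_unique]
    mean(keys %in% ok)
  }
}
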