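#' Per-sample isoform fractions within genes
#'
#' IF = isoform count / gene total count, `NA` when the gene total is 0
#' in that sample. Genes failing the expression inclusion rule (mean
#' gene TPM at or below `min_gene_tpm`) are flagged excluded but still
#' reported.
#'
#' @param counts A [count_matrix()].
#' @param design A [sample_design()] data.frame covering every sample.
#' @param gene_map Named character vector isoform_id -> gene_id covering
#'   every isoform.
#' @param min_gene_tpm Gene-level TPM inclusion cutoff (default 0.1).
#' @return A list of class `isoform_fraction_table`: `IF` (isoform x
#'   sample matrix), `gene_map`, `gene_totals` (gene x sample),
#'   `excluded_genes`, `design`.
#' @export
isoform_fractions <- function(counts, design, gene_map, min_gene_tpm = 0.1) {
  m <- counts$counts
  if (!setequal(colnames(m), design$sample_id)) {
    stop("count matrix samples and design table disagree")
  }
  m <- m[, design$sample_id, drop = FALSE]
  miss <- setdiff(rownames(m), names(gene_map))
  if (length(miss)) stop("isoforms without gene assignment: ",
                         paste(utils::head(miss), collapse = ", "))
  genes <- gene_map[rownames(m)]
  gene_tot <- rowsum(m, group = genes)
  IF <- m / gene_tot[genes, , drop = FALSE]
  IF[!is.finite(IF)] <- NA
  tpm <- normalize_counts(counts, "TPM")[, design$sample_id, drop = FALSE]
  gene_tpm <- rowsum(tpm, group = genes)
  excluded <- rownames(gene_tpm)[rowMeans(gene_tpm) <= min_gene_tpm]
  structure(list(IF = IF, gene_map = genes, gene_totals = gene_tot,
                 excluded_genes = excluded, design = design),
            class = "isoform_fraction_table")
}

#' Mean isoform fractions per condition and dIF for a condition pair
#'
#' @param ift An `isoform_fraction_table`.
#' @param condition_pair Character vector `c(reference, contrast)`; dIF =
#'   mean IF(contrast) - mean IF(reference).
#' @return A data.frame with `isoform_id`, `gene_id`, `mean_if_1`,
#'   `mean_if_2`, `dIF`.
#' @export
isoform_dif <- function(ift, condition_pair) {
  s1 <- ift$design$sample_id[ift$design$condition == condition_pair[1L]]
  s2 <- ift$design$sample_id[ift$design$condition == condition_pair[2L]]
  if (length(s1) == 0L || length(s2) == 0L) {
    stop("condition not present in design: ",
         paste(condition_pair, collapse = ", "))
  }
  m1 <- rowMeans(ift$IF[, s1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(ift$IF[, s2, drop = FALSE], na.rm = TRUE)
  data.frame(isoform_id = rownames(ift$IF),
             gene_id = unname(ift$gene_map),
             mean_if_1 = unname(m1), mean_if_2 = unname(m2),
             dIF = unname(m2 - m1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Isoform switch test between two conditions
#'
#' For every isoform passing the expression filters, per-replicate
#' isoform fractions are logit-transformed (`logit(x) = log((x + eps) /
#' (1 - x + eps))`) and compared between the two conditions with a Welch
#' t test; p values are BH-adjusted across all tested isoforms. dIF is
#' the difference of raw mean isoform fractions. An isoform switches
#' significantly when `|dIF| > dif_cut` and `q < alpha`.
#'
#' @param counts A [count_matrix()].
#' @param design A [sample_design()] data.frame.
#' @param gene_map Named vector isoform_id -> gene_id.
#' @param condition_pair `c(reference, contrast)` condition labels.
#' @param dif_cut dIF magnitude cutoff (default 0.05).
#' @param alpha FDR cutoff (default 0.05).
#' @param eps Logit offset (default 0.01).
#' @param min_gene_tpm Gene TPM inclusion cutoff (default 0.1).
#' @param min_iso_tpm,min_iso_frac Isoform prefilter: TPM above
#'   `min_iso_tpm` in at least `min_iso_frac` of samples.
#' @return A data.frame of switch results: `isoform_id`, `gene_id`,
#'   `dIF`, `p_value`, `q_value`, `significant`.
#' @export
test_switch <- function(counts, design, gene_map, condition_pair,
                        dif_cut = 0.05, alpha = 0.05, eps = 0.01,
                        min_gene_tpm = 0.1, min_iso_tpm = 0.1,
                        min_iso_frac = 0.1) {
  for (cond in condition_pair) {
    if (sum(design$condition == cond) < 2L) {
      stop("need >= 2 replicates in condition '", cond,
           "'; run descriptive dIF only via isoform_dif()")
    }
  }
  ift <- isoform_fractions(counts, design, gene_map, min_gene_tpm)
  tpm <- normalize_counts(counts, "TPM")[, design$sample_id, drop = FALSE]
  iso_keep <- rowMeans(tpm > min_iso_tpm) >= min_iso_frac
  gene_keep <- !(ift$gene_map %in% ift$excluded_genes)
  keep <- iso_keep & gene_keep
  dif <- isoform_dif(ift, condition_pair)
  s1 <- design$sample_id[design$condition == condition_pair[1L]]
  s2 <- design$sample_id[design$condition == condition_pair[2L]]
  ids <- rownames(ift$IF)[keep]
  p <- vapply(ids, function(id) {
    welch_logit_p(ift$IF[id, s1], ift$IF[id, s2], eps)
  }, numeric(1))
  res <- dif[match(ids, dif$isoform_id), c("isoform_id", "gene_id", "dIF")]
  res$p_value <- unname(p)
  res$q_value <- bh_fdr(res$p_value)
  res$significant <- !is.na(res$q_value) & res$q_value < alpha &
    abs(res$dIF) > dif_cut
  rownames(res) <- NULL
  res
}

#' Top switching pair (most increased vs most decreased isoform) per gene
#'
#' @param gene_id Gene to inspect.
#' @param switch_results Data.frame from [test_switch()].
#' @return `list(up, down)` of isoform ids, or `NULL` when the gene has
#'   no isoform with positive and negative dIF. Ties are broken by
#'   smaller q value, then lexicographic isoform id (logged).
#' @export
top_switch_pair <- function(gene_id, switch_results) {
  d <- switch_results[switch_results$gene_id == gene_id & !is.na(switch_results$dIF), ]
  if (nrow(d) < 2L) return(NULL)
  if (max(d$dIF) <= 0 || min(d$dIF) >= 0) return(NULL)
  pick <- function(dir) {
    target <- if (dir > 0) max(d$dIF) else min(d$dIF)
    cand <- d[d$dIF == target, ]
    if (nrow(cand) > 1L) {
      cand <- cand[order(cand$q_value, cand$isoform_id), ]
      message("top_switch_pair: dIF tie in ", gene_id, "; keeping ",
              cand$isoform_id[1L])
    }
    cand$isoform_id[1L]
  }
  list(up = pick(1), down = pick(-1))
}

#' Longest-ORF prediction in a nucleotide sequence
#'
#' Scans all reading frames for ATG-initiated open reading frames ending
#' at the first in-frame stop codon; ORFs running off the transcript end
#' without a stop are flagged incomplete. The longest ORF wins, ties go
#' to the most 5' start; `NULL` when the longest ORF is shorter than
#' `min_len` nt.
#'
#' @param seq Nucleotide string over A/C/G/T/N.
#' @param min_len Minimum ORF length in nt, stop codon included
#'   (default 30; 0 disables).
#' @return `list(orf_start, orf_end, protein, incomplete)` (0-based
#'   half-open coordinates including the stop codon) or `NULL`.
#' @export
predict_orf <- function(seq, min_len = 30L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 3L) return(NULL)
  chars <- strsplit(seq, "")[[1L]]
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence must be over A/C/G/T/N")
  }
  codon_at <- function(i) substr(seq, i + 1L, i + 3L)
  best <- NULL
  for (frame in 0:2) {
    starts <- integer(0); open <- FALSE; orf_start <- NA_integer_
    i <- frame
    while (i + 3L <= n) {
      cod <- codon_at(i)
      if (!open && cod == "ATG") { open <- TRUE; orf_start <- i }
      if (open && cod %in% c("TAA", "TAG", "TGA")) {
        len <- i + 3L - orf_start
        if (is.null(best) || len > best$len ||
            (len == best$len && orf_start < best$orf_start)) {
          best <- list(orf_start = orf_start, orf_end = i + 3L, len = len,
                       incomplete = FALSE)
        }
        open <- FALSE
      }
      i <- i + 3L
    }
    if (open) {
      end <- frame + 3L * ((n - frame) %/% 3L)
      len <- end - orf_start
      if (is.null(best) || len > best$len ||
          (len == best$len && orf_start < best$orf_start)) {
        best <- list(orf_start = orf_start, orf_end = end, len = len,
                     incomplete = TRUE)
      }
    }
  }
  if (is.null(best)) return(NULL)
  if (min_len > 0 && best$len < min_len) return(NULL)
  cds <- substr(seq, best$orf_start + 1L, best$orf_end)
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(cds),
                          if.fuzzy.codon = "X")))
  aa <- sub("\\*$", "", aa)
  list(orf_start = best$orf_start, orf_end = best$orf_end,
       protein = aa, incomplete = best$incomplete)
}

#' NMD sensitivity by the 50-nt exon-junction rule
#'
#' TRUE when the stop codon ends more than `rule_nt` nt (transcript
#' coordinates) upstream of the last exon-exon junction — the premature
#' termination codon configuration that recruits nonsense-mediated
#' decay. Mono-exonic transcripts are never NMD-sensitive.
#'
#' @param tx A [transcript_model()].
#' @param orf_end_tx_coord Transcript coordinate just past the stop
#'   codon (as returned by [predict_orf()]).
#' @param rule_nt Distance rule (default 50, strict inequality).
#' @return Logical scalar.
#' @export
nmd_status <- function(tx, orf_end_tx_coord, rule_nt = 50) {
  ex <- tx$exons
  if (nrow(ex) < 2L) return(FALSE)
  lens <- ex[, "end"] - ex[, "start"]
  if (tx$strand == "-") lens <- rev(lens)
  last_junction <- sum(lens[-length(lens)])
  (last_junction - orf_end_tx_coord) > rule_nt
}

#' Functional consequences of an isoform switch pair
#'
#' Compares the most-increased (up) and most-decreased (down) isoform of
#' a gene: 3'UTR length change (stop codon to transcript 3' end), NMD
#' sensitivity gain/loss, domain gain/loss by name, and AS events typed
#' by [detect_events()] (an event whose `isoform_in` is the up isoform
#' is a gain). When an ORF cannot be called on either isoform, the
#' ORF-dependent consequences are skipped with a message.
#'
#' @param up_tx,down_tx [transcript_model()]s of the pair.
#' @param genome A `DNAStringSet`.
#' @param domains Optional data.frame from [read_domains_tsv()].
#' @param utr_min_diff Minimum 3'UTR difference (nt) to report
#'   (default 50).
#' @param min_end_dist Passed to [detect_events()].
#' @return A data.frame: `gene_id`, `up_isoform`, `down_isoform`,
#'   `consequence_type`, `magnitude`.
#' @export
switch_consequences <- function(up_tx, down_tx, genome, domains = NULL,
                                utr_min_diff = 50, min_end_dist = 50) {
  out <- list()
  add <- function(type, mag) {
    out[[length(out) + 1L]] <<- data.frame(
      gene_id = up_tx$gene_id, up_isoform = up_tx$transcript_id,
      down_isoform = down_tx$transcript_id, consequence_type = type,
      magnitude = mag, stringsAsFactors = FALSE)
  }
  orf_up <- predict_orf(transcript_sequence(up_tx, genome))
  orf_down <- predict_orf(transcript_sequence(down_tx, genome))
  if (is.null(orf_up) || is.null(orf_down)) {
    message("ORF missing on one isoform of ", up_tx$gene_id,
            "; restricting to AS-event consequences")
  } else {
    utr_up <- tx_length(up_tx) - orf_up$orf_end
    utr_down <- tx_length(down_tx) - orf_down$orf_end
    if (abs(utr_up - utr_down) >= utr_min_diff) {
      add(if (utr_up < utr_down) "utr3_shorter" else "utr3_longer",
          abs(utr_up - utr_down))
    }
    nmd_up <- nmd_status(up_tx, orf_up$orf_end)
    nmd_down <- nmd_status(down_tx, orf_down$orf_end)
    if (nmd_up && !nmd_down) add("nmd_gain", 1)
    if (!nmd_up && nmd_down) add("nmd_loss", 1)
  }
  if (!is.null(domains) && nrow(domains) > 0L) {
    dcount <- function(id) table(domains$domain_name[domains$isoform_id == id])
    du <- dcount(up_tx$transcript_id); dd <- dcount(down_tx$transcript_id)
    all_names <- union(names(du), names(dd))
    for (nm in all_names) {
      cu <- if (nm %in% names(du)) du[[nm]] else 0L
      cd <- if (nm %in% names(dd)) dd[[nm]] else 0L
      if (cu > cd) add("domain_gain", cu - cd)
      if (cd > cu) add("domain_loss", cd - cu)
    }
  }
  ev <- detect_events(up_tx, down_tx, min_end_dist)
  for (i in seq_len(nrow(ev))) {
    dir <- if (ev$isoform_in[i] == up_tx$transcript_id) "as_gain" else "as_loss"
    add(paste0(dir, ":", ev$event_type[i]), ev$end[i] - ev$start[i])
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(0), up_isoform = character(0),
                      down_isoform = character(0),
                      consequence_type = character(0),
                      magnitude = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enrichment of opposing switch consequences across genes
#'
#' For each opposing consequence pair (shorter vs longer 3'UTR, NMD gain
#' vs loss, domain gain vs loss), counts genes carrying each direction
#' and applies a two-sided exact binomial test against 0.5; BH across
#' pairs.
#'
#' @param consequences Data.frame of pooled [switch_consequences()]
#'   output across genes.
#' @return A data.frame: `pair`, `n_first`, `n_second`, `proportion`,
#'   `p_value`, `q_value`.
#' @export
consequence_enrichment <- function(consequences) {
  pairs <- list(utr3 = c("utr3_shorter", "utr3_longer"),
                nmd = c("nmd_gain", "nmd_loss"),
                domain = c("domain_gain", "domain_loss"))
  rows <- lapply(names(pairs), function(nm) {
    a <- pairs[[nm]][1L]; b <- pairs[[nm]][2L]
    na <- length(unique(consequences$gene_id[consequences$consequence_type == a]))
    nb <- length(unique(consequences$gene_id[consequences$consequence_type == b]))
    if (na + nb == 0L) return(NULL)
    data.frame(pair = paste(a, "vs", b), n_first = na, n_second = nb,
               proportion = na / (na + nb),
               p_value = exact_binomial_p(na, na + nb),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(pair = character(0), n_first = numeric(0),
                      n_second = numeric(0), proportion = numeric(0),
                      p_value = numeric(0), q_value = numeric(0)))
  }
  res <- do.call(rbind, rows)
  res$q_value <- bh_fdr(res$p_value)
  rownames(res) <- NULL
  res
}
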