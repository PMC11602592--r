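#' Detect alternative-splicing events between two isoforms of a gene
#'
#' Pairwise, deterministic typing of the splicing differences between two
#' isoforms on the same gene, chromosome and strand. Event definitions
#' (all spans genomic, labels strand-resolved):
#' \describe{
#'   \item{IR}{an exon of one isoform fully contains an intron of the
#'     other with at least 1 exonic bp on both sides; span = the intron;
#'     `isoform_in` = the retainer.}
#'   \item{ES}{an intron of one isoform fully contains one or more
#'     internal exons of the other; one event per skipped exon; span =
#'     the exon; `isoform_in` = the includer.}
#'   \item{A5/A3}{two junctions share the acceptor (A5) or the donor
#'     (A3) and differ at the other site; span = the interval between
#'     the differing coordinates; `isoform_in` = the isoform in which
#'     the span is exonic.}
#'   \item{aTSS/aTTS}{strand-resolved start/end coordinates differ by at
#'     least `min_end_dist`; span = the interval between the two ends;
#'     `isoform_in` = the isoform extending further.}
#' }
#' A junction pair consumed by IR or ES is not re-reported as A5/A3
#' (precedence IR > ES > A5/A3).
#'
#' @param isoA,isoB [transcript_model()]s from the same gene.
#' @param min_end_dist Minimum end difference (nt) for aTSS/aTTS
#'   (default 50).
#' @return A data.frame with columns `event_type`, `chrom`, `start`,
#'   `end`, `strand`, `isoform_in`, `isoform_out` (0 rows when the
#'   isoforms are identical).
#' @export
detect_events <- function(isoA, isoB, min_end_dist = 50) {
  if (isoA$gene_id != isoB$gene_id || isoA$chrom != isoB$chrom ||
      isoA$strand != isoB$strand) {
    stop("detect_events: isoforms must share gene, chromosome and strand")
  }
  strand <- isoA$strand
  chrom <- isoA$chrom
  ev <- list()
  add <- function(type, s, e, inn, out) {
    ev[[length(ev) + 1L]] <<- data.frame(
      event_type = type, chrom = chrom, start = s, end = e, strand = strand,
      isoform_in = inn, isoform_out = out, stringsAsFactors = FALSE)
  }
  jA <- tx_junctions(isoA); jB <- tx_junctions(isoB)
  kA <- paste(jA[, 1L], jA[, 2L]); kB <- paste(jB[, 1L], jB[, 2L])
  consumedA <- character(0); consumedB <- character(0)

  ir_scan <- function(retainer, spliced, jspliced, kspliced) {
    for (i in seq_len(nrow(jspliced))) {
      s <- jspliced[i, 1L]; e <- jspliced[i, 2L]
      hit <- any(retainer$exons[, "start"] < s & retainer$exons[, "end"] > e)
      if (hit) {
        add("IR", s, e, retainer$transcript_id, spliced$transcript_id)
        if (identical(spliced$transcript_id, isoA$transcript_id)) {
          consumedA <<- c(consumedA, kspliced[i])
        } else {
          consumedB <<- c(consumedB, kspliced[i])
        }
      }
    }
  }
  ir_scan(isoA, isoB, jB, kB)
  ir_scan(isoB, isoA, jA, kA)

  es_scan <- function(skipper, includer, jskip, kskip) {
    exI <- includer$exons
    nI <- nrow(exI)
    jI <- tx_junctions(includer)
    kI <- paste(jI[, 1L], jI[, 2L])
    for (i in seq_len(nrow(jskip))) {
      s <- jskip[i, 1L]; e <- jskip[i, 2L]
      internal <- setdiff(seq_len(nI), c(1L, nI))
      hits <- internal[exI[internal, "start"] >= s & exI[internal, "end"] <= e]
      for (h in hits) {
        add("ES", exI[h, "start"], exI[h, "end"],
            includer$transcript_id, skipper$transcript_id)
        flank <- c(paste(jI[h - 1L, 1L], jI[h - 1L, 2L]),
                   paste(jI[h, 1L], jI[h, 2L]))
        if (identical(skipper$transcript_id, isoA$transcript_id)) {
          consumedA <<- c(consumedA, kskip[i]); consumedB <<- c(consumedB, flank)
        } else {
          consumedB <<- c(consumedB, kskip[i]); consumedA <<- c(consumedA, flank)
        }
      }
    }
  }
  es_scan(isoA, isoB, jA, kA)
  es_scan(isoB, isoA, jB, kB)

  # A5/A3: junction pairs sharing exactly one coordinate, not consumed,
  # not identical in both isoforms
  if (nrow(jA) > 0L && nrow(jB) > 0L) {
    for (i in seq_len(nrow(jA))) {
      if (kA[i] %in% c(consumedA, kB)) next
      for (k in seq_len(nrow(jB))) {
        if (kB[k] %in% c(consumedB, kA)) next
        sameL <- jA[i, 1L] == jB[k, 1L]
        sameR <- jA[i, 2L] == jB[k, 2L]
        if (sameR && !sameL) {
          # left (intron-start) coordinates differ: donor side on '+',
          # acceptor side on '-'
          type <- if (strand == "+") "A5" else "A3"
          lo <- min(jA[i, 1L], jB[k, 1L]); hi <- max(jA[i, 1L], jB[k, 1L])
          inn <- if (jA[i, 1L] > jB[k, 1L]) isoA else isoB
          out <- if (jA[i, 1L] > jB[k, 1L]) isoB else isoA
          add(type, lo, hi, inn$transcript_id, out$transcript_id)
        } else if (sameL && !sameR) {
          type <- if (strand == "+") "A3" else "A5"
          lo <- min(jA[i, 2L], jB[k, 2L]); hi <- max(jA[i, 2L], jB[k, 2L])
          inn <- if (jA[i, 2L] < jB[k, 2L]) isoA else isoB
          out <- if (jA[i, 2L] < jB[k, 2L]) isoB else isoA
          add(type, lo, hi, inn$transcript_id, out$transcript_id)
        }
      }
    }
  }

  # alternative ends (strand-resolved)
  tssA <- tx_tss(isoA); tssB <- tx_tss(isoB)
  if (abs(tssA - tssB) >= min_end_dist) {
    further5 <- if (strand == "+") {
      if (tssA < tssB) isoA else isoB
    } else {
      if (tssA > tssB) isoA else isoB
    }
    other <- if (identical(further5$transcript_id, isoA$transcript_id)) isoB else isoA
    add("aTSS", min(tssA, tssB), max(tssA, tssB),
        further5$transcript_id, other$transcript_id)
  }
  ttsA <- tx_tts(isoA); ttsB <- tx_tts(isoB)
  if (abs(ttsA - ttsB) >= min_end_dist) {
    further3 <- if (strand == "+") {
      if (ttsA > ttsB) isoA else isoB
    } else {
      if (ttsA < ttsB) isoA else isoB
    }
    other <- if (identical(further3$transcript_id, isoA$transcript_id)) isoB else isoA
    add("aTTS", min(ttsA, ttsB), max(ttsA, ttsB),
        further3$transcript_id, other$transcript_id)
  }

  if (length(ev) == 0L) {
    return(data.frame(event_type = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), isoform_in = character(0),
                      isoform_out = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, ev)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Retained introns of an isoform against its gene companions
#'
#' The deduplicated union of IR spans for which `iso` is the retainer
#' against any companion isoform. An isoform is IR-labeled when this
#' list is non-empty.
#'
#' @param iso A [transcript_model()].
#' @param companions List of same-gene [transcript_model()]s.
#' @return A numeric matrix of intron intervals (`start`, `end`), 0 rows
#'   when none.
#' @export
find_retained_introns <- function(iso, companions) {
  spans <- list()
  for (comp in companions) {
    if (comp$gene_id != iso$gene_id) stop("companion from a different gene")
    if (identical(comp$transcript_id, iso$transcript_id)) next
    j <- tx_junctions(comp)
    for (i in seq_len(nrow(j))) {
      s <- j[i, 1L]; e <- j[i, 2L]
      if (any(iso$exons[, "start"] < s & iso$exons[, "end"] > e)) {
        spans[[length(spans) + 1L]] <- c(s, e)
      }
    }
  }
  if (length(spans) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  m <- unique(do.call(rbind, spans))
  m <- m[order(m[, 1L]), , drop = FALSE]
  colnames(m) <- c("start", "end")
  m
}

#' Gain/loss enrichment of AS event types across switching pairs
#'
#' For each (up, down) switching pair, events are detected with
#' [detect_events()]; an event is a gain when `isoform_in` is the up
#' isoform and a loss when it is the down isoform. Per event type, the
#' gain proportion is tested against 0.5 with a two-sided exact binomial
#' test; BH correction across event types.
#'
#' @param switch_pairs List of `list(up = tx, down = tx)` pairs.
#' @param min_end_dist Passed to [detect_events()].
#' @return A data.frame: `event_type`, `gains`, `losses`, `proportion`,
#'   `p_value`, `q_value`.
#' @export
splicing_gain_loss_enrichment <- function(switch_pairs, min_end_dist = 50) {
  if (length(switch_pairs) == 0L) stop("empty switch-pair list")
  tally <- list()
  for (pair in switch_pairs) {
    ev <- detect_events(pair$up, pair$down, min_end_dist)
    if (nrow(ev) == 0L) next
    gain <- ev$isoform_in == pair$up$transcript_id
    for (i in seq_len(nrow(ev))) {
      t <- ev$event_type[i]
      if (is.null(tally[[t]])) tally[[t]] <- c(gain = 0, loss = 0)
      tally[[t]][if (gain[i]) "gain" else "loss"] <-
        tally[[t]][if (gain[i]) "gain" else "loss"] + 1
    }
  }
  if (length(tally) == 0L) {
    return(data.frame(event_type = character(0), gains = numeric(0),
                      losses = numeric(0), proportion = numeric(0),
                      p_value = numeric(0), q_value = numeric(0)))
  }
  types <- sort(names(tally))
  gains <- vapply(tally[types], `[[`, numeric(1), "gain")
  losses <- vapply(tally[types], `[[`, numeric(1), "loss")
  p <- mapply(function(g, n) exact_binomial_p(g, n), gains, gains + losses)
  data.frame(event_type = types, gains = gains, losses = losses,
             proportion = gains / (gains + losses),
             p_value = p, q_value = bh_fdr(p),
             row.names = NULL, stringsAsFactors = FALSE)
}
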