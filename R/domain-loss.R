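#' Map domain transcript coordinates onto the genome
#'
#' Attaches genomic intervals (via [map_tx_to_genome()]) to every domain
#' row for its isoform.
#'
#' @param domains Data.frame from [read_domains_tsv()].
#' @param transcripts Named list of [transcript_model()]s.
#' @return The input data.frame with a `genomic_intervals` list-column.
#' @export
map_domains <- function(domains, transcripts) {
  miss <- setdiff(unique(domains$isoform_id), names(transcripts))
  if (length(miss)) stop("domains on unknown isoforms: ",
                         paste(utils::head(miss), collapse = ", "))
  domains$genomic_intervals <- lapply(seq_len(nrow(domains)), function(i) {
    map_tx_to_genome(transcripts[[domains$isoform_id[i]]],
                     domains$tx_start[i], domains$tx_end[i])
  })
  domains
}

#' Domain presence matrix for one gene (isoform x domain, copy counts)
#'
#' @param gene_id Gene to tabulate.
#' @param transcripts Named list of the gene's [transcript_model()]s.
#' @param domains Domain data.frame (optionally from [map_domains()]).
#' @return An integer matrix, isoforms in rows, domain names in columns.
#' @export
domain_presence <- function(gene_id, transcripts, domains) {
  iso <- names(transcripts)[vapply(transcripts, function(t) t$gene_id == gene_id,
                                   logical(1))]
  d <- domains[domains$isoform_id %in% iso, , drop = FALSE]
  dn <- sort(unique(d$domain_name))
  m <- matrix(0L, nrow = length(iso), ncol = length(dn),
              dimnames = list(iso, dn))
  for (i in seq_len(nrow(d))) {
    m[d$isoform_id[i], d$domain_name[i]] <- m[d$isoform_id[i], d$domain_name[i]] + 1L
  }
  m
}

#' Detect within-gene domain losses between isoform pairs
#'
#' For each ordered pair (bearer, loser) of gene isoforms and each
#' domain name present more often in the bearer, copies are matched
#' greedily by genomic overlap (ties to the leftmost bearer copy);
#' unmatched bearer copies are emitted as one loss event each, carrying
#' the bearer copy's genomic intervals.
#'
#' @param gene_id Gene to inspect.
#' @param transcripts Named list of the gene's [transcript_model()]s
#'   (at least 2 isoforms).
#' @param domains Data.frame from [map_domains()] (must carry
#'   `genomic_intervals`).
#' @return A data.frame of class `domain_loss_table`: `gene_id`,
#'   `bearer_isoform`, `loser_isoform`, `domain_name`, plus list-column
#'   `lost_intervals` and `attributed_types` (filled by
#'   [attribute_loss_to_as()], initially empty).
#' @export
detect_domain_loss <- function(gene_id, transcripts, domains) {
  if (is.null(domains$genomic_intervals)) {
    stop("domains must be mapped with map_domains() first")
  }
  iso <- names(transcripts)[vapply(transcripts, function(t) t$gene_id == gene_id,
                                   logical(1))]
  if (length(iso) < 2L) stop("gene ", gene_id, " has fewer than 2 isoforms")
  d <- domains[domains$isoform_id %in% iso, , drop = FALSE]
  out <- list()
  for (bearer in iso) for (loser in iso) {
    if (bearer == loser) next
    db <- d[d$isoform_id == bearer, , drop = FALSE]
    for (nm in unique(db$domain_name)) {
      bc <- db[db$domain_name == nm, , drop = FALSE]
      lc <- d[d$isoform_id == loser & d$domain_name == nm, , drop = FALSE]
      if (nrow(bc) <= nrow(lc)) next
      # greedy matching of loser copies to bearer copies by overlap
      bearer_left <- vapply(bc$genomic_intervals, function(m) m[1L, 1L], numeric(1))
      bc <- bc[order(bearer_left), , drop = FALSE]
      unmatched <- rep(TRUE, nrow(bc))
      for (k in seq_len(nrow(lc))) {
        ov <- vapply(seq_len(nrow(bc)), function(j) {
          if (!unmatched[j]) return(-1)
          interval_overlap_bp(bc$genomic_intervals[[j]],
                              lc$genomic_intervals[[k]])
        }, numeric(1))
        best <- which(ov == max(ov))[1L]
        if (max(ov) >= 0) unmatched[best] <- FALSE
      }
      for (j in which(unmatched)) {
        out[[length(out) + 1L]] <- list(
          gene_id = gene_id, bearer_isoform = bearer, loser_isoform = loser,
          domain_name = nm, lost_intervals = bc$genomic_intervals[[j]])
      }
    }
  }
  res <- data.frame(
    gene_id = vapply(out, `[[`, "", "gene_id"),
    bearer_isoform = vapply(out, `[[`, "", "bearer_isoform"),
    loser_isoform = vapply(out, `[[`, "", "loser_isoform"),
    domain_name = vapply(out, `[[`, "", "domain_name"),
    stringsAsFactors = FALSE)
  res$lost_intervals <- lapply(out, `[[`, "lost_intervals")
  res$attributed_types <- rep(list(character(0)), nrow(res))
  class(res) <- c("domain_loss_table", "data.frame")
  res
}

#' Attribute domain losses to overlapping AS events
#'
#' For each loss, AS events between loser and bearer are detected and
#' every event type whose span overlaps the lost domain region by at
#' least `min_overlap` bp is recorded. The lost region is taken as the
#' genomic hull of the lost copy's intervals (min start to max end):
#' a domain straddling a spliced-out intron in the bearer maps to exon
#' pieces flanking that intron, and the hull — not the pieces — contains
#' the retained intron that removed it.
#'
#' @param losses A `domain_loss_table` from [detect_domain_loss()].
#' @param transcripts Named list of [transcript_model()]s covering every
#'   bearer and loser.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @param min_end_dist Passed to [detect_events()].
#' @return The table with `attributed_types` filled in.
#' @export
attribute_loss_to_as <- function(losses, transcripts, min_overlap = 1,
                                 min_end_dist = 50) {
  for (i in seq_len(nrow(losses))) {
    loser <- transcripts[[losses$loser_isoform[i]]]
    bearer <- transcripts[[losses$bearer_isoform[i]]]
    if (is.null(loser) || is.null(bearer)) {
      stop("loss ", i, ": isoforms not found in the transcript set")
    }
    if (loser$gene_id != losses$gene_id[i] || bearer$gene_id != losses$gene_id[i]) {
      stop("loss ", i, ": events from a different gene pair")
    }
    ev <- detect_events(loser, bearer, min_end_dist)
    li <- losses$lost_intervals[[i]]
    hull <- matrix(c(min(li[, 1L]), max(li[, 2L])), ncol = 2)
    types <- character(0)
    for (k in seq_len(nrow(ev))) {
      ov <- interval_overlap_bp(hull, matrix(c(ev$start[k], ev$end[k]), ncol = 2))
      if (ov >= min_overlap) types <- union(types, ev$event_type[k])
    }
    losses$attributed_types[[i]] <- types
  }
  losses
}

#' Chi-square comparison of IR vs non-IR domain loss by dIF direction
#'
#' Builds the 2x2 table (IR-attributed vs non-IR-attributed) x (loser
#' dIF above `+dif_threshold` vs below `-dif_threshold`) over attributed
#' losses and applies [chi_square_independence()]. Losses attributed to
#' both IR and a non-IR type count once in the IR row; unattributed
#' losses and losers inside the dIF band are excluded. When several
#' thresholds are given, one test per threshold with BH correction
#' across them.
#'
#' @param losses Attributed `domain_loss_table`.
#' @param loser_dif Named numeric vector: dIF per loser isoform id.
#' @param dif_threshold One or more dIF thresholds (default 0.05).
#' @return A data.frame with one row per threshold: `dif_threshold`,
#'   `statistic`, `df`, `p_value`, `q_value`, and the table cells
#'   `ir_up`, `ir_down`, `nonir_up`, `nonir_down`.
#' @export
domain_loss_by_as_test <- function(losses, loser_dif, dif_threshold = 0.05) {
  rows <- lapply(dif_threshold, function(thr) {
    attributed <- lengths(losses$attributed_types) > 0L
    dif <- loser_dif[losses$loser_isoform]
    up <- !is.na(dif) & dif > thr
    down <- !is.na(dif) & dif < -thr
    is_ir <- vapply(losses$attributed_types, function(t) "IR" %in% t, logical(1))
    tab <- matrix(c(sum(attributed & is_ir & up),
                    sum(attributed & is_ir & down),
                    sum(attributed & !is_ir & up),
                    sum(attributed & !is_ir & down)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("IR", "non-IR"), c("increased", "decreased")))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      stop("zero margin in the domain-loss table:\n",
           paste(utils::capture.output(print(tab)), collapse = "\n"))
    }
    res <- chi_square_independence(tab)
    data.frame(dif_threshold = thr, statistic = res$statistic, df = res$df,
               p_value = res$p_value, ir_up = tab[1, 1], ir_down = tab[1, 2],
               nonir_up = tab[2, 1], nonir_down = tab[2, 2])
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}
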