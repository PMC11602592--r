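# Small builders and independent brute-force oracles used across tests.

tm <- function(id, gene, chrom, strand, starts, ends, ...) {
  transcript_model(id, gene, chrom, strand, starts, ends, ...)
}

toy_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

# --- brute-force per-base transcript->genome map ------------------------
oracle_tx_positions <- function(tx) {
  ex <- tx$exons
  pos <- unlist(lapply(seq_len(nrow(ex)), function(i) {
    seq(ex[i, "start"], ex[i, "end"] - 1)
  }))
  if (tx$strand == "-") pos <- rev(pos)
  pos  # pos[i+1] = genomic coordinate of transcript base i (0-based)
}

# --- brute-force structural-category oracle -----------------------------
# Enumerates reference chains, all their consecutive sub-chains, and the
# strand-resolved site sets; independent of the package's matching code.
oracle_classify <- function(qj, ref_chains, strand) {
  ckey <- function(m) paste(m[, 1L], m[, 2L], sep = "-", collapse = ";")
  full <- vapply(ref_chains, ckey, "")
  subs <- unlist(lapply(ref_chains, function(ch) {
    n <- nrow(ch)
    out <- character(0)
    for (i in seq_len(n)) for (j in i:n) {
      out <- c(out, ckey(ch[i:j, , drop = FALSE]))
    }
    out
  }))
  qkey <- ckey(qj)
  if (qkey %in% full) return("FSM")
  if (qkey %in% subs) return("ISM")
  donors <- unique(unlist(lapply(ref_chains, function(ch) {
    if (strand == "+") ch[, 1L] else ch[, 2L]
  })))
  acceptors <- unique(unlist(lapply(ref_chains, function(ch) {
    if (strand == "+") ch[, 2L] else ch[, 1L]
  })))
  qd <- if (strand == "+") qj[, 1L] else qj[, 2L]
  qa <- if (strand == "+") qj[, 2L] else qj[, 1L]
  if (!all(qd %in% donors) || !all(qa %in% acceptors)) return("NNC")
  "NIC"
}

# build exons spanning a junction chain (with terminal overhangs)
exons_from_chain <- function(chain, overhang = 20) {
  k <- nrow(chain)
  starts <- c(chain[1L, 1L] - overhang, chain[, 2L])
  ends <- c(chain[, 1L], chain[k, 2L] + overhang)
  list(starts = starts, ends = ends)
}

# random junction chain over a coordinate pool (sorted distinct sites)
random_chain <- function(pool, k) {
  sites <- sort(sample(pool, 2L * k))
  cbind(start = sites[seq(1L, 2L * k, by = 2L)],
        end = sites[seq(2L, 2L * k, by = 2L)])
}

# --- exon-membership difference oracle for AS events --------------------
exon_membership <- function(tx, lo, hi) {
  v <- logical(hi - lo)
  for (i in seq_len(nrow(tx$exons))) {
    a <- max(tx$exons[i, "start"], lo); b <- min(tx$exons[i, "end"], hi)
    if (a < b) v[(a - lo + 1):(b - lo)] <- TRUE
  }
  v
}

# --- sliding-window motif-match oracle ----------------------------------
oracle_scan <- function(seq, iupac) {
  classes <- c(A = "A", C = "C", G = "G", T = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
  s <- strsplit(toupper(seq), "")[[1L]]
  m <- strsplit(toupper(iupac), "")[[1L]]
  k <- length(m); n <- length(s)
  hits <- integer(0)
  for (p in seq_len(max(0, n - k + 1L))) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!s[p + j - 1L] %in% strsplit(classes[[m[j]]], "")[[1L]]) {
        ok <- FALSE; break
      }
    }
    if (ok) hits <- c(hits, p - 1L)
  }
  hits
}

# --- independent BH step-up ---------------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m); out[o] <- q
  out
}

# reflect a transcript about coordinate C and flip strand
reflect_tx <- function(tx, C) {
  transcript_model(tx$transcript_id, tx$gene_id, tx$chrom,
                   if (tx$strand == "+") "-" else "+",
                   C - tx$exons[, "end"], C - tx$exons[, "start"],
                   category = tx$category)
}

# sorted canonical event key for comparing event tables
event_keys <- function(ev) {
  sort(paste(ev$event_type, ev$start, ev$end, ev$isoform_in, ev$isoform_out))
}

# standard small synthetic run shared by a few tests
small_sim <- function(seed = 99, n_genes = 30, ...) {
  cfg <- generator_config(seed = seed, n_genes = n_genes, ...)
  ann <- generate_annotation(cfg)
  sim <- simulate_counts(ann)
  list(cfg = cfg, ann = ann, sim = sim,
       gene_map = stats::setNames(ann$truth$isoforms$gene_id,
                                  ann$truth$isoforms$transcript_id),
       ir_labels = stats::setNames(ann$truth$isoforms$ir_label,
                                   ann$truth$isoforms$transcript_id))
}
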