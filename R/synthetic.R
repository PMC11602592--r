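#' Configuration for the synthetic-data generator
#'
#' The defaults emulate the study conditions the analysis assumes: a
#' three-point time course (0/24/72 h) with 4 replicates per condition,
#' 200 multi-isoform genes, one planted isoform per structural category
#' per gene, Dirichlet-multinomial counts, a STAT1-like intron-retention
#' time course (aggregated IR fraction 0.19 / 0.27 / 0.34), switch dIF
#' magnitudes of 0.2-0.35, a 2x motif-density excess in retained
#' introns, and splicing-factor expression rank-correlated at -0.95 with
#' IR isoform expression.
#'
#' @param seed Mandatory RNG seed.
#' @param n_genes Number of genes.
#' @param n_exons_range Range of backbone exon counts (min >= 6; the
#'   per-category isoform constructions need that much internal
#'   structure).
#' @param exon_len_range,intron_len_range Exon/intron length ranges (bp).
#' @param flank Flanking sequence per contig end (bp).
#' @param n_replicates Replicates per condition.
#' @param timepoints Timepoints in hours (conditions are `h<t>`).
#' @param library_size Reads per sample.
#' @param dispersion Dirichlet concentration of isoform fractions.
#' @param fraction_switch_genes,dif_range Fraction of genes with a
#'   planted switch and the planted |dIF| range.
#' @param fraction_ir_genes Fraction of genes carrying an IR isoform.
#' @param ir_profile Aggregated IR fractions at the time course of an
#'   increasing-profile gene.
#' @param ir_profile_props Proportions of increasing / flat / decreasing
#'   IR profiles among IR genes.
#' @param fraction_intra_priming Fraction of genes whose ISM isoform is
#'   planted with an A-rich downstream window.
#' @param fraction_rescue Fraction of genes whose reference (and FSM)
#'   carries a non-canonical, unsupported junction.
#' @param fraction_unsupported_nnc Fraction of genes whose NNC novel
#'   junction is non-canonical and forced below the support threshold.
#' @param sj_mean_support Poisson mean of unique-read junction support.
#' @param motif,motif_intron_density,motif_density_ratio,motif_exon_density,motif_exon_ratio
#'   Motif consensus and planted densities (sites/bp): IR introns get
#'   `motif_intron_density`, other introns that divided by
#'   `motif_density_ratio`; non-IR exons get `motif_exon_density`, IR
#'   exons that times `motif_exon_ratio`.
#' @param factor_rho,n_factors,n_null_factors Planted Spearman
#'   correlation of splicing-factor expression with IR isoform
#'   expression; numbers of correlated and independent factors.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_genes = 200L,
                             n_exons_range = c(6L, 9L),
                             exon_len_range = c(90L, 250L),
                             intron_len_range = c(150L, 400L),
                             flank = 300L,
                             n_replicates = 4L,
                             timepoints = c(0, 24, 72),
                             library_size = 3e5,
                             dispersion = 100,
                             fraction_switch_genes = 0.3,
                             dif_range = c(0.2, 0.35),
                             fraction_ir_genes = 0.3,
                             ir_profile = c(0.19, 0.27, 0.34),
                             ir_profile_props = c(increasing = 0.6,
                                                  flat = 0.3,
                                                  decreasing = 0.1),
                             fraction_intra_priming = 0.15,
                             fraction_rescue = 0.15,
                             fraction_unsupported_nnc = 0.5,
                             sj_mean_support = 30,
                             motif = "GGAGGA",
                             motif_intron_density = 0.02,
                             motif_density_ratio = 2,
                             motif_exon_density = 0.01,
                             motif_exon_ratio = 0.5,
                             factor_rho = -0.95,
                             n_factors = 4L,
                             n_null_factors = 4L) {
  if (missing(seed)) stop("seed is mandatory")
  fr <- c(fraction_switch_genes, fraction_ir_genes, fraction_intra_priming,
          fraction_rescue, fraction_unsupported_nnc)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (fraction_switch_genes + fraction_ir_genes > 1) {
    stop("switch and IR gene fractions overlap (sum > 1)")
  }
  if (n_exons_range[1L] < 6L) {
    stop("config infeasible: the category constructions need >= 6 exons")
  }
  if (length(timepoints) < 2L) stop("need >= 2 timepoints")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed %% .Machine$integer.max)
  structure(cfg, class = "generator_config")
}

# write characters into a contig character vector
.poke <- function(chars, start0, s) {
  v <- strsplit(s, "")[[1L]]
  chars[(start0 + 1L):(start0 + length(v))] <- v
  chars
}

# canonical / non-canonical intron boundary dinucleotides (sense-resolved)
.write_boundary <- function(chars, s, e, strand, canonical = TRUE) {
  if (strand == "+") {
    chars <- .poke(chars, s, if (canonical) "GT" else "GG")
    chars <- .poke(chars, e - 2L, "AG")
  } else {
    chars <- .poke(chars, s, "CT")                       # sense acceptor AG
    chars <- .poke(chars, e - 2L, if (canonical) "AC" else "CC")  # sense donor
  }
  chars
}

#' Generate a synthetic annotation with planted structural categories
#'
#' Per gene, a multi-exon backbone defines one reference transcript; the
#' query isoforms are built by rule to realise each structural category:
#' an FSM (copy), an ISM (the 5'-most exon dropped, a consecutive
#' junction sub-chain), a NIC (one internal exon skipped — a novel
#' combination of known sites), an NNC (one donor shifted 6 nt into the
#' intron — a novel site), and in IR genes an IR isoform (one intron
#' merged into its flanking exons, itself a NIC by sites). The genome is
#' random sequence with canonical GT..AG dinucleotides written at every
#' junction except where a non-canonical junction is planted; A-rich
#' intra-priming windows, rescue-gene non-canonical reference junctions
#' and binned motif occurrences are planted per the config, and
#' everything is recorded in the truth tables.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_annotation`: `reference`,
#'   `queries` (lists of [transcript_model()]), `genome`
#'   (`DNAStringSet`) and `truth` (list of data.frames / vectors).
#' @export
generate_annotation <- function(config) {
  set.seed(config$seed)
  n_sw <- round(config$fraction_switch_genes * config$n_genes)
  n_ir <- round(config$fraction_ir_genes * config$n_genes)
  roles <- c(rep("switch", n_sw), rep("ir", n_ir),
             rep("null", config$n_genes - n_sw - n_ir))
  pr <- config$ir_profile_props / sum(config$ir_profile_props)
  n_inc <- round(pr[["increasing"]] * n_ir)
  n_dec <- round(pr[["decreasing"]] * n_ir)
  ir_profiles <- c(rep("increasing", n_inc),
                   rep("flat", n_ir - n_inc - n_dec),
                   rep("decreasing", n_dec))
  ip_genes <- stats::runif(config$n_genes) < config$fraction_intra_priming
  rescue_genes <- stats::runif(config$n_genes) < config$fraction_rescue
  unsupported_nnc <- stats::runif(config$n_genes) < config$fraction_unsupported_nnc

  reference <- list(); queries <- list()
  genome_chars <- list()
  iso_rows <- list(); gene_rows <- list()
  ir_intron_rows <- list(); forced_junctions <- list()
  motif_regions <- list()      # for later density planting
  protected_windows <- list()  # planted A-rich windows; keep motif-free

  for (g in seq_len(config$n_genes)) {
    gene_id <- sprintf("G%04d", g)
    chrom <- sprintf("chr%04d", g)
    strand <- if (g %% 2L == 1L) "+" else "-"
    role <- roles[g]
    n_ex <- sample(config$n_exons_range[1L]:config$n_exons_range[2L], 1L)
    elen <- sample(config$exon_len_range[1L]:config$exon_len_range[2L], n_ex,
                   replace = TRUE)
    ilen <- sample(config$intron_len_range[1L]:config$intron_len_range[2L],
                   n_ex - 1L, replace = TRUE)
    starts <- numeric(n_ex); ends <- numeric(n_ex)
    pos <- config$flank
    for (i in seq_len(n_ex)) {
      starts[i] <- pos; ends[i] <- pos + elen[i]
      pos <- ends[i] + if (i < n_ex) ilen[i] else config$flank
    }
    contig_len <- pos
    # planted structural indices: IR intron r=2, skipped exon s=4,
    # NNC-shifted junction t = n_ex - 2
    r <- 2L; s_ex <- 4L; t_j <- n_ex - 2L

    mk <- function(suffix, st, en, category) {
      transcript_model(paste0(gene_id, ".", suffix), gene_id, chrom, strand,
                       st, en, category = "unclassified")
    }
    ref_tx <- mk("ref", starts, ends, "unclassified")
    fsm <- mk("FSM", starts, ends, "unclassified")
    # ISM: drop the strand-resolved 5'-most exon
    if (strand == "+") { ism_idx <- 2:n_ex } else { ism_idx <- 1:(n_ex - 1L) }
    ism_st <- starts[ism_idx]; ism_en <- ends[ism_idx]
    ip_window <- NULL
    if (ip_genes[g]) {
      # truncate the ISM 3'-terminal exon and plant the A-rich window
      if (strand == "+") {
        k <- length(ism_en)
        ism_en[k] <- ism_st[k] + floor((ism_en[k] - ism_st[k]) / 2)
        ip_window <- c(ism_en[k], ism_en[k] + 20L, 1L)  # A-rich on +
      } else {
        ism_st[1L] <- ism_st[1L] + floor((ism_en[1L] - ism_st[1L]) / 2)
        ip_window <- c(ism_st[1L] - 20L, ism_st[1L], 0L)  # T-rich on + (A on -)
      }
    }
    ism <- mk("ISM", ism_st, ism_en, "unclassified")
    nic <- mk("NIC", starts[-s_ex], ends[-s_ex], "unclassified")
    nnc_en <- ends; nnc_en[t_j] <- ends[t_j] + 6L
    nnc <- mk("NNC", starts, nnc_en, "unclassified")
    gene_queries <- list(fsm, ism, nic, nnc)
    has_ir <- role == "ir"
    if (has_ir) {
      ir_st <- c(starts[seq_len(r - 1L)], starts[r], starts[(r + 2L):n_ex])
      ir_en <- c(ends[seq_len(r - 1L)], ends[r + 1L], ends[(r + 2L):n_ex])
      gene_queries[[5L]] <- mk("IR", ir_st, ir_en, "unclassified")
      ir_intron_rows[[length(ir_intron_rows) + 1L]] <- data.frame(
        gene_id = gene_id, chrom = chrom, start = ends[r], end = starts[r + 1L],
        strand = strand, stringsAsFactors = FALSE)
    }

    # contig sequence
    chars <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)
    # neutral downstream-of-TTS window at the shared 3' end (keeps the
    # intra-priming filter quiet for non-planted isoforms)
    neutral <- paste(rep("GTC", 7L), collapse = "")
    if (strand == "+") {
      chars <- .poke(chars, ends[n_ex], substr(neutral, 1L, 20L))
    } else {
      chars <- .poke(chars, starts[1L] - 20L, substr(neutral, 1L, 20L))
    }
    if (!is.null(ip_window)) {
      fill <- if (ip_window[3L] == 1L) "A" else "T"
      chars[(ip_window[1L] + 1L):(ip_window[2L])] <- fill
      protected_windows[[length(protected_windows) + 1L]] <- data.frame(
        chrom = chrom, start = ip_window[1L], end = ip_window[2L])
    }
    # canonical boundaries at every backbone junction
    for (i in seq_len(n_ex - 1L)) {
      canonical <- !(rescue_genes[g] && i == 1L)
      chars <- .write_boundary(chars, ends[i], starts[i + 1L], strand, canonical)
    }
    # NNC novel donor boundary 6 nt into intron t
    chars <- .write_boundary(chars, ends[t_j] + 6L, starts[t_j + 1L], strand,
                             canonical = !unsupported_nnc[g])
    genome_chars[[chrom]] <- chars

    # forced-unsupported junctions
    if (unsupported_nnc[g]) {
      forced_junctions[[length(forced_junctions) + 1L]] <- data.frame(
        chrom = chrom, start = ends[t_j] + 6L, end = starts[t_j + 1L],
        reason = "nnc", stringsAsFactors = FALSE)
    }
    if (rescue_genes[g]) {
      forced_junctions[[length(forced_junctions) + 1L]] <- data.frame(
        chrom = chrom, start = ends[1L], end = starts[2L],
        reason = "rescue", stringsAsFactors = FALSE)
    }

    # regions for motif planting (backbone exons/introns)
    for (i in seq_len(n_ex - 1L)) {
      motif_regions[[length(motif_regions) + 1L]] <- data.frame(
        chrom = chrom, start = ends[i], end = starts[i + 1L], strand = strand,
        kind = if (has_ir && i == r) "IR_intron" else "nonIR_intron",
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_ex)) {
      motif_regions[[length(motif_regions) + 1L]] <- data.frame(
        chrom = chrom, start = starts[i], end = ends[i], strand = strand,
        kind = if (has_ir && i %in% c(r, r + 1L)) "IR_exon" else "nonIR_exon",
        stringsAsFactors = FALSE)
    }

    reference[[ref_tx$transcript_id]] <- ref_tx
    for (q in gene_queries) queries[[q$transcript_id]] <- q
    cat_expected <- c("FSM", "ISM", "NIC", "NNC", if (has_ir) "NIC")
    roles_q <- c("FSM", "ISM", "NIC", "NNC", if (has_ir) "IR")
    iso_rows[[g]] <- data.frame(
      transcript_id = vapply(gene_queries, `[[`, "", "transcript_id"),
      gene_id = gene_id, planted_role = roles_q,
      expected_category = cat_expected,
      ir_label = roles_q == "IR",
      intra_priming = ip_genes[g] & roles_q == "ISM",
      removed_nc = unsupported_nnc[g] & roles_q == "NNC",
      rescued = rescue_genes[g] & roles_q == "FSM",
      stringsAsFactors = FALSE)
    gene_rows[[g]] <- data.frame(
      gene_id = gene_id, role = role, chrom = chrom, strand = strand,
      n_exons = n_ex,
      ir_profile = if (has_ir) ir_profiles[g - n_sw] else NA_character_,
      stringsAsFactors = FALSE)
  }

  genes_df <- do.call(rbind, gene_rows)
  isoforms_df <- do.call(rbind, iso_rows)
  rownames(genes_df) <- rownames(isoforms_df) <- NULL

  # plant motif occurrences at class-specific densities
  dens <- c(IR_intron = config$motif_intron_density,
            nonIR_intron = config$motif_intron_density / config$motif_density_ratio,
            nonIR_exon = config$motif_exon_density,
            IR_exon = config$motif_exon_density * config$motif_exon_ratio)
  k <- nchar(config$motif)
  regions_df <- do.call(rbind, motif_regions)
  prot <- if (length(protected_windows)) do.call(rbind, protected_windows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  for (i in seq_len(nrow(regions_df))) {
    reg <- regions_df[i, ]
    lo <- reg$start + 10L; hi <- reg$end - 10L - k
    if (hi <= lo) next
    grid <- seq(lo, hi, by = k)
    pw <- prot[prot$chrom == reg$chrom, , drop = FALSE]
    if (nrow(pw)) {
      clash <- vapply(grid, function(p) {
        any(p < pw$end & p + k > pw$start)
      }, logical(1))
      grid <- grid[!clash]
    }
    if (length(grid) == 0L) next
    n_sites <- stats::rpois(1L, (hi - lo) * dens[[reg$kind]])
    n_sites <- min(n_sites, length(grid))
    if (n_sites == 0L) next
    at <- sample(grid, n_sites)
    # write in the region's sense orientation so the sense-strand scan
    # sees the planted consensus
    instance <- if (reg$strand == "+") config$motif else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(config$motif)))
    ch <- genome_chars[[reg$chrom]]
    for (p in at) ch <- .poke(ch, p, instance)
    genome_chars[[reg$chrom]] <- ch
  }

  genome <- Biostrings::DNAStringSet(
    vapply(genome_chars, paste, "", collapse = ""))
  names(genome) <- names(genome_chars)

  truth <- list(
    genes = genes_df, isoforms = isoforms_df,
    ir_introns = if (length(ir_intron_rows)) do.call(rbind, ir_intron_rows) else
      data.frame(gene_id = character(0), chrom = character(0),
                 start = numeric(0), end = numeric(0), strand = character(0)),
    forced_junctions = if (length(forced_junctions))
      do.call(rbind, forced_junctions) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 reason = character(0)),
    motif = data.frame(name = "SRSF_like", iupac = config$motif,
                       stringsAsFactors = FALSE),
    motif_densities = dens)
  structure(list(reference = reference, queries = queries, genome = genome,
                 truth = truth, config = config),
            class = "synthetic_annotation")
}

#' Simulate Dirichlet-multinomial isoform counts with planted switches
#'
#' Per sample, gene totals are a multinomial share of the library size
#' proportional to lognormal gene expression levels; isoform counts are
#' Dirichlet-multinomial around the planted per-condition isoform
#' fractions with concentration `dispersion`. Switch genes interpolate
#' linearly between base and shifted fractions over the time course; IR
#' genes follow the configured aggregated-IR profile.
#'
#' @param ann A `synthetic_annotation`.
#' @return A list: `counts` ([count_matrix()]), `design`
#'   ([sample_design()]), `truth_if` (isoform x condition planted
#'   fractions), `truth_dif` (planted dIF between the first and last
#'   condition).
#' @export
simulate_counts <- function(ann) {
  cfg <- ann$config
  set.seed(cfg$seed + 1L)
  tps <- cfg$timepoints
  conds <- paste0("h", tps)
  n_t <- length(tps)
  design <- sample_design(
    sample_id = as.vector(t(outer(conds, seq_len(cfg$n_replicates),
                                  function(c, r) sprintf("s_%s_r%d", c, r)))),
    condition = rep(conds, each = cfg$n_replicates),
    timepoint_h = rep(tps, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), times = n_t))

  genes <- ann$truth$genes
  isoforms <- ann$truth$isoforms
  iso_ids <- isoforms$transcript_id
  # planted per-condition IF per gene
  truth_if <- matrix(NA_real_, nrow = length(iso_ids), ncol = n_t,
                     dimnames = list(iso_ids, conds))
  sw_count <- 0L
  for (gi in seq_len(nrow(genes))) {
    gene_id <- genes$gene_id[gi]
    iso <- isoforms[isoforms$gene_id == gene_id, ]
    k <- nrow(iso)
    role <- genes$role[gi]
    if (role == "switch") {
      sw_count <- sw_count + 1L
      up_role <- if (sw_count %% 2L == 0L) "NIC" else "FSM"
      down_role <- if (up_role == "NIC") "FSM" else "NIC"
      delta <- stats::runif(1L, cfg$dif_range[1L], cfg$dif_range[2L])
      b_up <- 0.10 + stats::runif(1L, 0, 0.1)
      b_down <- delta + 0.10 + stats::runif(1L, 0, 0.1)
      rest <- which(!iso$planted_role %in% c(up_role, down_role))
      w <- stats::rgamma(length(rest), 4, 1); w <- w / sum(w)
      base <- numeric(k)
      base[iso$planted_role == up_role] <- b_up
      base[iso$planted_role == down_role] <- b_down
      base[rest] <- (1 - b_up - b_down) * w
      final <- base
      final[iso$planted_role == up_role] <- b_up + delta
      final[iso$planted_role == down_role] <- b_down - delta
      for (t in seq_len(n_t)) {
        f <- (t - 1) / (n_t - 1)
        truth_if[iso$transcript_id, t] <- (1 - f) * base + f * final
      }
    } else if (role == "ir") {
      prof <- genes$ir_profile[gi]
      p3 <- switch(prof,
                   increasing = cfg$ir_profile,
                   flat = rep(cfg$ir_profile[1L], 3L),
                   decreasing = rev(cfg$ir_profile))
      # interpolate the 3-point profile onto however many timepoints
      pp <- stats::approx(seq_len(3L), p3,
                          xout = seq(1, 3, length.out = n_t))$y
      others <- which(iso$planted_role != "IR")
      w <- stats::rgamma(length(others), 4, 1); w <- w / sum(w)
      for (t in seq_len(n_t)) {
        v <- numeric(k)
        v[iso$planted_role == "IR"] <- pp[t]
        v[others] <- (1 - pp[t]) * w
        truth_if[iso$transcript_id, t] <- v
      }
    } else {
      w <- stats::rgamma(k, 4, 1); w <- w / sum(w)
      truth_if[iso$transcript_id, ] <- w
    }
  }

  gene_levels <- stats::rlnorm(nrow(genes), 0, 0.5)
  names(gene_levels) <- genes$gene_id
  counts <- matrix(0, nrow = length(iso_ids), ncol = nrow(design),
                   dimnames = list(iso_ids, design$sample_id))
  for (s in seq_len(nrow(design))) {
    tot <- stats::rmultinom(1L, cfg$library_size, gene_levels)[, 1L]
    cond <- design$condition[s]
    for (gi in seq_len(nrow(genes))) {
      gene_id <- genes$gene_id[gi]
      n_g <- tot[gene_id]
      iso <- isoforms$transcript_id[isoforms$gene_id == gene_id]
      if (n_g == 0) next
      alpha <- cfg$dispersion * truth_if[iso, cond]
      gam <- ifelse(alpha > 0, stats::rgamma(length(alpha), alpha, 1), 0)
      if (sum(gam) == 0) next
      counts[iso, s] <- stats::rmultinom(1L, n_g, gam / sum(gam))[, 1L]
    }
  }
  lens <- vapply(ann$queries[iso_ids], tx_length, numeric(1))
  truth_dif <- truth_if[, n_t] - truth_if[, 1L]
  list(counts = count_matrix(counts, lens), design = design,
       truth_if = truth_if, truth_dif = truth_dif)
}

#' Simulate a junction-support table
#'
#' Every junction of the reference and query transcripts receives
#' Poisson unique-read support per sample; the planted unsupported
#' junctions (non-canonical NNC junctions and rescue-gene reference
#' junctions) are forced below 3 reads in every sample.
#'
#' @param ann A `synthetic_annotation`.
#' @param design A [sample_design()] data.frame.
#' @return A combined junction-support data.frame (see
#'   [read_sj_table()]).
#' @export
simulate_junction_support <- function(ann, design) {
  cfg <- ann$config
  set.seed(cfg$seed + 2L)
  jx <- list()
  for (tx in c(ann$reference, ann$queries)) {
    j <- tx_junctions(tx)
    for (i in seq_len(nrow(j))) {
      jx[[length(jx) + 1L]] <- data.frame(
        chrom = tx$chrom, start = j[i, 1L], end = j[i, 2L],
        strand = tx$strand, stringsAsFactors = FALSE)
    }
  }
  jx <- unique(do.call(rbind, jx))
  forced <- ann$truth$forced_junctions
  fkey <- paste0(forced$chrom, ":", forced$start, "-", forced$end)
  key <- paste0(jx$chrom, ":", jx$start, "-", jx$end)
  out <- lapply(design$sample_id, function(smp) {
    u <- stats::rpois(nrow(jx), cfg$sj_mean_support)
    u[key %in% fkey] <- sample(0:2, sum(key %in% fkey), replace = TRUE)
    data.frame(chrom = jx$chrom, start = jx$start, end = jx$end,
               strand = jx$strand, unique_reads = u,
               multi_reads = stats::rpois(nrow(jx), 2),
               sample_id = smp, stringsAsFactors = FALSE)
  })
  combine_sj_tables(out)
}

#' Plant protein domains, motif definitions and factor expression
#'
#' Domains are written so the derived losses are attributable by
#' construction: in IR genes a 60-nt domain straddles the retained
#' intron's junction in every spliced isoform (its genomic hull covers
#' the intron; the IR isoform lacks it), and in every gene a domain sits
#' inside the skipped exon (absent from the NIC isoform). Splicing
#' factor expression is generated by a Gaussian copula with rank
#' correlation `factor_rho` against the log2(CPM+1) expression of the
#' IR isoforms of increasing-profile genes, plus independent null
#' factors.
#'
#' @param ann A `synthetic_annotation`.
#' @param counts_sim Output of [simulate_counts()].
#' @return A list: `domains` (data.frame), `motifs` (data.frame of
#'   definitions), `factor_expr` (factors x samples matrix),
#'   `domain_truth` (planted loss records), `factor_truth`.
#' @export
plant_domains_and_motifs <- function(ann, counts_sim) {
  cfg <- ann$config
  set.seed(cfg$seed + 3L)
  genes <- ann$truth$genes
  isoforms <- ann$truth$isoforms
  dom_rows <- list(); truth_rows <- list()
  for (gi in seq_len(nrow(genes))) {
    gene_id <- genes$gene_id[gi]
    iso <- isoforms[isoforms$gene_id == gene_id, ]
    fsm <- ann$queries[[iso$transcript_id[iso$planted_role == "FSM"]]]
    ex <- fsm$exons
    # ES domain inside the skipped exon (exon 4 of the backbone)
    es_piece <- c(ex[4L, "start"] + 10, ex[4L, "end"] - 10)
    es_bearers <- iso$transcript_id[iso$planted_role != "NIC"]
    for (b in es_bearers) {
      tx <- ann$queries[[b]]
      a <- map_genome_to_tx(tx, es_piece[1L])
      b2 <- map_genome_to_tx(tx, es_piece[2L] - 1)
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        isoform_id = b, domain_name = paste0("DomES_", gene_id),
        tx_start = min(a, b2), tx_end = max(a, b2) + 1,
        stringsAsFactors = FALSE)
    }
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      gene_id = gene_id, domain_name = paste0("DomES_", gene_id),
      loser_isoform = iso$transcript_id[iso$planted_role == "NIC"],
      planted_type = "ES", stringsAsFactors = FALSE)
    if (genes$role[gi] == "ir") {
      # domain straddling the retained intron (junction 2)
      left <- c(ex[2L, "end"] - 30, ex[2L, "end"])
      right <- c(ex[3L, "start"], ex[3L, "start"] + 30)
      ir_bearers <- iso$transcript_id[iso$planted_role != "IR"]
      for (b in ir_bearers) {
        tx <- ann$queries[[b]]
        a <- map_genome_to_tx(tx, left[1L])
        b2 <- map_genome_to_tx(tx, right[2L] - 1)
        dom_rows[[length(dom_rows) + 1L]] <- data.frame(
          isoform_id = b, domain_name = paste0("DomIR_", gene_id),
          tx_start = min(a, b2), tx_end = max(a, b2) + 1,
          stringsAsFactors = FALSE)
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        gene_id = gene_id, domain_name = paste0("DomIR_", gene_id),
        loser_isoform = iso$transcript_id[iso$planted_role == "IR"],
        planted_type = "IR", stringsAsFactors = FALSE)
    }
  }
  domains <- do.call(rbind, dom_rows); rownames(domains) <- NULL
  domain_truth <- do.call(rbind, truth_rows); rownames(domain_truth) <- NULL

  # factor expression via Gaussian copula against IR isoform expression
  lc <- log_cpm(counts_sim$counts)
  inc_genes <- genes$gene_id[genes$role == "ir" &
                               genes$ir_profile == "increasing"]
  targets <- isoforms$transcript_id[isoforms$gene_id %in% inc_genes &
                                      isoforms$planted_role == "IR"]
  n_smp <- ncol(lc)
  rho_n <- 2 * sin(pi * cfg$factor_rho / 6)  # normal corr for target Spearman
  fac_rows <- list(); fac_truth <- list()
  n_use <- min(cfg$n_factors, length(targets))
  for (f in seq_len(n_use)) {
    target <- targets[f]
    x <- lc[target, ]
    z <- stats::qnorm((rank(x, ties.method = "average") - 0.5) / n_smp)
    z <- (z - mean(z)) / stats::sd(z)
    e <- stats::rnorm(n_smp)
    e <- stats::residuals(stats::lm(e ~ z))
    e <- (e - mean(e)) / stats::sd(e)
    # sample correlation of (z, zf) is exactly rho_n by construction
    zf <- rho_n * z + sqrt(1 - rho_n^2) * e
    fac_rows[[sprintf("SFcor%02d", f)]] <- 8 + 1.5 * zf
    fac_truth[[f]] <- data.frame(factor_gene = sprintf("SFcor%02d", f),
                                 target_isoform = target,
                                 rho = cfg$factor_rho,
                                 stringsAsFactors = FALSE)
  }
  for (f in seq_len(cfg$n_null_factors)) {
    fac_rows[[sprintf("SFnull%02d", f)]] <- stats::rnorm(n_smp, 8, 1.5)
  }
  factor_expr <- do.call(rbind, fac_rows)
  colnames(factor_expr) <- colnames(lc)
  list(domains = domains, motifs = ann$truth$motif,
       factor_expr = factor_expr, domain_truth = domain_truth,
       factor_truth = if (length(fac_truth)) do.call(rbind, fac_truth) else
         data.frame(factor_gene = character(0), target_isoform = character(0),
                    rho = numeric(0)))
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits reference.gtf, query.gtf, genome.fa, counts.tsv, design.tsv,
#' per-sample sj_<sample>.tsv, domains.tsv, motifs.tsv, factors.tsv and
#' truth/*.tsv. Identical config and seed give byte-identical files.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixtures <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  ann <- generate_annotation(config)
  sim <- simulate_counts(ann)
  sj <- simulate_junction_support(ann, sim$design)
  dm <- plant_domains_and_motifs(ann, sim)
  write_gtf(ann$reference, file.path(dir, "reference.gtf"))
  write_gtf(ann$queries, file.path(dir, "query.gtf"))
  Biostrings::writeXStringSet(ann$genome, file.path(dir, "genome.fa"))
  cm <- data.frame(isoform_id = rownames(sim$counts$counts),
                   length = unname(sim$counts$isoform_lengths),
                   sim$counts$counts, check.names = FALSE)
  utils::write.table(cm, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (smp in unique(sj$sample_id)) {
    write_sj_table(sj[sj$sample_id == smp, ],
                   file.path(dir, paste0("sj_", smp, ".tsv")))
  }
  utils::write.table(dm$domains, file.path(dir, "domains.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dm$motifs, file.path(dir, "motifs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fx <- data.frame(factor_gene = rownames(dm$factor_expr), dm$factor_expr,
                   check.names = FALSE)
  utils::write.table(fx, file.path(dir, "factors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ann$truth$genes, file.path(dir, "truth", "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ann$truth$isoforms,
                     file.path(dir, "truth", "isoforms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dm$domain_truth,
                     file.path(dir, "truth", "domain_losses.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
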