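DEFAULT_COMPOUNDS <- data.frame(
  compound = c("geraniol", "nerol", "neral", "geranyl_acetate",
               "neryl_acetate", "citronellyl_acetate", "citral", "beta_pinene",
               "beta_copaene", "trans_beta_ocimene", "dihydro_beta_ionone",
               "dihydro_beta_ionol", "trans_beta_ionone", "aromandendrene",
               "phenethyl_alcohol", "phenethyl_acetate", "DMT",
               "methyleugenol", "hexenol_acetate",
               "nonane", "decanal"),
  class = c(rep("terpenoid", 14),
            rep("phenylpropanoid_benzenoid", 4),
            "fatty_acid_derivative",
            "non_scent", "non_scent"),
  stringsAsFactors = FALSE
)

#' Simulation configuration
#'
#' Defines the study design the generator emulates: one annotated
#' chromosome with multi-exon coding genes and housekeeping ncRNAs; planted
#' lncRNAs of the four positional classes plus single-exon noise and
#' coding-like decoys; a three-stage (EF/SF/LF), three-replicate,
#' multi-cultivar expression design with planted up-down / down-up
#' differential-expression patterns; module-structured expression tied to
#' volatile compounds at a planted correlation; and GC-MS peak tables
#' consistent with the internal-standard emission formula.
#'
#' @param seed integer RNG seed; the whole bundle is a deterministic
#'   function of the config including the seed.
#' @param n_coding_genes number of protein-coding genes.
#' @param n_lnc_per_class named counts for lincRNA / antisense /
#'   sense_overlapping / sense_intronic.
#' @param n_housekeeping number of housekeeping ncRNA genes (and matching
#'   decoy transcripts).
#' @param n_single_exon_noise number of single-exon noise transcripts.
#' @param n_coding_like_decoys decoys passing length/exon filters and
#'   failing only the hit-table or domain/coding-potential gate (half
#'   each).
#' @param chrom_length_bp chromosome length; layout errors out if the
#'   requested features do not fit.
#' @param stages ordered stage labels.
#' @param replicates_per_stage biological replicates per stage.
#' @param n_cultivars cultivars; total samples = cultivars x stages x
#'   replicates (default 36, comfortably above the 15-sample network
#'   floor).
#' @param n_modules planted co-expression modules.
#' @param module_size_range inclusive (min, max) module sizes.
#' @param trait_link data.frame (compound, class, module_index, r) linking
#'   compounds to modules at a planted correlation; defaults to 19 rose
#'   scent compounds cycled over the modules at r = 0.9, plus two unlinked
#'   non-scent compounds.
#' @param de_pattern_counts named counts of planted DE patterns (up_down,
#'   down_up, single_transition) among the lncRNAs.
#' @param n_below_floor how many planted DE lncRNAs are expressed below the
#'   0.5 floor in every stage.
#' @param noise_sd log2-scale expression noise SD.
#' @param de_fold planted stage fold change for DE patterns.
#' @param volatile_stage_effect per-stage multipliers for unlinked
#'   compounds (rise-and-fall emission profile).
#' @param n_coexpr_pairs planted lncRNA-mRNA co-expression pairs
#'   (r ~ 0.99).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_coding_genes = 150,
                       n_lnc_per_class = c(lincRNA = 60, antisense = 30,
                                           sense_overlapping = 20,
                                           sense_intronic = 40),
                       n_housekeeping = 30,
                       n_single_exon_noise = 100,
                       n_coding_like_decoys = 20,
                       chrom_length_bp = 6e6,
                       stages = c("EF", "SF", "LF"),
                       replicates_per_stage = 3,
                       n_cultivars = 4,
                       n_modules = 13,
                       module_size_range = c(6, 8),
                       trait_link = NULL,
                       de_pattern_counts = c(up_down = 9, down_up = 9,
                                             single_transition = 20),
                       n_below_floor = 6,
                       noise_sd = 0.25,
                       de_fold = 4,
                       volatile_stage_effect = c(1, 10, 4),
                       n_coexpr_pairs = 10) {
  stopifnot(n_coding_genes >= 0, all(n_lnc_per_class >= 0),
            n_housekeeping >= 0, n_single_exon_noise >= 0,
            n_modules >= 0, length(module_size_range) == 2,
            module_size_range[1] <= module_size_range[2],
            length(volatile_stage_effect) == length(stages))
  if (is.null(trait_link)) {
    scent <- DEFAULT_COMPOUNDS[DEFAULT_COMPOUNDS$class != "non_scent", ]
    trait_link <- data.frame(
      compound = scent$compound, class = scent$class,
      module_index = if (n_modules > 0)
        ((seq_len(nrow(scent)) - 1L) %% n_modules) + 1L else NA_integer_,
      r = 0.9, stringsAsFactors = FALSE)
  }
  stopifnot(all(abs(trait_link$r) < 1))
  structure(list(
    seed = seed, n_coding_genes = n_coding_genes,
    n_lnc_per_class = n_lnc_per_class, n_housekeeping = n_housekeeping,
    n_single_exon_noise = n_single_exon_noise,
    n_coding_like_decoys = n_coding_like_decoys,
    chrom_length_bp = chrom_length_bp, stages = stages,
    replicates_per_stage = replicates_per_stage, n_cultivars = n_cultivars,
    n_modules = n_modules, module_size_range = module_size_range,
    trait_link = trait_link, de_pattern_counts = de_pattern_counts,
    n_below_floor = n_below_floor, noise_sd = noise_sd, de_fold = de_fold,
    volatile_stage_effect = volatile_stage_effect,
    n_coexpr_pairs = n_coexpr_pairs
  ), class = "sim_config")
}

.rand_seq <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

#' Generate a nucleotide sequence with a bounded longest ORF
#'
#' Rejection-samples uniform random sequences until the longest
#' forward-frame ATG-initiated ORF is shorter than `max_orf_aa` codons
#' (checked with the same [longest_orf()] finder the identification module
#' uses). Errors after `max_tries` failures.
#'
#' @param length_nt sequence length (>= 1).
#' @param max_orf_aa exclusive ORF bound in amino acids.
#' @param max_tries rejection budget.
#' @return a character sequence of length `length_nt`.
#' @export
plant_orf_free_sequence <- function(length_nt, max_orf_aa = 100,
                                    max_tries = 200) {
  stopifnot(length_nt >= 1, max_orf_aa >= 1)
  for (i in seq_len(max_tries)) {
    s <- .rand_seq(length_nt)
    if (longest_orf(s)$aa_length < max_orf_aa) return(s)
  }
  stop("generation error: could not build an ORF-free sequence of length ",
       length_nt, " under ", max_orf_aa, " aa in ", max_tries, " tries")
}

# sequence with a planted ORF of orf_aa codons starting at a random offset;
# the ORF body is drawn from non-stop codons so the planted ORF is complete
.plant_coding_sequence <- function(length_nt, orf_aa) {
  body_nt <- 3 * orf_aa + 3   # ATG + (orf_aa - 1) codons + stop
  stopifnot(body_nt <= length_nt)
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  sense <- setdiff(codons, STOP_CODONS)
  pre_n <- sample.int(length_nt - body_nt + 1L, 1L) - 1L
  post_n <- length_nt - body_nt - pre_n
  orf <- paste0("ATG",
                paste(sample(sense, orf_aa - 1L, replace = TRUE),
                      collapse = ""),
                sample(STOP_CODONS, 1L))
  paste0(if (pre_n) .rand_seq(pre_n) else "",
         orf,
         if (post_n) .rand_seq(post_n) else "")
}

# ---- geometry helpers -------------------------------------------------------

# lay out coding genes left to right; the first intron is kept wide so it
# can host sense-intronic lncRNAs
.layout_coding_genes <- function(n, chrom_len) {
  genes <- vector("list", n)
  cursor <- 1L
  for (i in seq_len(n)) {
    gap <- sample(6000:10000, 1)
    start <- cursor + gap
    n_ex <- sample(2:4, 1)
    widths <- sample(200:400, n_ex, replace = TRUE)
    introns <- c(sample(1600:2400, 1),
                 if (n_ex > 2) sample(300:800, n_ex - 2, replace = TRUE))
    ex_start <- start + c(0L, cumsum(widths[-n_ex] + introns))
    ex_end <- ex_start + widths - 1L
    genes[[i]] <- list(gene_id = sprintf("gene%04d", i),
                       strand = sample(c("+", "-"), 1),
                       ex_start = ex_start, ex_end = ex_end)
    cursor <- max(ex_end)
  }
  if (cursor + 6000 > chrom_len)
    stop("config error: infeasible geometry, ", n,
         " coding genes do not fit in ", chrom_len, " bp")
  genes
}

# free gaps between consecutive gene spans (with outer margins)
.gene_gaps <- function(genes, chrom_len, margin = 1000) {
  spans <- vapply(genes, function(g) c(min(g$ex_start), max(g$ex_end)),
                  numeric(2))
  starts <- c(1, spans[2, ] + margin)
  ends <- c(spans[1, ] - margin, chrom_len)
  data.frame(start = starts, end = ends)[ends - starts > 2 * margin, ]
}

# place `widths[i]` bp features into the gaps sequentially
.place_in_gaps <- function(gaps, widths, spacing = 800) {
  out <- matrix(NA_real_, length(widths), 2)
  gi <- 1L; cursor <- gaps$start[1]
  for (i in seq_along(widths)) {
    repeat {
      if (gi > nrow(gaps))
        stop("config error: infeasible geometry, intergenic features do not fit")
      if (cursor + widths[i] <= gaps$end[gi]) break
      gi <- gi + 1L
      if (gi <= nrow(gaps)) cursor <- gaps$start[gi]
    }
    out[i, ] <- c(cursor, cursor + widths[i] - 1)
    cursor <- cursor + widths[i] + spacing
  }
  out
}

# ---- main generator ---------------------------------------------------------

#' Generate a complete synthetic fixture bundle
#'
#' Produces, deterministically for a given config, the full set of inputs
#' the pipeline consumes plus a ground-truth manifest: a gene annotation
#' (coding, housekeeping and annotated-lncRNA genes), transcript models
#' with sequences, a protein-alignment hit table, Pfam and external
#' coding-potential score tables, an expression matrix with sample
#' metadata, volatile emission targets with a matching GC-MS peak table,
#' compound class labels, and a qPCR Ct table.
#'
#' Planted structure: lncRNA sequences satisfy the length/ORF constraints;
#' coding transcripts carry an ORF covering most of the transcript and a
#' qualifying hit-table row; the four positional classes are realized
#' geometrically; stage DE patterns are planted multiplicatively on the
#' log2 scale; module members follow shared eigen-trajectories; linked
#' volatile vectors are generated to correlate with their module trajectory
#' at the planted r; peak areas are back-computed through the inverse of
#' the emission-rate formula so that quantification round-trips exactly.
#'
#' @param config a [sim_config()].
#' @return list of class `scent_sim`; see elements `annotation`,
#'   `transcripts`, `hits`, `pfam`, `cpc`, `expr`, `sample_meta`,
#'   `volatile_rates`, `compound_classes`, `gcms`, `ct`, `manifest`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  set.seed(config$seed)
  chrom <- "chr1"

  # --- coding gene geometry
  genes <- .layout_coding_genes(config$n_coding_genes, config$chrom_length_bp)
  gaps <- .gene_gaps(genes, config$chrom_length_bp)

  exon_rows <- list()  # transcript exons
  tx_info <- list()    # id, gene, category, annotated
  seqs <- character()

  add_tx <- function(id, gene_id, strand, starts, ends, category,
                     annotated = FALSE, sequence = NULL) {
    exon_rows[[length(exon_rows) + 1L]] <<- data.frame(
      start = starts, end = ends, strand = strand,
      transcript_id = id, gene_id = gene_id, stringsAsFactors = FALSE)
    tx_info[[length(tx_info) + 1L]] <<- data.frame(
      transcript_id = id, gene_id = gene_id, category = category,
      annotated = annotated, length = sum(ends - starts + 1),
      stringsAsFactors = FALSE)
    if (!is.null(sequence)) seqs[[id]] <<- sequence
  }

  # --- coding transcripts (one per gene), planted long ORF + qualifying hit
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    id <- sprintf("tx_cod%04d", i)
    L <- sum(g$ex_end - g$ex_start + 1)
    orf_aa <- max(100L, as.integer(floor(L * stats::runif(1, 0.80, 0.90) / 3)) - 1L)
    add_tx(id, g$gene_id, g$strand, g$ex_start, g$ex_end, "coding",
           sequence = .plant_coding_sequence(L, orf_aa))
  }

  # --- lncRNAs of the four positional classes
  lnc_counter <- 0L
  new_lnc_id <- function() {
    lnc_counter <<- lnc_counter + 1L
    sprintf("tx_lnc%04d", lnc_counter)
  }
  lnc_seq <- function(L) plant_orf_free_sequence(L, 100)
  n_cls <- config$n_lnc_per_class
  host_used <- 0L  # genes are consumed left to right by hosted lnc classes
  take_hosts <- function(k) {
    if (host_used + k > length(genes))
      stop("config error: not enough coding genes to host the lncRNA classes")
    idx <- host_used + seq_len(k); host_used <<- host_used + k; idx
  }

  flip <- c("+" = "-", "-" = "+")
  for (gi in take_hosts(n_cls[["antisense"]])) {
    g <- genes[[gi]]
    # exon 1 straddles the 3' end of coding exon 1 (>= 50 bp overlap),
    # exon 2 sits inside the wide first intron
    e1s <- g$ex_end[1] - sample(80:140, 1); e1e <- g$ex_end[1] + sample(150:250, 1)
    e2s <- e1e + sample(200:400, 1); e2e <- e2s + sample(120:250, 1)
    id <- new_lnc_id()
    L <- (e1e - e1s + 1) + (e2e - e2s + 1)
    add_tx(id, paste0("g_", id), flip[[g$strand]], c(e1s, e2s), c(e1e, e2e),
           "antisense", annotated = lnc_counter %% 2L == 0L,
           sequence = lnc_seq(L))
  }
  for (gi in take_hosts(n_cls[["sense_overlapping"]])) {
    g <- genes[[gi]]
    e1s <- g$ex_end[1] - sample(80:140, 1); e1e <- g$ex_end[1] + sample(150:250, 1)
    e2s <- e1e + sample(200:400, 1); e2e <- e2s + sample(120:250, 1)
    id <- new_lnc_id()
    L <- (e1e - e1s + 1) + (e2e - e2s + 1)
    add_tx(id, paste0("g_", id), g$strand, c(e1s, e2s), c(e1e, e2e),
           "sense_overlapping", annotated = lnc_counter %% 2L == 0L,
           sequence = lnc_seq(L))
  }
  for (gi in take_hosts(n_cls[["sense_intronic"]])) {
    g <- genes[[gi]]
    # wholly inside the wide first intron, no exonic overlap, random strand
    i0 <- g$ex_end[1] + 100
    e1s <- i0; e1e <- i0 + sample(120:200, 1)
    e2s <- e1e + sample(150:300, 1); e2e <- e2s + sample(120:200, 1)
    stopifnot(e2e < g$ex_start[2] - 50)
    id <- new_lnc_id()
    L <- (e1e - e1s + 1) + (e2e - e2s + 1)
    add_tx(id, paste0("g_", id), sample(c("+", "-"), 1), c(e1s, e2s),
           c(e1e, e2e), "sense_intronic", annotated = lnc_counter %% 2L == 0L,
           sequence = lnc_seq(L))
  }

  # --- intergenic features share the gaps: lincRNAs, housekeeping genes,
  #     noise, decoys
  n_linc <- n_cls[["lincRNA"]]
  linc_ex1 <- sample(150:400, n_linc, replace = TRUE)
  linc_int <- sample(150:400, n_linc, replace = TRUE)
  linc_ex2 <- sample(150:400, n_linc, replace = TRUE)
  hk_w <- sample(90:160, config$n_housekeeping, replace = TRUE)
  noise_w <- sample(150:900, config$n_single_exon_noise, replace = TRUE)
  # decoys stay short with a 99-aa ORF so they clear the length/ORF filter
  # and fall only at the hit-table or domain/coding-potential gate
  n_dec <- config$n_coding_like_decoys
  dec_ex1 <- sample(155:180, n_dec, replace = TRUE)
  dec_int <- sample(150:400, n_dec, replace = TRUE)
  dec_ex2 <- sample(155:180, n_dec, replace = TRUE)

  widths <- c(linc_ex1 + linc_int + linc_ex2, hk_w, noise_w,
              dec_ex1 + dec_int + dec_ex2)
  pos <- .place_in_gaps(gaps, widths)
  off <- 0L

  for (i in seq_len(n_linc)) {
    p <- pos[off + i, ]
    id <- new_lnc_id()
    e1e <- p[1] + linc_ex1[i] - 1
    e2s <- e1e + linc_int[i] + 1
    L <- linc_ex1[i] + linc_ex2[i]
    add_tx(id, paste0("g_", id), sample(c("+", "-"), 1),
           c(p[1], e2s), c(e1e, e2s + linc_ex2[i] - 1),
           "lincRNA", annotated = lnc_counter %% 2L == 0L,
           sequence = lnc_seq(L))
  }
  off <- off + n_linc

  hk_genes <- list()
  hk_types <- rep(c("rRNA", "tRNA", "snRNA", "snoRNA"),
                  length.out = config$n_housekeeping)
  for (i in seq_len(config$n_housekeeping)) {
    p <- pos[off + i, ]
    gid <- sprintf("hk%03d", i)
    strand <- sample(c("+", "-"), 1)
    hk_genes[[i]] <- list(gene_id = gid, biotype = hk_types[i],
                          start = p[1], end = p[2], strand = strand)
    # matching decoy transcript overlapping the housekeeping exon
    add_tx(sprintf("tx_hk%03d", i), gid, strand, p[1], p[2],
           "housekeeping", sequence = .rand_seq(p[2] - p[1] + 1))
  }
  off <- off + config$n_housekeeping

  for (i in seq_len(config$n_single_exon_noise)) {
    p <- pos[off + i, ]
    id <- sprintf("tx_noise%04d", i)
    add_tx(id, paste0("g_", id), sample(c("+", "-"), 1), p[1], p[2], "noise",
           sequence = .rand_seq(p[2] - p[1] + 1))
  }
  off <- off + config$n_single_exon_noise

  for (i in seq_len(n_dec)) {
    p <- pos[off + i, ]
    id <- sprintf("tx_dec%03d", i)
    e1e <- p[1] + dec_ex1[i] - 1
    e2s <- e1e + dec_int[i] + 1
    L <- dec_ex1[i] + dec_ex2[i]
    add_tx(id, paste0("g_", id), sample(c("+", "-"), 1),
           c(p[1], e2s), c(e1e, e2s + dec_ex2[i] - 1),
           if (i <= ceiling(n_dec / 2)) "decoy_hit" else "decoy_pfam",
           sequence = .plant_coding_sequence(L, 99L))
  }

  tx_df <- do.call(rbind, tx_info)
  exons_df <- do.call(rbind, exon_rows)
  ex_gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = exons_df$start, end = exons_df$end),
    strand = exons_df$strand)
  ex_gr$transcript_id <- exons_df$transcript_id
  ex_gr$gene_id <- exons_df$gene_id
  ts <- transcript_set(ex_gr, Biostrings::DNAStringSet(seqs))

  # --- annotation: coding genes + housekeeping + annotated lncRNA genes
  ann_rows <- list(); ann_ex <- list()
  for (g in genes) {
    ann_rows[[length(ann_rows) + 1L]] <- data.frame(
      gene_id = g$gene_id, biotype = "protein_coding",
      start = min(g$ex_start), end = max(g$ex_end), strand = g$strand)
    ann_ex[[length(ann_ex) + 1L]] <- data.frame(
      gene_id = g$gene_id, start = g$ex_start, end = g$ex_end,
      strand = g$strand)
  }
  for (h in hk_genes) {
    ann_rows[[length(ann_rows) + 1L]] <- data.frame(
      gene_id = h$gene_id, biotype = h$biotype,
      start = h$start, end = h$end, strand = h$strand)
    ann_ex[[length(ann_ex) + 1L]] <- data.frame(
      gene_id = h$gene_id, start = h$start, end = h$end, strand = h$strand)
  }
  ann_lnc <- tx_df$transcript_id[tx_df$annotated]
  for (id in ann_lnc) {
    sub <- exons_df[exons_df$transcript_id == id, ]
    gid <- paste0("annlnc_", id)
    ann_rows[[length(ann_rows) + 1L]] <- data.frame(
      gene_id = gid, biotype = "lncRNA",
      start = min(sub$start), end = max(sub$end), strand = sub$strand[1])
    ann_ex[[length(ann_ex) + 1L]] <- data.frame(
      gene_id = gid, start = sub$start, end = sub$end, strand = sub$strand)
  }
  ag <- do.call(rbind, ann_rows); ae <- do.call(rbind, ann_ex)
  genes_gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(ag$start, ag$end), strand = ag$strand)
  genes_gr$gene_id <- ag$gene_id; genes_gr$biotype <- ag$biotype
  annex_gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(ae$start, ae$end), strand = ae$strand)
  annex_gr$gene_id <- ae$gene_id
  annex_gr$biotype <- ag$biotype[match(ae$gene_id, ag$gene_id)]
  annotation <- gene_annotation(genes_gr, annex_gr)

  # --- hit table: qualifying rows for coding + decoy_hit, near-miss rows
  #     (one sub-threshold field each) for a few lncRNAs
  hit_rows <- list()
  coding_ids <- tx_df$transcript_id[tx_df$category %in% c("coding", "decoy_hit")]
  for (id in coding_ids)
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      transcript_id = id, subject_id = paste0("prot_", id),
      identity_pct = stats::runif(1, 91, 99),
      coverage_pct = stats::runif(1, 81, 99),
      p_value = 10^stats::runif(1, -40, -15), stringsAsFactors = FALSE)
  lnc_ids_all <- tx_df$transcript_id[tx_df$category %in% LNC_CLASSES]
  near_miss <- utils::head(lnc_ids_all, 15)
  for (i in seq_along(near_miss)) {
    fail_field <- (i - 1L) %% 3L
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      transcript_id = near_miss[i], subject_id = "prot_near",
      identity_pct = if (fail_field == 0) stats::runif(1, 60, 90) else stats::runif(1, 91, 99),
      coverage_pct = if (fail_field == 1) stats::runif(1, 40, 80) else stats::runif(1, 81, 99),
      p_value = if (fail_field == 2) 10^stats::runif(1, -9, -3) else 10^stats::runif(1, -40, -15),
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, hit_rows)

  # --- Pfam hits for the pfam decoys; external coding-potential scores
  pfam_ids <- tx_df$transcript_id[tx_df$category == "decoy_pfam"]
  pfam <- data.frame(transcript_id = pfam_ids,
                     domain = paste0("PF", seq_along(pfam_ids) + 10000),
                     evalue = 10^stats::runif(length(pfam_ids), -20, -6),
                     stringsAsFactors = FALSE)
  is_lnc <- tx_df$category %in% LNC_CLASSES
  cpc <- data.frame(
    transcript_id = tx_df$transcript_id,
    score = ifelse(is_lnc,
                   -abs(stats::rnorm(nrow(tx_df), 1.5, 0.5)),
                   abs(stats::rnorm(nrow(tx_df), 2.0, 0.7))),
    stringsAsFactors = FALSE)

  # --- sample design
  meta <- expand.grid(replicate = seq_len(config$replicates_per_stage),
                      stage = config$stages,
                      cultivar = paste0("cv", seq_len(config$n_cultivars)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_%s_r%d", meta$cultivar, meta$stage,
                            meta$replicate)
  meta <- meta[, c("sample_id", "cultivar", "stage", "replicate")]
  n_samp <- nrow(meta)

  # --- planted roles: DE patterns, then module members, among lncRNAs
  dpc <- config$de_pattern_counts
  need_de <- sum(dpc)
  if (need_de > length(lnc_ids_all))
    stop("config error: more planted DE patterns than lncRNAs")
  # spread DE plants across the classes rather than consuming one class
  shuffled_lnc <- sample(lnc_ids_all)
  de_ids <- shuffled_lnc[seq_len(need_de)]
  de_pattern <- rep(names(dpc), times = dpc)
  names(de_pattern) <- de_ids
  below_floor_ids <- utils::head(
    de_ids[de_pattern == "single_transition"], config$n_below_floor)

  remaining <- setdiff(shuffled_lnc, de_ids)
  mod_sizes <- if (config$n_modules > 0)
    sample(seq(config$module_size_range[1], config$module_size_range[2]),
           config$n_modules, replace = TRUE) else integer(0)
  if (sum(mod_sizes) > length(remaining))
    stop("config error: not enough lncRNAs for the requested modules")
  module_members <- split(remaining[seq_len(sum(mod_sizes))],
                          rep(seq_along(mod_sizes), times = mod_sizes))

  # --- expression matrix
  all_ids <- tx_df$transcript_id
  base_log2 <- stats::rnorm(length(all_ids), 3, 1.2)
  names(base_log2) <- all_ids
  base_log2[below_floor_ids] <- -6
  expr <- matrix(0, length(all_ids), n_samp,
                 dimnames = list(all_ids, meta$sample_id))
  stage_idx <- match(meta$stage, config$stages)
  lf2 <- log2(config$de_fold)
  pattern_lfc <- list(
    up_down = c(0, lf2, 0),
    down_up = c(lf2, 0, lf2),
    single_transition = c(0, lf2, lf2))
  shift <- matrix(0, length(all_ids), n_samp)
  rownames(shift) <- all_ids
  for (id in de_ids)
    shift[id, ] <- pattern_lfc[[de_pattern[[id]]]][stage_idx]
  noise <- matrix(stats::rnorm(length(all_ids) * n_samp, 0, config$noise_sd),
                  length(all_ids), n_samp)
  expr <- 2^(base_log2 + shift + noise)
  dimnames(expr) <- list(all_ids, meta$sample_id)

  # module members override: trajectory x loading + noise on the linear scale
  eigen_traj <- NULL
  if (length(module_members)) {
    raw <- matrix(stats::rnorm(n_samp * length(module_members)), n_samp)
    eigen_traj <- qr.Q(qr(raw))           # orthonormal columns
    eigen_traj <- sweep(eigen_traj, 2, sqrt(colSums(eigen_traj^2) / (n_samp - 1)), "/")
    rownames(eigen_traj) <- meta$sample_id
    colnames(eigen_traj) <- sprintf("planted%02d", seq_along(module_members))
    for (mi in seq_along(module_members)) {
      for (id in module_members[[mi]]) {
        loading <- stats::runif(1, 2.5, 4)
        expr[id, ] <- pmax(
          stats::runif(1, 8, 15) + loading * eigen_traj[, mi] +
            stats::rnorm(n_samp, 0, 0.5),
          0.01)
      }
    }
  }

  # planted lncRNA-mRNA co-expression pairs (trans targets)
  linc_ids <- tx_df$transcript_id[tx_df$category == "lincRNA"]
  free_linc <- setdiff(linc_ids, c(de_ids, unlist(module_members)))
  n_pairs <- min(config$n_coexpr_pairs, length(free_linc),
                 config$n_coding_genes)
  coexpr_pairs <- data.frame(lnc_id = character(), gene_tx = character())
  if (n_pairs > 0) {
    pair_lnc <- free_linc[seq_len(n_pairs)]
    pair_cod <- tx_df$transcript_id[tx_df$category == "coding"][seq_len(n_pairs)]
    for (i in seq_len(n_pairs))
      expr[pair_cod[i], ] <- expr[pair_lnc[i], ] *
        stats::runif(1, 0.5, 2) * 2^stats::rnorm(n_samp, 0, 0.03)
    coexpr_pairs <- data.frame(lnc_id = pair_lnc, gene_tx = pair_cod,
                               stringsAsFactors = FALSE)
  }

  # --- volatiles: linked compounds track their module trajectory at the
  #     planted r; unlinked compounds follow the stage profile
  tl <- config$trait_link
  all_compounds <- unique(c(tl$compound, DEFAULT_COMPOUNDS$compound))
  classes <- DEFAULT_COMPOUNDS[match(all_compounds, DEFAULT_COMPOUNDS$compound), ]
  classes$compound <- all_compounds
  classes$class[is.na(classes$class)] <-
    tl$class[match(all_compounds[is.na(classes$class)], tl$compound)]
  rates <- matrix(0, length(all_compounds), n_samp,
                  dimnames = list(all_compounds, meta$sample_id))
  stage_mult <- config$volatile_stage_effect[stage_idx]
  for (ci in seq_along(all_compounds)) {
    cp <- all_compounds[ci]
    li <- match(cp, tl$compound)
    mi <- if (!is.na(li)) tl$module_index[li] else NA
    if (!is.na(mi) && !is.null(eigen_traj) && mi <= ncol(eigen_traj)) {
      r <- tl$r[li]
      z <- stats::rnorm(n_samp)
      v <- r * eigen_traj[, mi] + sqrt(1 - r^2) * scale(z)[, 1]
      rates[ci, ] <- pmax(8 + 2 * v, 0.001)
    } else {
      rates[ci, ] <- stats::runif(1, 0.5, 3) * stage_mult *
        2^stats::rnorm(n_samp, 0, config$noise_sd)
    }
  }

  # GC-MS peaks back-computed through the inverse of the emission formula
  is_conc <- 0.865; is_vol <- 10; mass <- 3; time_h <- 2 / 3
  gcms <- do.call(rbind, lapply(seq_len(n_samp), function(si) {
    isa <- stats::runif(1, 5e5, 1.5e6)
    data.frame(sample_id = meta$sample_id[si], compound = all_compounds,
               peak_area = rates[, si] * mass * time_h * isa /
                 (is_conc * is_vol),
               is_peak_area = isa, is_concentration = is_conc,
               is_volume = is_vol, sample_mass = mass,
               extraction_time = time_h, stringsAsFactors = FALSE)
  }))

  # --- qPCR Ct table for 10 DE lncRNAs (5 up_down, 5 down_up)
  qpcr_ids <- c(utils::head(de_ids[de_pattern == "up_down"], 5),
                utils::head(de_ids[de_pattern == "down_up"], 5))
  ref_cv <- meta$cultivar[1]
  ct_rows <- list()
  for (id in qpcr_ids) {
    for (st in config$stages[-1]) {
      m_ef <- mean(expr[id, meta$stage == config$stages[1] &
                          meta$cultivar == ref_cv])
      m_st <- mean(expr[id, meta$stage == st & meta$cultivar == ref_cv])
      lfc_seq <- log2((m_st + 0.01) / (m_ef + 0.01))
      lfc_q <- lfc_seq + stats::rnorm(1, 0, 0.5)
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        transcript_id = id, stage = st,
        ct_target_treat = 25 - lfc_q, ct_ref_treat = 20,
        ct_target_ctrl = 25, ct_ref_ctrl = 20,
        fc_seq = 2^lfc_seq, stringsAsFactors = FALSE)
    }
  }
  ct <- do.call(rbind, ct_rows)

  manifest <- list(
    transcripts = data.frame(
      tx_df,
      is_lnc = tx_df$category %in% LNC_CLASSES,
      orf_aa = longest_orf_lengths(ts$sequences[tx_df$transcript_id]),
      de_pattern = ifelse(tx_df$transcript_id %in% de_ids,
                          de_pattern[tx_df$transcript_id], "none"),
      below_floor = tx_df$transcript_id %in% below_floor_ids,
      module = NA_character_, stringsAsFactors = FALSE),
    modules = module_members,
    eigen_trajectories = eigen_traj,
    compounds = data.frame(
      compound = all_compounds, class = classes$class,
      linked_module = tl$module_index[match(all_compounds, tl$compound)],
      planted_r = tl$r[match(all_compounds, tl$compound)],
      stringsAsFactors = FALSE),
    target_rates = rates,
    coexpr_pairs = coexpr_pairs,
    de_ids = de_ids,
    below_floor_ids = below_floor_ids
  )
  for (mi in seq_along(module_members))
    manifest$transcripts$module[
      manifest$transcripts$transcript_id %in% module_members[[mi]]] <-
    sprintf("planted%02d", mi)

  structure(list(
    config = config, annotation = annotation, transcripts = ts,
    hits = hits, pfam = pfam, cpc = cpc,
    expr = expr, sample_meta = meta,
    volatile_rates = rates,
    compound_classes = classes[, c("compound", "class")],
    gcms = gcms, ct = ct, manifest = manifest
  ), class = "scent_sim")
}

#' @export
print.scent_sim <- function(x, ...) {
  cat("<scent_sim> ", length(x$transcripts), " transcripts, ",
      nrow(x$sample_meta), " samples, ",
      length(x$manifest$modules), " planted modules, seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a fixture bundle to disk
#'
#' Emits annotation GFF3, transcript GTF + FASTA, hit/Pfam/CPC tables,
#' expression + metadata TSVs, GC-MS peak and compound-class TSVs, the Ct
#' table and the manifest JSON into `dir`.
#'
#' @param sim a `scent_sim`.
#' @param dir output directory (created if needed).
#' @return named vector of the file paths, invisibly.
#' @export
write_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_annotation_gff3(sim$annotation, p("annotation.gff3"))
  write_transcripts_gtf(sim$transcripts, p("transcripts.gtf"))
  Biostrings::writeXStringSet(sim$transcripts$sequences, p("transcripts.fa"))
  wt <- function(df, f) utils::write.table(
    df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(sim$hits, "hits.tsv")
  wt(sim$pfam, "pfam.tsv")
  wt(sim$cpc, "cpc.tsv")
  expr_df <- data.frame(transcript_id = rownames(sim$expr), sim$expr,
                        check.names = FALSE)
  wt(expr_df, "expression.tsv")
  wt(sim$sample_meta, "samples.tsv")
  wt(sim$gcms, "gcms_peaks.tsv")
  wt(sim$compound_classes, "compound_classes.tsv")
  wt(sim$ct, "ct.tsv")
  manifest <- sim$manifest
  manifest$target_rates <- NULL  # large matrix kept in-memory only
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c("annotation.gff3", "transcripts.gtf", "transcripts.fa",
             "hits.tsv", "pfam.tsv", "cpc.tsv", "expression.tsv",
             "samples.tsv", "gcms_peaks.tsv", "compound_classes.tsv",
             "ct.tsv", "manifest.json")
  invisible(stats::setNames(file.path(dir, files), files))
}

#' Simulate a two-group DE benchmark matrix
#'
#' Focused generator for differential-expression benchmarking: `n_null`
#' unchanged transcripts and `n_de` transcripts with a planted fold change
#' between two stages, log-normal noise, `reps` replicates per stage.
#'
#' @param n_null,n_de transcript counts.
#' @param fold planted fold change (half up, half down).
#' @param reps replicates per stage.
#' @param noise_sd log2-scale noise SD.
#' @param stages two stage labels.
#' @return list with `expr`, `meta`, `truth` (data.frame transcript_id,
#'   de, direction).
#' @export
simulate_de_matrix <- function(n_null = 180, n_de = 20, fold = 4, reps = 3,
                               noise_sd = 0.25, stages = c("EF", "SF")) {
  n <- n_null + n_de
  ids <- sprintf("t%04d", seq_len(n))
  de <- c(rep(FALSE, n_null), rep(TRUE, n_de))
  dir_up <- de & (seq_len(n) - n_null) <= n_de / 2
  base <- stats::rnorm(n, 4, 1)
  lfc <- ifelse(!de, 0, ifelse(dir_up, log2(fold), -log2(fold)))
  meta <- data.frame(
    sample_id = c(paste0(stages[1], "_r", seq_len(reps)),
                  paste0(stages[2], "_r", seq_len(reps))),
    cultivar = "cv1",
    stage = rep(stages, each = reps),
    replicate = rep(seq_len(reps), 2), stringsAsFactors = FALSE)
  shift <- outer(lfc, as.numeric(meta$stage == stages[2]))
  expr <- 2^(base + shift +
               matrix(stats::rnorm(n * nrow(meta), 0, noise_sd), n))
  dimnames(expr) <- list(ids, meta$sample_id)
  list(expr = expr, meta = meta,
       truth = data.frame(transcript_id = ids, de = de,
                          direction = ifelse(!de, "ns",
                                             ifelse(dir_up, "up", "down")),
                          stringsAsFactors = FALSE))
}

#' Simulate a module-structured expression matrix
#'
#' Focused generator for network benchmarking: `n_modules` modules whose
#' members follow orthonormal eigen-trajectories, plus optional volatile
#' vectors linked to modules at a planted correlation.
#'
#' @param n_modules module count.
#' @param module_sizes integer vector (recycled) of module sizes.
#' @param n_samples sample count (>= 15 for network defaults).
#' @param noise_sd linear-scale member noise SD.
#' @param compounds optional data.frame (compound, module_index, r).
#' @return list with `expr`, `labels` (planted module per transcript),
#'   `trajectories`, and `volatiles` (matrix or NULL).
#' @export
simulate_module_matrix <- function(n_modules = 13, module_sizes = 7,
                                   n_samples = 36, noise_sd = 0.5,
                                   compounds = NULL) {
  sizes <- rep_len(module_sizes, n_modules)
  n <- sum(sizes)
  ids <- sprintf("m%04d", seq_len(n))
  lab <- rep(sprintf("planted%02d", seq_len(n_modules)), times = sizes)
  raw <- matrix(stats::rnorm(n_samples * n_modules), n_samples)
  traj <- qr.Q(qr(raw))
  traj <- sweep(traj, 2, sqrt(colSums(traj^2) / (n_samples - 1)), "/")
  colnames(traj) <- sprintf("planted%02d", seq_len(n_modules))
  rownames(traj) <- paste0("s", seq_len(n_samples))
  expr <- matrix(0, n, n_samples, dimnames = list(ids, rownames(traj)))
  for (i in seq_len(n)) {
    mi <- match(lab[i], colnames(traj))
    expr[i, ] <- pmax(stats::runif(1, 8, 15) +
                        stats::runif(1, 2.5, 4) * traj[, mi] +
                        stats::rnorm(n_samples, 0, noise_sd), 0.01)
  }
  volatiles <- NULL
  if (!is.null(compounds)) {
    volatiles <- matrix(0, nrow(compounds), n_samples,
                        dimnames = list(compounds$compound, rownames(traj)))
    for (i in seq_len(nrow(compounds))) {
      r <- compounds$r[i]
      v <- r * traj[, compounds$module_index[i]] +
        sqrt(1 - r^2) * scale(stats::rnorm(n_samples))[, 1]
      volatiles[i, ] <- pmax(8 + 2 * v, 0.001)
    }
  }
  list(expr = expr, labels = stats::setNames(lab, ids),
       trajectories = traj, volatiles = volatiles)
}
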