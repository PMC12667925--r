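# Synthetic cohort generator with planted ground truth.
#
# The generator emulates the data structure of a TMT proteogenomic tumor
# study: subtype-specific protein/phospho/mRNA signatures, per-plex
# multiplicative batch effects with pooled-reference channels, MS-style
# missingness, allele-specific segment profiles with controlled instability,
# copy-number-driven cis effects, kinase-driven phosphosite shifts, and
# subtype-dependent exponential survival.

#' Simulation configuration
#'
#' Defaults describe the study conditions every downstream test runs under:
#' a 60-sample cohort with 3 balanced subtypes measured in 16-channel TMT
#' plexes (15 tumors + 1 pooled reference per plex), a 1.0 log2 subtype
#' signature on 50 proteins/phosphosites per subtype, plex batch effects of
#' 0.3 log2 SD, 0.5 log2 measurement noise, and 20% missingness.
#'
#' @param n_samples Number of tumor samples.
#' @param n_subtypes Number of planted subtypes (balanced).
#' @param samples_per_plex TMT channels per plex including one
#'   pooled-reference channel.
#' @param n_proteins,n_phosphosites,n_mrna Feature counts per omic layer.
#' @param signature_size Signature features per subtype and omic layer.
#' @param signature_effect Log2 shift of signature features in their subtype
#'   (mRNA signatures use twice this shift, emulating the stronger dynamic
#'   range of transcript counts).
#' @param batch_effect_sd SD of the per-plex, per-feature multiplicative
#'   batch effect on the log2 scale.
#' @param noise_sd SD of per-cell noise on the log2 scale for tumor channels
#'   (biological + technical variation between samples).
#' @param ref_noise_sd SD of technical measurement noise on pooled-reference
#'   channels; default 0.1 log2 (a typical within-plex technical CV). The
#'   pooled reference is the same aliquot in every plex, so it carries no
#'   biological variation — only this term separates it from the true plex
#'   mean.
#' @param missing_rate Target fraction of missing tumor-channel cells
#'   (pooled-reference channels are always observed).
#' @param missing_mode `"random"` or `"intensity_dependent"` (logistic
#'   dropout on log2 abundance, emulating MS detection limits).
#' @param cis_gene_count Number of genes whose mRNA/protein levels track
#'   their own copy number.
#' @param cis_effect_slope Log2 expression change per copy relative to
#'   diploid.
#' @param kinase_count,substrates_per_kinase Planted kinases and their
#'   annotated substrate sites.
#' @param kinase_effect Log2 shift of a kinase's substrate sites in the
#'   subtype where it is active.
#' @param instability_targets List of per-subtype target lists with fields
#'   `ploidy`, `wgd_prob`, `hrd_loh`, `lst`, `tai`, `n_gain`, `n_loss`.
#' @param survival_hazards Per-subtype exponential hazard rates (events per
#'   month) for overall survival; recurrence-free survival uses 1.5x the
#'   rate.
#' @param censor_max Administrative censoring horizon (months).
#' @param segment_mode `"stochastic"` (Poisson-drawn lesion counts) or
#'   `"deterministic"` (exact targets).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 60,
                              n_subtypes = 3,
                              samples_per_plex = 16,
                              n_proteins = 1500,
                              n_phosphosites = 1000,
                              n_mrna = 1500,
                              signature_size = 50,
                              signature_effect = 1.0,
                              batch_effect_sd = 0.3,
                              noise_sd = 0.5,
                              ref_noise_sd = 0.1,
                              missing_rate = 0.2,
                              missing_mode = c("random", "intensity_dependent"),
                              cis_gene_count = 100,
                              cis_effect_slope = 0.5,
                              kinase_count = 10,
                              substrates_per_kinase = 10,
                              kinase_effect = 1.0,
                              instability_targets = NULL,
                              survival_hazards = c(0.02, 0.12, 0.06),
                              censor_max = 120,
                              segment_mode = c("stochastic", "deterministic"),
                              seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  segment_mode <- match.arg(segment_mode)
  if (samples_per_plex < 2) stop("samples_per_plex must be >= 2", call. = FALSE)
  if (signature_size > n_proteins) {
    stop("signature_size exceeds n_proteins", call. = FALSE)
  }
  counts <- c(n_samples, n_subtypes, n_proteins, n_phosphosites, n_mrna,
              signature_size, cis_gene_count, kinase_count, substrates_per_kinase)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must be in [0, 1]", call. = FALSE)
  }
  n_genes <- max(n_proteins, n_mrna)
  if (n_subtypes * signature_size + 2 * cis_gene_count > n_genes) {
    stop("signature and cis gene blocks exceed the gene universe", call. = FALSE)
  }
  if (is.null(instability_targets)) {
    instability_targets <- default_instability_targets(n_subtypes)
  }
  if (length(survival_hazards) != n_subtypes) {
    stop("survival_hazards must have one rate per subtype", call. = FALSE)
  }
  cfg <- list(
    n_samples = n_samples, n_subtypes = n_subtypes,
    samples_per_plex = samples_per_plex, n_proteins = n_proteins,
    n_phosphosites = n_phosphosites, n_mrna = n_mrna,
    signature_size = signature_size, signature_effect = signature_effect,
    batch_effect_sd = batch_effect_sd, noise_sd = noise_sd,
    ref_noise_sd = ref_noise_sd,
    missing_rate = missing_rate, missing_mode = missing_mode,
    cis_gene_count = cis_gene_count, cis_effect_slope = cis_effect_slope,
    kinase_count = kinase_count, substrates_per_kinase = substrates_per_kinase,
    kinase_effect = kinase_effect, instability_targets = instability_targets,
    survival_hazards = survival_hazards, censor_max = censor_max,
    segment_mode = segment_mode, seed = as.integer(seed))
  structure(cfg, class = "simulation_config")
}

# Subtype 1 genomically stable; later subtypes increasingly unstable with
# whole-genome doubling, mirroring the low/high instability split such
# cohorts show.
default_instability_targets <- function(n_subtypes) {
  base <- list(
    list(ploidy = 2.0, wgd_prob = 0.0, hrd_loh = 1, lst = 2, tai = 1,
         n_gain = 4, n_loss = 2),
    list(ploidy = 3.6, wgd_prob = 0.7, hrd_loh = 8, lst = 12, tai = 6,
         n_gain = 18, n_loss = 4),
    list(ploidy = 3.0, wgd_prob = 0.4, hrd_loh = 6, lst = 8, tai = 4,
         n_gain = 12, n_loss = 6)
  )
  if (n_subtypes <= 3) return(base[seq_len(n_subtypes)])
  c(base, rep(base[3], n_subtypes - 3))
}

# ---------------------------------------------------------------------------
# Segment simulation

# Lesion geometry (bp). Chosen so each lesion type moves exactly one score:
# copy-neutral LOH is invisible to total-CN-based LST; telomeric imbalance is
# kept below the LST flank minimum; LST insertions are balanced (no TAI) and
# interstitial (with one near-telomere variant for odd counts); CIN filler
# lesions are below both the LST flank and HRD-LOH length thresholds.
LESION_LEN <- list(loh = 20e6, lst = 12e6, tai = 8e6, small = 5e6)
LESION_BUFFER <- 12e6

#' Simulate one sample's allele-specific segment profile
#'
#' Builds a full-coverage autosomal profile whose instability scores hit the
#' requested targets: exactly in `"deterministic"` mode, in expectation
#' (Poisson-drawn counts) in `"stochastic"` mode. The background is diploid
#' (1+1), or tetraploid (2+2) for whole-genome-doubled samples.
#'
#' @param targets List with `wgd_prob` (or logical `wgd`), `hrd_loh`, `lst`,
#'   `tai`, and optionally `n_gain`, `n_loss` (CIN component targets; must be
#'   at least the counts implied by the planted TAI/LST lesions).
#' @param genome A `genome_build`.
#' @param seed Optional integer seed (set only if non-NULL, so the function
#'   can also run inside a larger seeded simulation).
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param sample_id Sample name for the emitted profile.
#' @return A `segment_profiles` data frame for one sample.
#' @export
simulate_segments <- function(targets, genome, seed = NULL,
                              mode = c("deterministic", "stochastic"),
                              sample_id = "S1") {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  wgd <- if (!is.null(targets$wgd)) {
    isTRUE(targets$wgd)
  } else if (mode == "stochastic") {
    stats::runif(1) < (targets$wgd_prob %||% 0)
  } else {
    (targets$wgd_prob %||% 0) >= 0.5
  }
  draw <- function(x) {
    x <- x %||% 0
    if (mode == "stochastic") stats::rpois(1, x) else as.integer(x)
  }
  n_loh <- draw(targets$hrd_loh)
  n_lst <- draw(targets$lst)
  n_tai <- draw(targets$tai)
  implied_gain <- n_tai + ceiling(n_lst / 2)
  n_loss <- draw(targets$n_loss)
  if (is.null(targets$n_gain)) {
    n_gain <- implied_gain
  } else if (mode == "stochastic") {
    # extra gains beyond those implied by the TAI/LST lesions, so the total
    # still matches the target in expectation
    expected_implied <- (targets$tai %||% 0) + ceiling((targets$lst %||% 0) / 2)
    n_gain <- implied_gain + stats::rpois(1, max(0, targets$n_gain - expected_implied))
  } else {
    n_gain <- as.integer(targets$n_gain)
    if (n_gain < implied_gain) {
      stop(sprintf(paste0("unachievable targets: n_gain (%d) below the %d gains ",
                          "implied by the TAI/LST lesions"), n_gain, implied_gain),
           call. = FALSE)
    }
  }

  bg <- if (wgd) c(2L, 2L) else c(1L, 1L)  # (major, minor)
  bg_total <- sum(bg)
  # lesion states on the background (major, minor)
  st <- if (wgd) {
    list(loh = c(4L, 0L), lst = c(3L, 3L), tai = c(3L, 1L),
         gain = c(3L, 3L), loss = c(0L, 0L))
  } else {
    list(loh = c(2L, 0L), lst = c(2L, 2L), tai = c(2L, 1L),
         gain = c(2L, 2L), loss = c(0L, 0L))
  }

  arms <- genome_arms(genome)
  arms <- arms[arms$is_autosome, , drop = FALSE]
  arms <- arms[order(-(arms$end - arms$start)), ]
  cursor <- arms$start + LESION_BUFFER
  limit <- arms$end - LESION_BUFFER
  q_telo_used <- rep(FALSE, nrow(arms))

  lesions <- list()
  add_lesion <- function(chrom, start, end, state) {
    lesions[[length(lesions) + 1]] <<- data.frame(
      chrom = chrom, start = start, end = end,
      total_cn = sum(state), major_cn = state[1], minor_cn = state[2],
      stringsAsFactors = FALSE)
  }
  alloc_interstitial <- function(len, what) {
    for (i in seq_len(nrow(arms))) {
      if (cursor[i] + len <= limit[i]) {
        s <- cursor[i]
        cursor[i] <<- cursor[i] + len + LESION_BUFFER
        return(c(i, s))
      }
    }
    stop("unachievable targets: no arm has capacity for a ", what,
         " lesion of ", len / 1e6, " Mb", call. = FALSE)
  }

  # telomeric allelic imbalance: p-arm telomere slots, then q-arm telomeres
  p_arms <- which(arms$arm == "p" & arms$start == 0 &
                    arms$end >= LESION_LEN$tai + LESION_BUFFER)
  q_arms <- which(arms$arm == "q")
  if (n_tai > 0) {
    slots_p <- p_arms[seq_len(min(n_tai, length(p_arms)))]
    for (i in slots_p) {
      add_lesion(arms$chrom[i], 0, LESION_LEN$tai, st$tai)
      cursor[i] <- max(cursor[i], LESION_LEN$tai + LESION_BUFFER)
    }
    remaining <- n_tai - length(slots_p)
    if (remaining > 0) {
      slots_q <- q_arms[seq_len(min(remaining, length(q_arms)))]
      for (i in slots_q) {
        chrom_len <- arms$end[i]
        add_lesion(arms$chrom[i], chrom_len - LESION_LEN$tai, chrom_len, st$tai)
        limit[i] <- min(limit[i], chrom_len - LESION_LEN$tai - LESION_BUFFER)
        q_telo_used[i] <- TRUE
        remaining <- remaining - 1
      }
      if (remaining > 0) {
        stop("unachievable targets: more TAI lesions than telomere slots",
             call. = FALSE)
      }
    }
  }

  # LST: pairs of junctions from interstitial insertions; odd remainder from
  # one q-telomere insertion contributing a single junction
  n_lst_insert <- ceiling(n_lst / 2)
  if (n_lst %% 2 == 1) {
    i <- q_arms[!q_telo_used[q_arms] &
                  limit[q_arms] - cursor[q_arms] >= 0][1]
    if (is.na(i)) {
      stop("unachievable targets: no free q-telomere for the odd LST junction",
           call. = FALSE)
    }
    chrom_len <- arms$end[i]
    add_lesion(arms$chrom[i], chrom_len - LESION_LEN$lst, chrom_len, st$lst)
    limit[i] <- min(limit[i], chrom_len - LESION_LEN$lst - LESION_BUFFER)
    q_telo_used[i] <- TRUE
    n_lst_insert <- n_lst_insert - 1
  }
  for (k in seq_len(n_lst_insert)) {
    hit <- alloc_interstitial(LESION_LEN$lst, "LST")
    add_lesion(arms$chrom[hit[1]], hit[2], hit[2] + LESION_LEN$lst, st$lst)
  }

  # HRD-LOH: interstitial copy-neutral LOH exceeding 15 Mb
  for (k in seq_len(n_loh)) {
    hit <- alloc_interstitial(LESION_LEN$loh, "LOH")
    add_lesion(arms$chrom[hit[1]], hit[2], hit[2] + LESION_LEN$loh, st$loh)
  }

  # CIN filler: short gains/losses below every other threshold
  for (k in seq_len(n_gain - implied_gain)) {
    hit <- alloc_interstitial(LESION_LEN$small, "gain")
    add_lesion(arms$chrom[hit[1]], hit[2], hit[2] + LESION_LEN$small, st$gain)
  }
  for (k in seq_len(n_loss)) {
    hit <- alloc_interstitial(LESION_LEN$small, "loss")
    add_lesion(arms$chrom[hit[1]], hit[2], hit[2] + LESION_LEN$small, st$loss)
  }

  # assemble: background fills everything not covered by a lesion
  les <- if (length(lesions)) do.call(rbind, lesions) else NULL
  segs <- list()
  autos <- genome[genome$is_autosome, ]
  for (ci in seq_len(nrow(autos))) {
    chrom <- autos$chrom[ci]
    len <- autos$length[ci]
    cl <- if (is.null(les)) NULL else les[les$chrom == chrom, , drop = FALSE]
    if (is.null(cl) || !nrow(cl)) {
      segs[[chrom]] <- data.frame(chrom = chrom, start = 0, end = len,
                                  total_cn = bg_total, major_cn = bg[1],
                                  minor_cn = bg[2], stringsAsFactors = FALSE)
      next
    }
    cl <- cl[order(cl$start), ]
    pieces <- list()
    pos <- 0
    for (j in seq_len(nrow(cl))) {
      if (cl$start[j] > pos) {
        pieces[[length(pieces) + 1]] <- data.frame(
          chrom = chrom, start = pos, end = cl$start[j], total_cn = bg_total,
          major_cn = bg[1], minor_cn = bg[2], stringsAsFactors = FALSE)
      }
      pieces[[length(pieces) + 1]] <- cl[j, ]
      pos <- cl$end[j]
    }
    if (pos < len) {
      pieces[[length(pieces) + 1]] <- data.frame(
        chrom = chrom, start = pos, end = len, total_cn = bg_total,
        major_cn = bg[1], minor_cn = bg[2], stringsAsFactors = FALSE)
    }
    segs[[chrom]] <- do.call(rbind, pieces)
  }
  out <- do.call(rbind, segs)
  out$sample <- sample_id
  segment_profiles(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Cohort simulation

#' Simulate a full synthetic cohort with planted truth
#'
#' Emits every input the analysis chain consumes: protein/phosphosite/mRNA
#' abundance matrices, gene-level copy-number values, sample metadata with
#' TMT plex structure and survival endpoints, allele-specific segment
#' profiles, a kinase-substrate map, gene sets over the planted signatures,
#' an alteration call matrix, and the `truth` record of everything planted.
#'
#' Pooled-reference channels equal, before noise and batch effects, the
#' arithmetic mean (on the intensity scale) of their plex's tumor channels —
#' the premise internal reference scaling relies on.
#'
#' @param config A [simulation_config()].
#' @return List with elements `protein`, `phospho`, `mrna`, `cna`
#'   (`omics_matrix`), `samples` (`sample_table`), `segments`
#'   (`segment_profiles`), `ks_map` (`kinase_substrate_map`), `gene_sets`
#'   (`gene_set_collection`), `alterations` (`alteration_matrix`), `truth`
#'   (list of planted parameters).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_samples
  K <- config$n_subtypes

  tumor_ids <- sprintf("S%03d", seq_len(n))
  labels <- rep(seq_len(K), length.out = n)
  labels <- labels[order(stats::runif(n))]  # shuffle subtype over samples
  names(labels) <- tumor_ids

  tumors_per_plex <- config$samples_per_plex - 1L
  n_plex <- ceiling(n / tumors_per_plex)
  plex_of <- rep(seq_len(n_plex), each = tumors_per_plex)[seq_len(n)]
  ref_ids <- sprintf("REF_P%d", seq_len(n_plex))

  gene_universe <- sprintf("G%04d", seq_len(max(config$n_proteins, config$n_mrna)))
  sig_genes <- lapply(seq_len(K), function(k) {
    gene_universe[((k - 1) * config$signature_size + 1):(k * config$signature_size)]
  })
  cis_start <- K * config$signature_size
  cis_genes <- gene_universe[(cis_start + 1):(cis_start + config$cis_gene_count)]
  null_cna_genes <- gene_universe[(cis_start + config$cis_gene_count + 1):
                                    (cis_start + 2 * config$cis_gene_count)]

  # --- gene-level copy number (cis + null genes) --------------------------
  # Per-gene copy numbers jitter around diploid independently of subtype, so
  # the cis effect adds CNA-tracking expression without planting sample
  # structure beyond the K subtypes (the subtype-linked instability lives in
  # the segment profiles).
  wgd_draw <- stats::runif(n) < vapply(config$instability_targets[labels],
                                       function(t) t$wgd_prob %||% 0, 0)
  cna_genes <- c(cis_genes, null_cna_genes)
  cn_mat <- matrix(pmax(0L, 2L + sample(c(-2L, -1L, 0L, 0L, 1L, 2L),
                                        length(cna_genes) * n, replace = TRUE)),
                   length(cna_genes), n, dimnames = list(cna_genes, tumor_ids))
  cna <- omics_matrix(cn_mat + 0, "raw_intensity", "cna_gene")

  # --- expression layers ---------------------------------------------------
  make_layer <- function(feat_genes, feat_ids, sig_effect, kind,
                         cis_slope = 0, extra_shift = NULL) {
    p <- length(feat_ids)
    base <- stats::rnorm(p, 20, 1.5)
    x <- matrix(base, p, n, dimnames = list(feat_ids, tumor_ids))
    for (k in seq_len(K)) {
      rows <- which(feat_genes %in% sig_genes[[k]])
      cols <- which(labels == k)
      if (length(rows) && length(cols)) {
        x[rows, cols] <- x[rows, cols] + sig_effect
      }
    }
    if (cis_slope != 0) {
      rows <- which(feat_genes %in% cis_genes)
      gidx <- match(feat_genes[rows], rownames(cn_mat))
      x[rows, ] <- x[rows, ] + cis_slope * (cn_mat[gidx, , drop = FALSE] - 2)
    }
    if (!is.null(extra_shift)) x <- x + extra_shift
    x
  }

  prot_genes <- gene_universe[seq_len(config$n_proteins)]
  prot_true <- make_layer(prot_genes, prot_genes, config$signature_effect,
                          "protein", cis_slope = 0.7 * config$cis_effect_slope)

  # phosphosites: attached to random genes; kinase substrates are dedicated
  # sites, disjoint from the subtype signature sites
  n_ph <- config$n_phosphosites
  ph_gene_idx <- sample(length(gene_universe), n_ph, replace = TRUE)
  ph_genes <- gene_universe[ph_gene_idx]
  ph_sites <- sprintf("%s_S%d", ph_genes, sample(1:999, n_ph, replace = TRUE))
  ph_sites <- make.unique(ph_sites, sep = "x")  # guard against collisions
  # subtype signatures on the first K*signature_size sites
  ph_sig_rows <- lapply(seq_len(K), function(k) {
    ((k - 1) * config$signature_size + 1):(k * config$signature_size)
  })
  kin_ids <- sprintf("KIN%02d", seq_len(config$kinase_count))
  kin_subtype <- rep(seq_len(K), length.out = config$kinase_count)
  kin_rows_start <- K * config$signature_size
  kin_rows <- lapply(seq_len(config$kinase_count), function(j) {
    (kin_rows_start + (j - 1) * config$substrates_per_kinase + 1):
      (kin_rows_start + j * config$substrates_per_kinase)
  })
  if (max(unlist(kin_rows)) > n_ph) {
    stop("not enough phosphosites for signatures plus kinase substrates",
         call. = FALSE)
  }
  ph_shift <- matrix(0, n_ph, n)
  for (k in seq_len(K)) {
    ph_shift[ph_sig_rows[[k]], labels == k] <-
      ph_shift[ph_sig_rows[[k]], labels == k] + config$signature_effect
  }
  for (j in seq_len(config$kinase_count)) {
    ph_shift[kin_rows[[j]], labels == kin_subtype[j]] <-
      ph_shift[kin_rows[[j]], labels == kin_subtype[j]] + config$kinase_effect
  }
  ph_true <- matrix(stats::rnorm(n_ph, 20, 1.5), n_ph, n,
                    dimnames = list(ph_sites, tumor_ids)) + ph_shift

  mrna_genes <- gene_universe[seq_len(config$n_mrna)]
  mrna_true <- make_layer(mrna_genes, mrna_genes, 2 * config$signature_effect,
                          "mrna", cis_slope = config$cis_effect_slope)

  # --- TMT assembly: reference channels, batch effects, noise, missingness -
  assemble_tmt <- function(true_log2) {
    p <- nrow(true_log2)
    ref <- matrix(NA_real_, p, n_plex, dimnames = list(rownames(true_log2), ref_ids))
    for (pl in seq_len(n_plex)) {
      cols <- which(plex_of == pl)
      ref[, pl] <- log2(rowMeans(2^true_log2[, cols, drop = FALSE]))
    }
    full <- cbind(true_log2, ref)
    plex_all <- c(plex_of, seq_len(n_plex))
    batch <- matrix(stats::rnorm(p * n_plex, 0, config$batch_effect_sd), p, n_plex)
    full <- full + batch[, plex_all]
    noise_sd_by_col <- c(rep(config$noise_sd, n), rep(config$ref_noise_sd, n_plex))
    full <- full + matrix(stats::rnorm(length(full)), nrow(full)) *
      rep(noise_sd_by_col, each = nrow(full))
    # missingness on tumor channels only
    tum <- full[, seq_len(n), drop = FALSE]
    if (config$missing_rate > 0) {
      if (config$missing_mode == "random") {
        drop <- matrix(stats::runif(length(tum)) < config$missing_rate,
                       nrow(tum), ncol(tum))
      } else {
        thr <- stats::quantile(tum, config$missing_rate)
        pm <- stats::plogis(-(tum - thr) / 0.5)
        pm <- pm * config$missing_rate / mean(pm)
        drop <- matrix(stats::runif(length(tum)) < pm, nrow(tum), ncol(tum))
      }
      tum[drop] <- NA
      full[, seq_len(n)] <- tum
    }
    omics_matrix(2^full, "raw_intensity",
                 if (identical(rownames(true_log2), ph_sites)) "phosphosite" else "protein")
  }
  protein <- assemble_tmt(prot_true)
  phospho <- assemble_tmt(ph_true)
  mrna <- omics_matrix(mrna_true + stats::rnorm(length(mrna_true), 0, config$noise_sd),
                       "log2", "mrna")

  # --- sample metadata and survival ---------------------------------------
  haz <- config$survival_hazards[labels]
  os_raw <- stats::rexp(n, haz)
  os_cens <- stats::runif(n, 0, config$censor_max)
  rfs_raw <- stats::rexp(n, 1.5 * haz)
  rfs_cens <- stats::runif(n, 0, config$censor_max)
  samples <- sample_table(data.frame(
    sample_id = c(tumor_ids, ref_ids),
    plex_id = sprintf("plex%d", c(plex_of, seq_len(n_plex))),
    channel_id = c(stats::ave(seq_len(n), plex_of, FUN = seq_along), rep(0L, n_plex)),
    is_pooled_reference = c(rep(FALSE, n), rep(TRUE, n_plex)),
    subtype_label = c(sprintf("P%d", labels), rep(NA_character_, n_plex)),
    tumor_status = c(sample(c("primary", "metastasis"), n, TRUE, c(0.7, 0.3)),
                     rep(NA_character_, n_plex)),
    pair_id = NA_character_,
    os_time = c(pmin(os_raw, os_cens), rep(NA_real_, n_plex)),
    os_event = c(as.integer(os_raw <= os_cens), rep(NA_integer_, n_plex)),
    rfs_time = c(pmin(rfs_raw, rfs_cens), rep(NA_real_, n_plex)),
    rfs_event = c(as.integer(rfs_raw <= rfs_cens), rep(NA_integer_, n_plex)),
    stringsAsFactors = FALSE))

  # --- segment profiles ----------------------------------------------------
  genome <- read_genome_build(system.file("extdata", "genome_grch37.tsv",
                                          package = "lmsproteo"))
  seg_targets <- vector("list", n)
  seg_list <- vector("list", n)
  for (s in seq_len(n)) {
    tg <- config$instability_targets[[labels[s]]]
    tg$wgd <- wgd_draw[s]
    seg_targets[[s]] <- tg
    seg_list[[s]] <- simulate_segments(tg, genome, seed = NULL,
                                       mode = config$segment_mode,
                                       sample_id = tumor_ids[s])
  }
  segments <- segment_profiles(do.call(rbind, seg_list))

  # --- kinase-substrate map ------------------------------------------------
  ks_map <- kinase_substrate_map(data.frame(
    kinase = rep(kin_ids, each = config$substrates_per_kinase),
    substrate = ph_genes[unlist(kin_rows)],
    site = ph_sites[unlist(kin_rows)],
    stringsAsFactors = FALSE))

  # --- gene sets over planted signatures ----------------------------------
  sets <- stats::setNames(sig_genes, sprintf("SIG_P%d", seq_len(K)))
  sets$RANDOM_1 <- sample(gene_universe, config$signature_size)
  sets$RANDOM_2 <- sample(gene_universe, config$signature_size)
  gene_sets <- gene_set_collection(sets)

  # --- alteration calls ----------------------------------------------------
  driver_genes <- sprintf("DRV%02d", 1:20)
  calls <- matrix("none", 20, n, dimnames = list(driver_genes, tumor_ids))
  alt_prob <- matrix(stats::runif(20 * K, 0.05, 0.3), 20, K)
  alt_prob[1, ] <- c(0.6, 0.75, 0.7)[seq_len(K)]   # a TP53-like common driver
  alt_prob[2, ] <- ifelse(seq_len(K) == 1, 0.05, 0.7)  # co-occurring pair
  alt_prob[3, ] <- ifelse(seq_len(K) == 1, 0.05, 0.7)
  types <- c("mutation", "amplification", "deep_deletion", "loh")
  for (g in 1:20) {
    hit <- stats::runif(n) < alt_prob[g, labels]
    calls[g, hit] <- sample(types, sum(hit), replace = TRUE)
  }
  alterations <- alteration_matrix(calls, provenance = "synthetic")

  truth <- list(
    labels = stats::setNames(sprintf("P%d", labels), tumor_ids),
    labels_int = labels,
    signature_genes = sig_genes,
    phospho_signature_sites = lapply(ph_sig_rows, function(r) ph_sites[r]),
    cis_genes = cis_genes,
    null_cna_genes = null_cna_genes,
    kinase_subtype = stats::setNames(sprintf("P%d", kin_subtype), kin_ids),
    kinase_sites = stats::setNames(lapply(kin_rows, function(r) ph_sites[r]), kin_ids),
    wgd = stats::setNames(wgd_draw, tumor_ids),
    segment_targets = stats::setNames(seg_targets, tumor_ids),
    survival_hazards = config$survival_hazards,
    seed = config$seed)

  list(protein = protein, phospho = phospho, mrna = mrna, cna = cna,
       samples = samples, segments = segments, ks_map = ks_map,
       gene_sets = gene_sets, alterations = alterations, truth = truth)
}
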