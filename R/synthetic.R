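#' Configuration for the synthetic data generator
#'
#' Builds the full parameterization of a seed-reproducible synthetic study:
#' a TE library of superfamilies with per-site transition/transversion
#' rates (so every copy has a known expected K2P divergence), six
#' developmental stages with per-TE-class read-share weights (a maternal
#' peak at the 1-cell stage, a trough around zygotic genome activation,
#' a rebound with ERV1 enrichment afterwards), a DMSO vs 5-aza-dC
#' derepression contrast with three replicates per arm, and gene sets
#' (heterochromatin, NuRD, trim33, KRAB-like, FiNZ, single-copy
#' orthologues, background) whose expression carries a programmed Pearson
#' correlation with the LTR activity trajectory.
#'
#' All stochastic outputs downstream are a pure function of this object.
#'
#' @param seed Integer seed controlling every random draw.
#' @param total_reads Mapped reads per sample before depth multipliers.
#' @param read_length Read length in bp for the developmental series (the
#'   treatment series uses `treatment_read_length`).
#' @param treatment_read_length Read length for the treatment series.
#' @param replicates Replicates per stage/arm (>= 2; ANOVA needs 2).
#' @param superfamilies Data frame describing the TE library: `name`,
#'   `class_family` (RepeatMasker label), `n_copies`, `consensus_length`,
#'   `p_true`, `q_true` (expected transition/transversion fractions of
#'   sites; must satisfy `2 p + q < 1`).
#' @param stage_class_weights 6 x 5 matrix of per-stage read-share
#'   fractions by TE class (`DNA`, `LINE`, `SINE`, `LTR`, `Unclear`);
#'   the remainder of each row is non-TE signal.
#' @param ltr_mix Per-stage composition of the LTR share across the LTR
#'   superfamilies present in the library (rows sum to 1).
#' @param treatment List with `base_weights` (class shares of the DMSO
#'   arm), `ltr_fold_change` (LTR share multiplier under 5-aza-dC; the
#'   extra mass is taken from the non-TE remainder so the other class
#'   shares are untouched), `ltr_mix` (DMSO LTR composition) and
#'   `superfamily_multipliers` (5-aza-dC reweighting of that composition,
#'   renormalized).
#' @param genes List of gene-set sizes: `n_heterochromatin`, `n_nurd`,
#'   `n_trim33`, `n_krab_like`, `n_finz`, `n_orthologues`,
#'   `n_background`.
#' @param rho Programmed Pearson correlation of each gene set's latent
#'   per-stage profile with the LTR trajectory.
#' @param silencing_fold_5aza Fold-increase of silencing-gene expression
#'   in the 5-aza-dC arm.
#' @param nb_dispersion Negative-binomial dispersion of count jitter
#'   (0 = deterministic, noise-free counts).
#' @param low_quality_fraction Fraction of extra reads emitted with poor
#'   alignment (aligned fraction 0.7) that the mapping filter must drop.
#' @param depth_multipliers Optional named per-sample depth multipliers
#'   (default 1 for every sample).
#' @param flank_length Non-repetitive flank added on each side of every
#'   embedded TE copy.
#' @param decoys Emit redundant/low-score/short/non-TE annotation rows
#'   that the redundancy filter must remove (default TRUE).
#' @return Object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(
    seed = 1,
    total_reads = 20000,
    read_length = 100,
    treatment_read_length = 150,
    replicates = 3,
    superfamilies = default_superfamilies(),
    stage_class_weights = default_stage_class_weights(),
    ltr_mix = default_ltr_mix(),
    treatment = default_treatment(),
    genes = list(n_heterochromatin = 10, n_nurd = 15, n_trim33 = 1,
                 n_krab_like = 8, n_finz = 10, n_orthologues = 2111,
                 n_background = 1200),
    rho = c(heterochromatin = 0.9, NuRD = 0.9, trim33 = 0.95,
            KRAB_like = 0.9, FiNZ = 0.3, background = 0),
    silencing_fold_5aza = 1.6,
    nb_dispersion = 0.05,
    low_quality_fraction = 0.02,
    depth_multipliers = NULL,
    flank_length = 200,
    decoys = TRUE) {
  cfg <- list(
    seed = as.integer(seed), total_reads = total_reads,
    read_length = read_length,
    treatment_read_length = treatment_read_length,
    replicates = as.integer(replicates),
    superfamilies = superfamilies,
    stage_class_weights = stage_class_weights,
    ltr_mix = ltr_mix, treatment = treatment, genes = genes, rho = rho,
    silencing_fold_5aza = silencing_fold_5aza,
    nb_dispersion = nb_dispersion,
    low_quality_fraction = low_quality_fraction,
    depth_multipliers = depth_multipliers,
    flank_length = flank_length, decoys = decoys
  )
  validate_sim_config(cfg)
}

#' @rdname simulation_config
#' @export
default_superfamilies <- function() {
  data.frame(
    name = c("ERV1", "ERV2", "Gypsy", "Copia", "DIRS",
             "L1", "Rex", "SINE2", "hAT", "Tc1", "UnkRep"),
    class_family = c("LTR/ERV1", "LTR/ERV2", "LTR/Gypsy", "LTR/Copia",
                     "LTR/DIRS", "LINE/L1", "LINE/Rex-Babar", "SINE/tRNA",
                     "DNA/hAT-Ac", "DNA/TcMar-Tc1", "Unknown"),
    n_copies = c(10, 8, 8, 6, 6, 8, 6, 8, 8, 8, 6),
    consensus_length = c(1000, 1000, 1000, 800, 800,
                         1200, 1000, 500, 900, 900, 700),
    p_true = c(0.02, 0.04, 0.10, 0.12, 0.06,
               0.12, 0.08, 0.10, 0.14, 0.10, 0.12),
    q_true = c(0.01, 0.02, 0.05, 0.06, 0.03,
               0.06, 0.04, 0.05, 0.07, 0.05, 0.06),
    stringsAsFactors = FALSE
  )
}

#' @rdname simulation_config
#' @export
default_stage_class_weights <- function() {
  m <- rbind(
    zygote        = c(0.040, 0.020, 0.010, 0.045, 0.010),
    blastula      = c(0.012, 0.006, 0.003, 0.012, 0.003),
    gastrula      = c(0.020, 0.012, 0.006, 0.040, 0.006),
    somitogenesis = c(0.022, 0.012, 0.006, 0.044, 0.006),
    pharyngula    = c(0.020, 0.010, 0.006, 0.042, 0.006),
    larva         = c(0.018, 0.010, 0.005, 0.038, 0.005)
  )
  colnames(m) <- te_classes()
  m
}

#' @rdname simulation_config
#' @export
default_ltr_mix <- function() {
  m <- rbind(
    zygote        = c(0.20, 0.20, 0.25, 0.15, 0.20),
    blastula      = c(0.20, 0.20, 0.25, 0.15, 0.20),
    gastrula      = c(0.45, 0.15, 0.15, 0.10, 0.15),
    somitogenesis = c(0.50, 0.15, 0.10, 0.10, 0.15),
    pharyngula    = c(0.50, 0.15, 0.10, 0.10, 0.15),
    larva         = c(0.45, 0.15, 0.15, 0.10, 0.15)
  )
  colnames(m) <- c("ERV1", "ERV2", "Gypsy", "Copia", "DIRS")
  m
}

#' @rdname simulation_config
#' @export
default_treatment <- function() {
  list(
    conditions = c("DMSO", "5Aza"),
    base_weights = c(DNA = 0.020, LINE = 0.010, SINE = 0.005,
                     LTR = 0.025, Unclear = 0.005),
    ltr_fold_change = 3,
    ltr_mix = c(ERV1 = 0.30, ERV2 = 0.20, Gypsy = 0.20,
                Copia = 0.15, DIRS = 0.15),
    superfamily_multipliers = c(ERV1 = 1.3, ERV2 = 1.3, Gypsy = 0.8,
                                Copia = 0.8, DIRS = 1.4)
  )
}

validate_sim_config <- function(cfg) {
  sf <- cfg$superfamilies
  if (any(sf$p_true < 0 | sf$q_true < 0 |
            2 * sf$p_true + sf$q_true >= 1)) {
    stop("invalid substitution rates: need p, q >= 0 and 2p + q < 1")
  }
  if (cfg$replicates < 2L) {
    stop("replicates must be >= 2 (ANOVA needs at least 2 per group)")
  }
  w <- cfg$stage_class_weights
  if (!identical(colnames(w), te_classes())) {
    stop("stage_class_weights columns must be ", paste(te_classes(),
                                                       collapse = ", "))
  }
  if (any(w < 0) || any(rowSums(w) >= 1)) {
    stop("stage class weights must be non-negative with row sums < 1")
  }
  if (any(abs(rowSums(cfg$ltr_mix) - 1) > 1e-9)) {
    stop("ltr_mix rows must sum to 1")
  }
  tr <- cfg$treatment
  aza_ltr <- tr$base_weights[["LTR"]] * tr$ltr_fold_change
  if (sum(tr$base_weights) - tr$base_weights[["LTR"]] + aza_ltr >= 1) {
    stop("treatment LTR fold change pushes total TE share to >= 1")
  }
  if (cfg$nb_dispersion < 0 || cfg$low_quality_fraction < 0 ||
        cfg$low_quality_fraction >= 1) {
    stop("invalid noise configuration")
  }
  class(cfg) <- "sim_config"
  cfg
}

# deterministic largest-remainder allocation of `total` into proportions w
allocate_exact <- function(total, w) {
  if (sum(w) == 0) return(integer(length(w)))
  target <- total * w / sum(w)
  base <- floor(target)
  rem <- target - base
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    ord <- order(-rem, seq_along(w))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

#' Simulate a TE library: consensus sequences, diverged copies, annotation
#'
#' Each superfamily gets a random consensus; each copy mutates every
#' consensus site independently -- a transition with probability `p_true`,
#' a transversion (uniform over the two options) with probability
#' `q_true` -- so the expected K2P divergence of a copy is the closed form
#' evaluated at the generating rates. Copies are embedded in contigs with
#' non-repetitive flanks and described by RepeatMasker-style annotation
#' rows with correct coordinates and class labels. With `decoys = TRUE`
#' the annotation additionally carries redundant lower-score overlaps,
#' sub-threshold short matches, and non-TE rows that the redundancy filter
#' is expected to remove.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return Object of class `te_simulation`: list with `consensus` and
#'   `contigs` (named character vectors), `annotation` (a
#'   `te_annotation`, decoys included), `pairs` (copy/consensus aligned
#'   pairs), and `truth` (per-copy data frame with expected and realized
#'   p, q, K).
#' @export
simulate_te_copies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_te_copies_impl(config))
}

simulate_te_copies_impl <- function(cfg) {
  sf <- cfg$superfamilies
  fl <- cfg$flank_length
  consensus <- character(0)
  contigs <- character(0)
  ann <- list(); pairs <- list(); truth <- list()
  rm_id <- 0L
  copy_no <- 0L
  for (i in seq_len(nrow(sf))) {
    L <- sf$consensus_length[i]
    cons <- rand_dna(L)
    consensus[[sf$name[i]]] <- cons
    cons_v <- strsplit(cons, "")[[1]]
    for (j in seq_len(sf$n_copies[i])) {
      copy_no <- copy_no + 1L
      u <- stats::runif(L)
      v <- stats::runif(L)
      cp <- cons_v
      is_ts <- u < sf$p_true[i]
      is_tv <- !is_ts & u < sf$p_true[i] + sf$q_true[i]
      cp[is_ts] <- TRANSITION[cons_v[is_ts]]
      if (any(is_tv)) {
        cp[is_tv] <- mapply(function(b, vv) TRANSVERSIONS[[b]][1 + (vv > 0.5)],
                            cons_v[is_tv], v[is_tv])
      }
      copy <- paste(cp, collapse = "")
      ctg <- paste0("contig_", sf$name[i], "_", j)
      contigs[[ctg]] <- paste0(rand_dna(fl), copy, rand_dna(fl))
      p_real <- sum(is_ts) / L
      q_real <- sum(is_tv) / L
      div <- 100 * (p_real + q_real)
      rm_id <- rm_id + 1L
      ann[[length(ann) + 1L]] <- data.frame(
        contig_id = ctg, start = fl, end = fl + L, strand = "+",
        sw_score = round(2 * L * (1 - div / 100)),
        pct_divergence = round(div, 1), pct_deleted = 0, pct_inserted = 0,
        repeat_name = paste0(sf$name[i], "-cons"),
        repeat_class_family = sf$class_family[i],
        repeat_start = 1, repeat_end = L, repeat_left = 0,
        rm_id = rm_id, overlap_flag = FALSE, stringsAsFactors = FALSE
      )
      pairs[[length(pairs) + 1L]] <- data.frame(
        entry_id = ctg, copy = copy, consensus = cons,
        stringsAsFactors = FALSE
      )
      truth[[length(truth) + 1L]] <- data.frame(
        entry_id = ctg, family = sf$name[i],
        class_family = sf$class_family[i],
        p_true = sf$p_true[i], q_true = sf$q_true[i],
        K_expected = kimura_k2p(sf$p_true[i], sf$q_true[i]),
        p_realized = p_real, q_realized = q_real,
        K_realized = kimura_k2p(p_real, q_real),
        stringsAsFactors = FALSE
      )
      if (cfg$decoys) {
        base <- ann[[length(ann)]]
        if (copy_no %% 3L == 0L) {
          # redundant overlapping hit with a lower score
          d <- base
          d$start <- base$start + 50; d$end <- base$end - 20
          d$sw_score <- base$sw_score - 200
          rm_id <- rm_id + 1L; d$rm_id <- rm_id; d$overlap_flag <- TRUE
          ann[[length(ann) + 1L]] <- d
        }
        if (copy_no %% 4L == 0L) {
          # non-TE annotation row in the right flank
          d <- base
          d$start <- base$end + 40; d$end <- base$end + 100
          d$sw_score <- 25; d$repeat_name <- "(TA)n"
          d$repeat_class_family <- "Simple_repeat"
          rm_id <- rm_id + 1L; d$rm_id <- rm_id
          ann[[length(ann) + 1L]] <- d
        }
        if (copy_no %% 5L == 0L) {
          # short TE match at the length threshold (must be dropped)
          d <- base
          d$start <- base$end + 110; d$end <- base$end + 190
          d$sw_score <- 120; d$repeat_class_family <- "SINE/tRNA"
          d$repeat_name <- "SINE2-frag"
          rm_id <- rm_id + 1L; d$rm_id <- rm_id
          ann[[length(ann) + 1L]] <- d
        }
      }
    }
  }
  annotation <- do.call(rbind, ann)
  class(annotation) <- c("te_annotation", "data.frame")
  structure(list(
    config = cfg,
    consensus = consensus,
    contigs = contigs,
    annotation = annotation,
    pairs = do.call(rbind, pairs),
    truth = do.call(rbind, truth)
  ), class = "te_simulation")
}

#' Simulate the read-alignment and gene-expression study
#'
#' Generates, per sample, TE-assigned read alignments drawn from the
#' stage- (or treatment-arm-) specific class weights, filler reads in the
#' non-repetitive flanks, and optionally low-quality reads the mapping
#' filter must discard; plus a gene x sample count matrix in which
#' single-copy orthologues are constant up to the injected depth
#' multiplier, silencing genes track the LTR activity trajectory with the
#' programmed correlation, and the 5-aza-dC arm carries both the LTR
#' fold-change and the configured silencing-gene response. With
#' `nb_dispersion = 0` every count is a deterministic exact allocation,
#' so the recovered stage x class percentage matrix equals the configured
#' one exactly.
#'
#' @param config A `sim_config`.
#' @param te_sim Result of [simulate_te_copies()] for the same config
#'   (regenerated if omitted).
#' @return Object of class `expression_simulation`: list with
#'   `sample_sheet`, `alignments` (named list of `read_alignment` data
#'   frames), `gene_counts`, `gene_lengths`, `gene_sets`, and `truth`
#'   (configured/realized class shares, per-entry counts, depths,
#'   programmed correlations, LTR trajectory).
#' @export
simulate_expression <- function(config, te_sim = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(te_sim)) te_sim <- simulate_te_copies(config)
  with_seed(config$seed + 1L, simulate_expression_impl(config, te_sim))
}

simulate_expression_impl <- function(cfg, te_sim) {
  stages <- rownames(cfg$stage_class_weights)
  reps <- cfg$replicates
  sheet <- rbind(
    expand.grid(replicate = seq_len(reps), stage = stages,
                stringsAsFactors = FALSE)[, 2:1],
    data.frame(stage = "12hpf",
               replicate = rep(seq_len(reps), times = 2))
  )
  sheet$condition <- c(rep("none", length(stages) * reps),
                       rep(cfg$treatment$conditions, each = reps))
  sheet$experiment <- ifelse(sheet$condition == "none",
                             "development", "treatment")
  sheet$sample <- ifelse(sheet$experiment == "development",
                         paste0(sheet$stage, "_rep", sheet$replicate),
                         paste0(sheet$condition, "_rep", sheet$replicate))
  sheet$read_length <- ifelse(sheet$experiment == "development",
                              cfg$read_length, cfg$treatment_read_length)
  depth <- cfg$depth_multipliers
  if (is.null(depth)) depth <- stats::setNames(rep(1, nrow(sheet)),
                                               sheet$sample)
  sheet$depth <- unname(depth[sheet$sample])
  sheet <- sheet[, c("sample", "stage", "condition", "replicate",
                     "experiment", "read_length", "depth")]
  rownames(sheet) <- NULL

  ann <- te_sim$annotation
  keep <- !ann$overlap_flag &
    classify_te(ann$repeat_class_family)$te_class != "NotTE" &
    (ann$end - ann$start) > 80
  entries <- ann[keep, , drop = FALSE]  # the true (non-decoy) copies
  ecls <- classify_te(entries$repeat_class_family)
  fam <- sub("-cons$", "", entries$repeat_name)

  cls_names <- te_classes()
  disp <- cfg$nb_dispersion
  aln <- list()
  class_counts <- matrix(0L, nrow(sheet), length(cls_names),
                         dimnames = list(sheet$sample, cls_names))
  entry_counts <- matrix(0L, nrow(sheet), nrow(entries),
                         dimnames = list(sheet$sample, entries$contig_id))
  totals <- integer(nrow(sheet))

  arm_weights <- function(s) {
    if (s$experiment == "development") {
      w <- cfg$stage_class_weights[s$stage, ]
      mix <- cfg$ltr_mix[s$stage, ]
    } else {
      w <- cfg$treatment$base_weights[cls_names]
      mix <- cfg$treatment$ltr_mix
      if (s$condition == "5Aza") {
        w[["LTR"]] <- w[["LTR"]] * cfg$treatment$ltr_fold_change
        mix <- mix * cfg$treatment$superfamily_multipliers[names(mix)]
        mix <- mix / sum(mix)
      }
    }
    list(w = w, mix = mix)
  }

  for (si in seq_len(nrow(sheet))) {
    s <- sheet[si, ]
    rl <- s$read_length
    total <- as.integer(round(cfg$total_reads * s$depth))
    aw <- arm_weights(s)
    w <- aw$w
    if (disp == 0) {
      ccounts <- as.integer(round(total * w))  # exact by configuration
    } else {
      mu <- total * w
      ccounts <- stats::rnbinom(length(w), mu = mu, size = 1 / disp)
      ccounts <- pmin(ccounts, as.integer(floor(3 * mu + 10)))
    }
    names(ccounts) <- cls_names
    class_counts[si, ] <- ccounts
    totals[si] <- total

    # split each class count over its entries (LTR via the superfamily mix)
    ec <- integer(nrow(entries))
    for (cl in cls_names) {
      sel <- which(ecls$te_class == cl)
      if (!length(sel) || ccounts[[cl]] == 0) next
      if (cl == "LTR") {
        mix <- aw$mix
        per_sf <- allocate_exact(ccounts[[cl]], mix)
        for (k in seq_along(mix)) {
          msel <- sel[fam[sel] == names(mix)[k]]
          if (length(msel)) {
            ec[msel] <- allocate_exact(per_sf[k], rep(1, length(msel)))
          }
        }
      } else {
        ec[sel] <- allocate_exact(ccounts[[cl]], rep(1, length(sel)))
      }
    }
    entry_counts[si, ] <- ec

    # TE reads tiled inside their entry; filler reads in the left flank
    n_te <- sum(ec)
    n_fill <- total - n_te
    te_entry <- rep(seq_len(nrow(entries)), ec)
    within <- unlist(lapply(ec[ec > 0], function(k) seq_len(k) - 1L),
                     use.names = FALSE)
    if (n_te > 0) {
      span <- entries$end[te_entry] - entries$start[te_entry] - rl
      offs <- (within * 37L) %% (span + 1L)
      starts <- entries$start[te_entry] + offs
      te_df <- data.frame(
        read_id = sprintf("%s_te%06d", s$sample, seq_len(n_te)),
        contig_id = entries$contig_id[te_entry],
        aln_start = starts, aln_end = starts + rl,
        read_length = rl, aligned_bases = rl,
        matches = if (disp == 0) rl else
          rl - stats::rbinom(n_te, rl, 0.02),
        stringsAsFactors = FALSE
      )
    } else te_df <- NULL
    if (n_fill > 0) {
      ctg <- entries$contig_id[((seq_len(n_fill) - 1L) %%
                                  nrow(entries)) + 1L]
      fs <- 10L + ((seq_len(n_fill) - 1L) %% 7L)
      fill_df <- data.frame(
        read_id = sprintf("%s_bg%06d", s$sample, seq_len(n_fill)),
        contig_id = ctg,
        aln_start = fs, aln_end = fs + rl,
        read_length = rl, aligned_bases = rl,
        matches = if (disp == 0) rl else
          rl - stats::rbinom(n_fill, rl, 0.02),
        stringsAsFactors = FALSE
      )
    } else fill_df <- NULL
    n_lq <- as.integer(round(total * cfg$low_quality_fraction))
    if (n_lq > 0) {
      ctg <- entries$contig_id[((seq_len(n_lq) - 1L) %% nrow(entries)) + 1L]
      ab <- as.integer(floor(0.7 * rl))
      lq_df <- data.frame(
        read_id = sprintf("%s_lq%06d", s$sample, seq_len(n_lq)),
        contig_id = ctg,
        aln_start = 10L, aln_end = 10L + ab,
        read_length = rl, aligned_bases = ab, matches = ab,
        stringsAsFactors = FALSE
      )
    } else lq_df <- NULL
    x <- rbind(te_df, fill_df, lq_df)
    rownames(x) <- NULL
    aln[[s$sample]] <- validate_alignments(x)
  }

  # ---- gene expression -------------------------------------------------
  gs <- cfg$genes
  het <- c("cbx5", "cbx1a", "cbx1b", "cbx3a", "cbx3b", "dnmt1",
           "dnmt3ba", "dnmt3bb", "setdb1a", "setdb1b")
  nurd <- c("chd3", "chd4a", "chd4b", "hdac1", "hdac3", "mbd2", "mbd3a",
            "mbd3b", "mta1", "mta2", "mta3", "gatad2ab", "gatad2b",
            "rbbp4", "rbbp7")
  gene_sets <- list(
    heterochromatin = utils::head(het, gs$n_heterochromatin),
    NuRD = utils::head(nurd, gs$n_nurd),
    trim33 = if (gs$n_trim33 > 0) "trim33" else character(),
    KRAB_like = sprintf("krabl_znf%02d", seq_len(gs$n_krab_like)),
    FiNZ = sprintf("finz_znf%02d", seq_len(gs$n_finz)),
    single_copy_orthologues = sprintf("ortho_%04d",
                                      seq_len(gs$n_orthologues)),
    background = sprintf("bg_%04d", seq_len(gs$n_background))
  )
  genes <- unlist(gene_sets, use.names = FALSE)
  set_of <- rep(names(gene_sets), lengths(gene_sets))
  ngene <- length(genes)
  lengths_bp <- stats::setNames(
    10 * sample(50:300, ngene, replace = TRUE), genes)

  # latent LTR activity trajectory over the 6 developmental stages
  traj <- cfg$stage_class_weights[, "LTR"]
  zT <- as.numeric(scale(traj))
  base_expr <- stats::setNames(
    exp(stats::rnorm(ngene, mean = log(200), sd = 0.6)), genes)
  rho_of <- function(set) {
    switch(set,
           heterochromatin = cfg$rho[["heterochromatin"]],
           NuRD = cfg$rho[["NuRD"]],
           trim33 = cfg$rho[["trim33"]],
           KRAB_like = cfg$rho[["KRAB_like"]],
           FiNZ = cfg$rho[["FiNZ"]],
           background = cfg$rho[["background"]],
           single_copy_orthologues = NA_real_)
  }
  rho_g <- vapply(set_of, rho_of, numeric(1))

  # per-gene, per-stage latent profile shared by replicates
  eps <- matrix(stats::rnorm(ngene * length(stages)), ngene,
                dimnames = list(genes, stages))
  y <- matrix(0, ngene, length(stages), dimnames = list(genes, stages))
  varies <- !is.na(rho_g)
  y[varies, ] <- rho_g[varies] %o% zT +
    sqrt(1 - rho_g[varies]^2) * eps[varies, , drop = FALSE]

  gene_counts <- matrix(0, ngene, nrow(sheet),
                        dimnames = list(genes, sheet$sample))
  silencing <- set_of %in% c("heterochromatin", "NuRD", "trim33",
                             "KRAB_like", "FiNZ")
  for (si in seq_len(nrow(sheet))) {
    s <- sheet[si, ]
    if (s$experiment == "development") {
      mu <- base_expr * exp(0.5 * y[, s$stage])
    } else {
      mu <- base_expr
      if (s$condition == "5Aza") {
        mu[silencing] <- mu[silencing] * cfg$silencing_fold_5aza
      }
    }
    lambda <- mu * s$depth * lengths_bp / 1000
    gene_counts[, si] <- if (disp == 0) round(lambda) else
      stats::rnbinom(ngene, mu = lambda, size = 1 / disp)
  }

  truth <- list(
    class_counts = class_counts,
    class_percent = 100 * class_counts / totals,
    configured_percent_development =
      100 * cfg$stage_class_weights,
    entry_counts = entry_counts,
    totals = stats::setNames(totals, sheet$sample),
    depths = stats::setNames(sheet$depth, sheet$sample),
    rho = stats::setNames(rho_g, genes),
    ltr_trajectory = traj
  )
  structure(list(
    config = cfg, sample_sheet = sheet, alignments = aln,
    gene_counts = gene_counts, gene_lengths = lengths_bp,
    gene_sets = gene_sets, truth = truth
  ), class = "expression_simulation")
}

#' Write every synthetic input to disk in its standard format
#'
#' Emits FASTA (consensus library and contigs), the RepeatMasker-style
#' `.out` annotation, aligned copy/consensus FASTA pairs, one alignment
#' TSV per sample, the gene count table, sample sheet, one gene-set file
#' per set, the ground-truth JSON and the config YAML. Every file
#' round-trips through the package's readers; output is byte-identical
#' for identical config and seed.
#'
#' @param te_sim Result of [simulate_te_copies()].
#' @param expr_sim Result of [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(te_sim, expr_sim, dir) {
  dir.create(file.path(dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "gene_sets"), showWarnings = FALSE)
  write_fasta(te_sim$consensus, file.path(dir, "consensus.fasta"))
  write_fasta(te_sim$contigs, file.path(dir, "contigs.fasta"))
  write_rm_out(te_sim$annotation, file.path(dir, "annotation.out"))
  pairs <- te_sim$pairs
  inter <- stats::setNames(
    as.vector(rbind(pairs$copy, pairs$consensus)),
    as.vector(rbind(pairs$entry_id, paste0(pairs$entry_id, "_consensus"))))
  write_fasta(inter, file.path(dir, "aligned_pairs.fasta"))
  for (nm in names(expr_sim$alignments)) {
    write_alignment_tsv(expr_sim$alignments[[nm]],
                        file.path(dir, "alignments", paste0(nm, ".tsv")))
  }
  write_count_table(expr_sim$gene_counts, expr_sim$gene_lengths,
                    file.path(dir, "gene_counts.tsv"))
  utils::write.table(expr_sim$sample_sheet,
                     file.path(dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(expr_sim$gene_sets)) {
    writeLines(c(paste("#", nm), expr_sim$gene_sets[[nm]]),
               file.path(dir, "gene_sets", paste0(nm, ".txt")))
  }
  jsonlite::write_json(
    c(expr_sim$truth, list(copies = te_sim$truth)),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, matrix = "rowmajor")
  cfg <- te_sim$config
  cfg$superfamilies <- as.list(cfg$superfamilies)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

write_fasta <- function(seqs, file) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(seqs), file, width = 80L)
  } else {
    con <- file(file, "w")
    on.exit(close(con))
    for (nm in names(seqs)) {
      writeLines(c(paste0(">", nm),
                   gsub("(.{80})", "\\1\n", seqs[[nm]])), con)
    }
  }
  invisible(file)
}
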