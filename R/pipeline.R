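#' Run the full TE-activity pipeline on synthetic inputs
#'
#' Orchestrates every stage end-to-end: input generation (or reuse),
#' annotation redundancy filtering, per-sample read quantification into
#' class/superfamily profiles, K2P divergence landscapes of the expressed
#' LTR fraction, TPM computation with single-copy-orthologue scaling,
#' family-mean expression, the correlation panel with its random-gene
#' null control, and the DMSO vs 5-aza-dC ANOVA battery. All stage
#' outputs are tab-separated tables under `outdir`, and a manifest
#' records parameters, seeds and file checksums; two runs with the same
#' config produce byte-identical outputs.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @param outdir Output directory.
#' @param min_length Redundancy-filter length cutoff in bp (matches must
#'   be strictly longer; default 80).
#' @param length_fraction,similarity_fraction Mapping cutoffs
#'   (default 0.80 / 0.80).
#' @param min_overlap_fraction Read-to-entry assignment cutoff.
#' @param alpha Significance level for correlations and stars.
#' @param n_random Size of the random-gene null set.
#' @return Invisibly, a list with the main in-memory results
#'   (`profiles`, `profile_table`, `landscapes`, `scaling`,
#'   `family_means`, `correlations`, `null_control`, `anova`,
#'   `manifest_path`).
#' @export
run_pipeline <- function(config, outdir,
                         min_length = 80,
                         length_fraction = 0.80,
                         similarity_fraction = 0.80,
                         min_overlap_fraction = 0.5,
                         alpha = 0.05,
                         n_random = 100) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, nm) {
    utils::write.table(x, file.path(outdir, nm), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    nm
  }
  written <- character(0)

  # --- inputs -----------------------------------------------------------
  te_sim <- simulate_te_copies(config)
  expr_sim <- simulate_expression(config, te_sim)
  input_dir <- file.path(outdir, "inputs")
  write_simulation(te_sim, expr_sim, input_dir)

  # --- annotation filter ------------------------------------------------
  ann_raw <- parse_rm_out(file.path(input_dir, "annotation.out"))
  ann <- filter_redundancy(ann_raw, min_length = min_length)
  if (nrow(ann) == 0L) {
    stop("no TE entries survive filtering (min_length = ", min_length, ")")
  }
  write_annotation_table(ann, file.path(outdir, "filtered_annotation.tsv"))
  written <- c(written, "filtered_annotation.tsv")

  # --- quantification ---------------------------------------------------
  samples <- expr_sim$sample_sheet$sample
  profiles <- vector("list", length(samples))
  names(profiles) <- samples
  entry_counts <- matrix(0L, nrow(ann), length(samples),
                         dimnames = list(ann$contig_id, samples))
  for (nm in samples) {
    alnf <- file.path(input_dir, "alignments", paste0(nm, ".tsv"))
    aln <- read_alignment_tsv(alnf)
    prof <- quantify_sample(aln, ann, sample_id = nm,
                            length_fraction = length_fraction,
                            similarity_fraction = similarity_fraction,
                            min_overlap_fraction = min_overlap_fraction)
    profiles[[nm]] <- prof
    entry_counts[, nm] <- attr(prof, "entry_counts")
  }
  ptab <- profile_table(profiles)
  written <- c(written, tsv(ptab, "te_profiles.tsv"))
  written <- c(written, tsv(
    data.frame(entry_id = rownames(entry_counts), entry_counts,
               check.names = FALSE), "te_entry_counts.tsv"))

  # --- divergence landscapes -------------------------------------------
  pairs <- read_aligned_pairs(file.path(input_dir, "aligned_pairs.fasta"))
  pairs <- pairs[pairs$entry_id %in% ann$contig_id, , drop = FALSE]
  idx <- match(pairs$entry_id, ann$contig_id)
  cls <- classify_te(ann$repeat_class_family[idx])
  rec_bp <- divergence_records(pairs, cls)
  landscapes <- list()
  ltr <- rec_bp[rec_bp$te_class == "LTR", , drop = FALSE]
  landscapes$bp <- build_landscape(ltr, group_by = "ltr_superfamily")
  for (exp_nm in unique(expr_sim$sample_sheet$experiment)) {
    smp <- samples[expr_sim$sample_sheet$experiment == exp_nm]
    w <- rowSums(entry_counts[pairs$entry_id, smp, drop = FALSE])
    rec <- divergence_records(pairs, cls, weights = unname(w))
    rec <- rec[rec$te_class == "LTR" & rec$weight > 0, , drop = FALSE]
    landscapes[[exp_nm]] <- build_landscape(rec,
                                            group_by = "ltr_superfamily")
  }
  for (nm in names(landscapes)) {
    written <- c(written,
                 tsv(landscapes[[nm]], paste0("landscape_", nm, ".tsv")))
  }

  # --- expression normalization ----------------------------------------
  ct <- read_count_table(file.path(input_dir, "gene_counts.tsv"))
  tpm <- compute_tpm(ct$counts, ct$lengths)
  ortho <- read_gene_set(file.path(input_dir, "gene_sets",
                                   "single_copy_orthologues.txt"))
  scaling <- ortholog_scaling(tpm, ortho)
  scaled <- scaling$scaled_tpm
  written <- c(written, tsv(
    data.frame(gene = rownames(tpm), tpm, check.names = FALSE),
    "tpm.tsv"))
  written <- c(written, tsv(
    data.frame(gene = rownames(scaled), scaled, check.names = FALSE),
    "scaled_tpm.tsv"))
  written <- c(written, tsv(
    data.frame(sample = names(scaling$scaling_factors),
               scaling_factor = as.numeric(scaling$scaling_factors)),
    "scaling_factors.tsv"))

  sets <- expr_sim$gene_sets
  fam_rows <- rbind(
    family_mean_expression(scaled, sets$KRAB_like, "KRAB_like"),
    family_mean_expression(scaled, sets$FiNZ, "FiNZ"),
    family_mean_expression(scaled, sets$trim33, "trim33"),
    family_mean_expression(scaled, sets$heterochromatin,
                           "heterochromatin"),
    family_mean_expression(scaled, sets$NuRD, "NuRD")
  )
  rownames(fam_rows) <- c("KRAB_like", "FiNZ", "trim33",
                          "heterochromatin", "NuRD")
  written <- c(written, tsv(
    data.frame(family = rownames(fam_rows), fam_rows,
               check.names = FALSE), "family_means.tsv"))

  # --- statistics -------------------------------------------------------
  sheet <- expr_sim$sample_sheet
  dev <- sheet[sheet$experiment == "development", ]
  stages <- unique(dev$stage)
  stage_means <- function(values_by_sample) {
    vapply(stages, function(st) {
      mean(values_by_sample[dev$sample[dev$stage == st]])
    }, numeric(1))
  }
  cls_names <- te_classes()
  te_traj <- t(vapply(cls_names, function(cl) {
    pc <- vapply(profiles, function(p) p$percentages[[cl]], numeric(1))
    stage_means(pc)
  }, numeric(length(stages))))
  colnames(te_traj) <- stages

  goi <- c(sets$heterochromatin, sets$NuRD, sets$trim33)
  gene_traj <- t(vapply(goi, function(g) stage_means(scaled[g, ]),
                        numeric(length(stages))))
  gene_traj <- rbind(gene_traj,
                     KRAB_like = stage_means(fam_rows["KRAB_like", ]),
                     FiNZ = stage_means(fam_rows["FiNZ", ]))
  correlations <- correlation_panel(te_traj, gene_traj, alpha = alpha)
  written <- c(written, tsv(correlations, "correlations.tsv"))

  gene_stage_means <- t(vapply(rownames(scaled), function(g) {
    stage_means(scaled[g, ])
  }, numeric(length(stages))))
  nullc <- null_correlation_control(
    te_traj, gene_stage_means, n_random = n_random,
    seed = config$seed + 2L,
    exclude = c(goi, sets$KRAB_like, sets$FiNZ,
                sets$single_copy_orthologues),
    alpha = alpha)
  written <- c(written, tsv(nullc$summary, "null_correlation.tsv"))

  trt <- sheet[sheet$experiment == "treatment", ]
  arms <- split(trt$sample, trt$condition)
  anova_rows <- list()
  add_anova <- function(label, values_by_sample) {
    g <- lapply(arms, function(smp) unname(values_by_sample[smp]))
    if (any(vapply(g, stats::var, numeric(1)) > 0) ||
          stats::var(unlist(g)) > 0) {
      a <- one_way_anova(g)
      ms <- lapply(g, mean_sem)
      anova_rows[[length(anova_rows) + 1L]] <<- data.frame(
        contrast = label, F = a$F, df_between = a$df_between,
        df_within = a$df_within, p_value = a$p_value, stars = a$stars,
        mean_DMSO = ms$DMSO$mean, sem_DMSO = ms$DMSO$sem,
        mean_5Aza = ms$`5Aza`$mean, sem_5Aza = ms$`5Aza`$sem,
        stringsAsFactors = FALSE)
    }
  }
  for (cl in cls_names) {
    pc <- vapply(profiles, function(p) p$percentages[[cl]], numeric(1))
    add_anova(paste0("class_", cl), pc)
  }
  for (sfam in ltr_superfamilies()) {
    pc <- vapply(profiles, function(p) p$ltr_percentages[[sfam]],
                 numeric(1))
    if (any(pc[trt$sample] > 0)) add_anova(paste0("ltr_", sfam), pc)
  }
  for (fm in rownames(fam_rows)) add_anova(paste0("expr_", fm),
                                           fam_rows[fm, ])
  anova_tab <- do.call(rbind, anova_rows)
  written <- c(written, tsv(anova_tab, "anova.tsv"))

  stage_summary <- do.call(rbind, lapply(cls_names, function(cl) {
    pc <- vapply(profiles, function(p) p$percentages[[cl]], numeric(1))
    do.call(rbind, lapply(stages, function(st) {
      ms <- mean_sem(pc[dev$sample[dev$stage == st]])
      data.frame(stage = st, te_class = cl, mean_percent = ms$mean,
                 sem = ms$sem, n = ms$n, stringsAsFactors = FALSE)
    }))
  }))
  written <- c(written, tsv(stage_summary, "stage_summary.tsv"))

  # --- manifest ---------------------------------------------------------
  input_files <- sort(list.files(input_dir, recursive = TRUE))
  manifest <- list(
    tool = "TEactivity",
    version = as.character(utils::packageVersion("TEactivity")),
    seed = config$seed,
    parameters = list(
      min_length = min_length, length_fraction = length_fraction,
      similarity_fraction = similarity_fraction,
      min_overlap_fraction = min_overlap_fraction, alpha = alpha,
      n_random = n_random, total_reads = config$total_reads,
      replicates = config$replicates,
      nb_dispersion = config$nb_dispersion
    ),
    input_checksums = as.list(stats::setNames(
      unname(tools::md5sum(file.path(input_dir, input_files))),
      file.path("inputs", input_files))),
    output_checksums = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outdir, sort(written)))),
      sort(written)))
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(
    profiles = profiles, profile_table = ptab, landscapes = landscapes,
    scaling = scaling, family_means = fam_rows,
    correlations = correlations, null_control = nullc,
    anova = anova_tab, stage_summary = stage_summary,
    manifest_path = manifest_path, outdir = outdir
  ))
}

#' Assemble figure-ready report tables from pipeline outputs
#'
#' Reads the stage outputs under `outdir` (erroring with the name of any
#' missing one) and writes the tables behind the standard figures: the
#' stacked-bar class-percentage table per sample, the LTR-superfamily
#' table, the divergence landscape, the family-expression table, the
#' correlation bar table with a significance colour field, and the ANOVA
#' star table. An empty LTR fraction yields a zero-row landscape table
#' with a warning.
#'
#' @param outdir Directory written by [run_pipeline()].
#' @param report_dir Destination (default `outdir/report`).
#' @return Invisibly, the list of report tables.
#' @export
make_report <- function(outdir, report_dir = file.path(outdir, "report")) {
  need <- c("te_profiles.tsv", "landscape_bp.tsv", "family_means.tsv",
            "correlations.tsv", "anova.tsv", "stage_summary.tsv")
  for (f in need) {
    if (!file.exists(file.path(outdir, f))) {
      stop("missing stage output: ", f)
    }
  }
  dir.create(report_dir, recursive = TRUE, showWarnings = FALSE)
  rd <- function(f) utils::read.delim(file.path(outdir, f),
                                      check.names = FALSE)
  wr <- function(x, f) {
    utils::write.table(x, file.path(report_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    x
  }
  prof <- rd("te_profiles.tsv")
  tables <- list()
  tables$stacked_bar <- wr(prof[prof$level == "class",
                               c("sample", "name", "percent")],
                           "stacked_bar.tsv")
  tables$ltr_superfamily <- wr(prof[prof$level == "ltr_superfamily",
                                    c("sample", "name", "percent")],
                               "ltr_superfamily.tsv")
  land <- rd("landscape_bp.tsv")
  if (nrow(land) == 0L) {
    warning("LTR fraction is empty: landscape table has zero rows")
  }
  tables$landscape <- wr(land, "landscape.tsv")
  tables$family_expression <- wr(rd("family_means.tsv"),
                                 "family_expression.tsv")
  corr <- rd("correlations.tsv")
  corr$colour <- ifelse(corr$significant %in% c(TRUE, "TRUE"),
                        "blue", "orange")
  tables$correlation_bars <- wr(corr, "correlation_bars.tsv")
  tables$anova_stars <- wr(rd("anova.tsv"), "anova_stars.tsv")
  tables$stage_summary <- wr(rd("stage_summary.tsv"), "stage_summary.tsv")
  invisible(tables)
}
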