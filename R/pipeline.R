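participant_measures <- function(p, canonical, id) {
  rows <- list()
  rdms <- list()
  for (roi in names(p$rois)) {
    r <- p$rois[[roi]]
    noise <- estimate_noise(r$residuals, r$dof)
    rdm <- crossnobis(r$betas, noise)
    act <- mean(vapply(r$betas, mean_activity, numeric(1)))
    sh <- if (length(r$betas) >= 4)
      split_half_consistency(r$betas, noise) else NA_real_
    rows[[roi]] <- data.frame(
      participant = id, group = p$group, roi = roi,
      hand = unname(roi_hand(roi)),
      mean_activity = act,
      mean_dissimilarity = mean_dissimilarity(rdm),
      typicality = typicality(rdm, canonical),
      splithalf_rho = sh,
      stringsAsFactors = FALSE)
    rdms[[roi]] <- rdm
  }
  list(table = do.call(rbind, rows), rdms = rdms)
}

pooled_diff <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  list(diff = mean(a) - mean(b), se = sqrt(sp2 * (1 / n1 + 1 / n2)),
       dof = n1 + n2 - 2)
}

group_contrasts <- function(tab, measure, roi) {
  vals <- function(g) tab[tab$group == g & tab$roi == roi, measure]
  cmp <- list(c("amputee", "control"), c("amputee", "congenital"),
              c("congenital", "control"))
  rows <- lapply(cmp, function(pair) {
    tt <- group_ttest(vals(pair[1]), vals(pair[2]), family_size = 3)
    data.frame(analysis = "group_contrast", measure = measure, roi = roi,
               comparison = paste(pair, collapse = "_vs_"),
               statistic = "t", value = tt$value, dof1 = tt$dof,
               dof2 = NA_real_, p = tt$p, alpha_adjusted = tt$alpha_adjusted,
               stringsAsFactors = FALSE)
  })
  zero <- lapply(c("amputee", "congenital", "control"), function(g) {
    tt <- one_sample_ttest(vals(g), mu = 0)
    data.frame(analysis = "vs_zero", measure = measure, roi = roi,
               comparison = paste0(g, "_vs_0"),
               statistic = "t", value = tt$value, dof1 = tt$dof,
               dof2 = NA_real_, p = tt$p, alpha_adjusted = tt$alpha_adjusted,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, zero))
}

#' Run the full simulated study
#'
#' End-to-end orchestration: simulate the cohort, estimate per-participant
#' noise models and crossnobis RDMs in all four regions, compute mean
#' activity, mean dissimilarity, typicality and split-half reliability,
#' generate behavioural covariates coupled to realized typicality, and run
#' the inferential layer: Bonferroni-adjusted group contrasts in
#' contralateral SI/M1, the calibrated Bayes factor for amputees versus
#' controls (prior width from the congenital-versus-control difference),
#' forward stepwise regression of amputee SI typicality on the covariates
#' with bootstrap replicability, kinaesthesia correlations with an M1-
#' typicality-adjusted partial correlation, the ipsilateral/V5 control
#' analysis with the mixed-design group x area ANOVA, and MDS projections
#' with Procrustes alignment.
#'
#' @param config a [study_config()].
#' @param B bootstrap resamples for the stepwise analysis (default 1000).
#' @return List of class \code{"group_results"}: \code{participant_table},
#'   \code{rdm_table} (long format), \code{group_summary},
#'   \code{inferential}, \code{covariates}, \code{stepwise},
#'   \code{bootstrap}, \code{bayes} (per measure), \code{projections}
#'   (per group Procrustes-aligned MDS), \code{provenance}.
#' @export
run_study <- function(config, B = 1000) {
  stopifnot(inherits(config, "study_config"))
  canonical <- do.call(canonical_rdm, config$canonical_params)
  cohort <- simulate_cohort(config)
  tabs <- list(); rdm_rows <- list(); rdms_si <- list()
  for (g in names(cohort)) {
    rdms_si[[g]] <- list()
    for (i in seq_along(cohort[[g]])) {
      id <- sprintf("%s_%02d", g, i)
      pm <- participant_measures(cohort[[g]][[i]], canonical, id)
      tabs[[id]] <- pm$table
      rdms_si[[g]][[i]] <- pm$rdms[["SI_contra"]]
      for (roi in names(pm$rdms)) {
        v <- rdm_pairs(pm$rdms[[roi]])
        rdm_rows[[paste(id, roi)]] <- data.frame(
          participant = id, group = g, roi = roi,
          hand = unname(roi_hand(roi)), pair = names(v), distance = unname(v),
          stringsAsFactors = FALSE)
      }
    }
  }
  participant_table <- do.call(rbind, tabs)
  rownames(participant_table) <- NULL
  rdm_table <- do.call(rbind, rdm_rows)
  rownames(rdm_table) <- NULL

  agg <- stats::aggregate(
    participant_table[c("mean_activity", "mean_dissimilarity",
                        "typicality", "splithalf_rho")],
    by = participant_table[c("group", "roi")], FUN = mean, na.rm = TRUE)
  group_summary <- agg[order(agg$roi, agg$group), ]
  rownames(group_summary) <- NULL

  inferential <- do.call(rbind, c(
    lapply(c("SI_contra", "M1_contra"), function(roi) rbind(
      group_contrasts(participant_table, "typicality", roi),
      group_contrasts(participant_table, "mean_dissimilarity", roi),
      group_contrasts(participant_table, "mean_activity", roi))),
    lapply("SI_ipsi", function(roi) rbind(
      group_contrasts(participant_table, "typicality", roi),
      group_contrasts(participant_table, "mean_dissimilarity", roi)))))

  # Bayes factors: amputee-vs-control difference tested against a half-t
  # prior whose width is the congenital-vs-control difference
  bayes <- list()
  for (measure in c("typicality", "mean_dissimilarity")) {
    sel <- function(g) participant_table[
      participant_table$group == g & participant_table$roi == "SI_contra",
      measure]
    prior <- pooled_diff(sel("control"), sel("congenital"))
    obs <- pooled_diff(sel("control"), sel("amputee"))
    bayes[[measure]] <- calibrated_bayes_factor(
      effect_obs = obs$diff, se_obs = obs$se, dof_obs = obs$dof,
      prior_effect = prior$diff, prior_dof = prior$dof)
  }

  # covariates coupled to realized SI typicality; stepwise + bootstrap
  amp_typ <- participant_table[
    participant_table$group == "amputee" &
      participant_table$roi == "SI_contra", "typicality"]
  covariates <- simulate_covariates(amp_typ, config$covariate_coupling,
                                    seed = config$rng_seed + 999983L)
  predictors <- c("kinaesthesia", "vividness_chronic", "vividness_acute",
                  "pain_chronic", "pain_acute", "years_since_amputation",
                  "age_at_amputation", "intact_typicality")
  Xmat <- as.matrix(covariates[predictors])
  stepwise <- stepwise_forward(amp_typ, Xmat)
  boot <- bootstrap_stepwise(amp_typ, Xmat, B = B,
                             seed = config$rng_seed + 424243L)

  m1_typ <- participant_table[
    participant_table$group == "amputee" &
      participant_table$roi == "M1_contra", "typicality"]
  kin_cor <- spearman_cor(covariates$kinaesthesia, amp_typ, family_size = 3)
  kin_partial <- partial_correlation(amp_typ, covariates$kinaesthesia, m1_typ)
  correlations <- rbind(
    data.frame(analysis = "correlation", measure = "typicality",
               roi = "SI_contra", comparison = "kinaesthesia",
               statistic = "rho", value = kin_cor$value, dof1 = kin_cor$dof,
               dof2 = NA_real_, p = kin_cor$p,
               alpha_adjusted = kin_cor$alpha_adjusted,
               stringsAsFactors = FALSE),
    data.frame(analysis = "partial_correlation", measure = "typicality",
               roi = "SI_contra", comparison = "kinaesthesia_given_M1",
               statistic = "beta", value = kin_partial$value,
               dof1 = kin_partial$dof, dof2 = NA_real_, p = kin_partial$p,
               alpha_adjusted = kin_partial$alpha_adjusted,
               stringsAsFactors = FALSE))

  # ipsilateral vs V5 control analysis: group x area mixed ANOVA
  anova_rows <- lapply(c("mean_dissimilarity", "typicality"), function(measure) {
    sub <- participant_table[participant_table$roi %in% c("SI_ipsi", "V5"), ]
    an <- mixed_anova(sub[[measure]], sub$group, sub$roi, sub$participant)
    data.frame(analysis = "mixed_anova_interaction", measure = measure,
               roi = "SI_ipsi_vs_V5", comparison = "group_x_area",
               statistic = "F", value = an$value, dof1 = an$dof[1],
               dof2 = an$dof[2], p = an$p, alpha_adjusted = an$alpha_adjusted,
               stringsAsFactors = FALSE)
  })
  inferential <- rbind(inferential, correlations, do.call(rbind, anova_rows))
  rownames(inferential) <- NULL

  projections <- lapply(rdms_si, function(rs) {
    procrustes_align(lapply(rs, classical_mds))
  })

  structure(list(
    config = config, canonical = canonical,
    participant_table = participant_table, rdm_table = rdm_table,
    group_summary = group_summary, inferential = inferential,
    covariates = covariates, stepwise = stepwise, bootstrap = boot,
    bayes = bayes, projections = projections,
    provenance = list(config_hash = config_hash(config),
                      seed = config$rng_seed,
                      package_version = as.character(utils::packageVersion("limbrsa")))),
    class = "group_results")
}

#' @export
print.group_results <- function(x, ...) {
  cat("Simulated study results (seed", x$provenance$seed, ", config",
      x$provenance$config_hash, ")\n\n")
  cat("Group means, contralateral SI:\n")
  print(x$group_summary[x$group_summary$roi == "SI_contra",
                        c("group", "mean_dissimilarity", "typicality",
                          "splithalf_rho")], row.names = FALSE, digits = 3)
  cat("\nStepwise regression of amputee SI typicality:\n")
  print(x$stepwise)
  cat(sprintf("  kinaesthesia bootstrap inclusion: %.1f%% (B = %d)\n",
              100 * x$bootstrap$inclusion[["kinaesthesia"]], x$bootstrap$B))
  cat(sprintf("\nBF (amputee vs control typicality): %.3f%s\n",
              x$bayes$typicality$bf,
              if (x$bayes$typicality$support_null) "  [supports the null]" else ""))
  invisible(x)
}

#' Write study results to files
#'
#' Writes tidy delimited tables (participant measures, long-format RDMs,
#' group summary, inferential results, covariates, bootstrap inclusion,
#' aligned MDS coordinates), an optional MDS figure, and a JSON run manifest
#' listing every file with the provenance fields.
#'
#' @param results a \code{"group_results"} (may be partially filled;
#'   missing components are skipped).
#' @param out_dir output directory (created if needed).
#' @param plot also write \code{mds.pdf} (default TRUE).
#' @return Invisibly, the manifest as a list.
#' @export
report <- function(results, out_dir, plot = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    files <<- c(files, name)
  }
  if (!is.null(results$participant_table))
    wt(results$participant_table, "participant_measures.tsv")
  if (!is.null(results$rdm_table))
    wt(results$rdm_table, "rdm_long.tsv")
  if (!is.null(results$group_summary))
    wt(results$group_summary, "group_summary.tsv")
  if (!is.null(results$inferential))
    wt(results$inferential, "inferential.tsv")
  if (!is.null(results$covariates))
    wt(results$covariates, "covariates.tsv")
  if (!is.null(results$bootstrap)) {
    wt(data.frame(predictor = names(results$bootstrap$inclusion),
                  inclusion_proportion = unname(results$bootstrap$inclusion),
                  stringsAsFactors = FALSE),
       "bootstrap_inclusion.tsv")
  }
  if (!is.null(results$projections)) {
    coords <- do.call(rbind, lapply(names(results$projections), function(g) {
      m <- results$projections[[g]]$mean
      s <- results$projections[[g]]$se
      data.frame(group = g, digit = digit_labels(),
                 dim1 = m[, 1], dim2 = m[, 2],
                 se1 = s[, 1], se2 = s[, 2], stringsAsFactors = FALSE)
    }))
    wt(coords, "mds_mean.tsv")
    if (plot) {
      grDevices::pdf(file.path(out_dir, "mds.pdf"), width = 9, height = 3.2)
      op <- graphics::par(mfrow = c(1, length(results$projections)))
      for (g in names(results$projections)) {
        m <- results$projections[[g]]$mean
        lim <- range(m) + c(-0.3, 0.3) * max(diff(range(m)), 0.1)
        plot(m, type = "n", xlim = lim, ylim = lim, xlab = "dim 1",
             ylab = "dim 2", main = g, asp = 1)
        graphics::text(m, labels = digit_labels(), col = seq_len(5) + 1)
      }
      graphics::par(op)
      grDevices::dev.off()
      files <- c(files, "mds.pdf")
    }
  }
  manifest <- list(files = files,
                   provenance = results$provenance %||% list())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
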