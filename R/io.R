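# FNV-1a hash over serialized R objects; cheap provenance fingerprint.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write RDMs as a long-format table
#'
#' One row per (participant, region, digit pair): columns \code{participant},
#' \code{group}, \code{roi}, \code{hand}, \code{pair}, \code{distance}.
#'
#' @param rdm_table data.frame in that layout (as produced by [run_study()]).
#' @param path output file (tab-delimited).
#' @export
write_rdm_table <- function(rdm_table, path) {
  utils::write.table(rdm_table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a long-format RDM table
#'
#' @param path file written by [write_rdm_table()].
#' @return data.frame.
#' @export
read_rdm_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

roi_hand <- function(roi) {
  c(SI_contra = "contralateral", M1_contra = "contralateral",
    SI_ipsi = "ipsilateral", V5 = "bilateral")[roi]
}

#' Write a simulated cohort to a directory tree
#'
#' One directory per participant; per region a delimited conditions x voxels
#' beta matrix per run plus the residual matrix, with a JSON sidecar holding
#' condition labels, ROI name, degrees of freedom, group and seed.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(cohort)) {
    for (i in seq_along(cohort[[g]])) {
      p <- cohort[[g]][[i]]
      pdir <- file.path(dir, sprintf("%s_%02d", g, i))
      dir.create(pdir, showWarnings = FALSE)
      for (roi in names(p$rois)) {
        r <- p$rois[[roi]]
        for (run in seq_along(r$betas)) {
          utils::write.table(r$betas[[run]],
                             file.path(pdir, sprintf("%s_run%d_betas.tsv", roi, run)),
                             sep = "\t", row.names = FALSE, col.names = FALSE)
        }
        utils::write.table(r$residuals,
                           file.path(pdir, sprintf("%s_residuals.tsv", roi)),
                           sep = "\t", row.names = FALSE, col.names = FALSE)
        jsonlite::write_json(
          list(roi = roi, hand = unname(roi_hand(roi)), group = g,
               conditions = digit_labels(), n_runs = length(r$betas),
               dof = r$dof, seed = p$seed),
          file.path(pdir, sprintf("%s_sidecar.json", roi)),
          auto_unbox = TRUE)
      }
    }
  }
  invisible(dir)
}

#' Read one participant directory
#'
#' Inverse of the per-participant layout written by [write_cohort()]; also
#' the documented entry point for user-supplied real pattern exports.
#'
#' @param pdir participant directory containing
#'   \code{<roi>_run<k>_betas.tsv}, \code{<roi>_residuals.tsv} and
#'   \code{<roi>_sidecar.json} files.
#' @return List in the shape of a [simulate_participant()] result (without
#'   ground truth).
#' @export
read_participant_dir <- function(pdir) {
  sidecars <- list.files(pdir, pattern = "_sidecar\\.json$", full.names = TRUE)
  if (!length(sidecars)) stop("no sidecar files found in ", pdir)
  out <- list(rois = list())
  for (sc in sidecars) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    roi <- meta$roi
    betas <- lapply(seq_len(meta$n_runs), function(run) {
      b <- as.matrix(utils::read.table(
        file.path(pdir, sprintf("%s_run%d_betas.tsv", roi, run)), sep = "\t"))
      dimnames(b) <- list(meta$conditions, NULL)
      b
    })
    resid <- as.matrix(utils::read.table(
      file.path(pdir, sprintf("%s_residuals.tsv", roi)), sep = "\t"))
    dimnames(resid) <- NULL
    out$rois[[roi]] <- list(betas = betas, residuals = resid, dof = meta$dof)
    out$group <- meta$group
    out$seed <- meta$seed
  }
  out
}

#' Read a study configuration from JSON
#'
#' @param path JSON file whose fields mirror the [study_config()] arguments;
#'   omitted fields take the defaults.
#' @return A \code{"study_config"}.
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (nm in c("n_runs", "block_duration_s", "repeats_per_run", "tr_s",
               "noise_spatial_corr", "noise_sd", "subject_sigma",
               "covariate_coupling", "rng_seed"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  if (!is.null(raw$n_per_group)) args$n_per_group <- unlist(raw$n_per_group)
  if (!is.null(raw$n_voxels_per_roi))
    args$n_voxels_per_roi <- unlist(raw$n_voxels_per_roi)
  if (!is.null(raw$canonical_params))
    args$canonical_params <- as.list(raw$canonical_params)
  for (nm in c("signal_scale", "activity_level")) {
    if (!is.null(raw[[nm]])) {
      m <- as.matrix(as.data.frame(raw[[nm]]))
      rownames(m) <- raw[[paste0(nm, "_groups")]] %||%
        c("amputee", "congenital", "control")
      args[[nm]] <- m
    }
  }
  do.call(study_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
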