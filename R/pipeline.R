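#' Analysis configuration for an end-to-end VLSM run
#'
#' Collects the pipeline's constants.  Defaults follow the published
#' cohort-scale analysis: minimum overlap 10 patients, alpha 0.05, TFCE
#' `H = 2, E = 0.5`, 5000 permutations, mirroring on, DAZ dilation 1
#' voxel.
#'
#' @param cohort_table path to the cohort TSV (`patient_id`, `mask`,
#'   endpoint columns, `volume_ml`).
#' @param mask_dir directory containing the mask files named in the table.
#' @param dural_template path to the dural template NIfTI (required for
#'   `mask_source = "DAZ"`).
#' @param endpoint endpoint column name.
#' @param reference_level reference category for [dummy_code()]; `NULL`
#'   when the column is already 0/1.
#' @param mask_source `"TTV"` (whole tumor) or `"DAZ"` (attachment zone).
#' @param min_overlap minimum-overlap filter (default 10).
#' @param alpha significance level (default 0.05).
#' @param corrections character subset of
#'   `c("bonferroni", "fdr", "maxz", "tfce")`.
#' @param tfce a [tfce_params()].
#' @param n_permutations permutations for the permutation-based methods
#'   (default 5000).
#' @param mirror mirror masks to the right hemisphere first (default TRUE).
#' @param daz_dilation dural-domain dilation in voxels for DAZ extraction
#'   (default 1).
#' @param direction one-sided test direction (default `"positive"`).
#' @param seed seed for all pipeline randomness.
#' @param output_dir where to write results; `NULL` keeps everything in
#'   memory.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(cohort_table = NULL, mask_dir = NULL,
                            dural_template = NULL, endpoint = "endpoint",
                            reference_level = NULL,
                            mask_source = c("TTV", "DAZ"),
                            min_overlap = 10, alpha = 0.05,
                            corrections = "fdr",
                            tfce = tfce_params(),
                            n_permutations = 5000,
                            mirror = TRUE, daz_dilation = 1,
                            direction = "positive",
                            seed = 1, output_dir = NULL) {
  mask_source <- match.arg(mask_source)
  stopifnot(alpha > 0, alpha < 1, min_overlap >= 1,
            all(corrections %in% c("bonferroni", "fdr", "maxz", "tfce")))
  structure(
    list(cohort_table = cohort_table, mask_dir = mask_dir,
         dural_template = dural_template, endpoint = endpoint,
         reference_level = reference_level, mask_source = mask_source,
         min_overlap = min_overlap, alpha = alpha,
         corrections = corrections, tfce = tfce,
         n_permutations = n_permutations, mirror = mirror,
         daz_dilation = daz_dilation, direction = direction,
         seed = seed, output_dir = output_dir),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from a YAML file
#'
#' Any key of [analysis_config()] may appear in the file; `tfce` may be a
#' mapping with `H`, `E`, `dh`, `connectivity`.
#'
#' @param path YAML file path.
#' @param ... overrides applied on top of the file's keys.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  if (!is.null(raw$tfce) && !inherits(raw$tfce, "tfce_params")) {
    raw$tfce <- do.call(tfce_params, raw$tfce)
  }
  do.call(analysis_config, raw)
}

#' Run the full VLSM pipeline on an in-memory cohort
#'
#' Executes read/validate -> mirror -> (DAZ) -> frequency map -> lesion
#' matrix -> voxel-wise regression -> each requested correction, and
#' optionally writes all maps plus a JSON run manifest.
#'
#' @param masks list of [mask_volume()] objects (one per table row), or
#'   `NULL` to read them from `config$mask_dir` per the cohort table.
#' @param table cohort tibble/data.frame with `patient_id`, the endpoint
#'   column, and optionally `volume_ml`; or `NULL` to read
#'   `config$cohort_table`.
#' @param config an [analysis_config()].
#' @param dura a [dural_template()] (required for DAZ mode when
#'   `config$dural_template` is unset).
#' @return A list of class `vlsm_run`: `stat_map`, `corrections` (named
#'   list of `correction_result`), `freq`, `lesion_matrix`, `manifest`.
#' @export
run_pipeline <- function(config, masks = NULL, table = NULL, dura = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(table)) {
    if (is.null(config$cohort_table)) {
      stop("run_pipeline: no cohort table given", call. = FALSE)
    }
    table <- tibble::as_tibble(utils::read.delim(config$cohort_table,
                                                 check.names = FALSE))
  }
  if (!config$endpoint %in% names(table)) {
    stop("run_pipeline: endpoint column '", config$endpoint,
         "' not found in the cohort table", call. = FALSE)
  }
  if (is.null(masks)) {
    if (is.null(config$mask_dir)) {
      stop("run_pipeline: no masks given", call. = FALSE)
    }
    masks <- lapply(seq_len(nrow(table)), function(i) {
      read_mask(file.path(config$mask_dir, table$mask[i]),
                label = table$patient_id[i])
    })
  }
  stopifnot(length(masks) == nrow(table))
  if (is.null(dura) && !is.null(config$dural_template)) {
    dura <- read_dural_template(config$dural_template)
  }

  outcome_raw <- table[[config$endpoint]]
  if (!is.null(config$reference_level)) {
    outcome_raw <- dummy_code(outcome_raw, config$reference_level)
  }
  # complete-case per endpoint: drop missing, rebuild everything downstream
  keep <- !is.na(outcome_raw)
  if (!all(keep)) {
    message("run_pipeline: dropping ", sum(!keep),
            " patients with missing endpoint")
  }
  masks <- masks[keep]
  table <- table[keep, , drop = FALSE]
  outcome <- as.numeric(outcome_raw[keep])
  if (!all(outcome %in% c(0, 1))) {
    stop("run_pipeline: endpoint must be dummy-coded 0/1 (use ",
         "reference_level for categorical columns)", call. = FALSE)
  }

  validate_cohort_grid(masks)
  n_read <- length(masks)
  if (config$mirror) {
    masks <- lapply(masks, mirror_to_right)
  }
  n_unattached <- 0L
  if (config$mask_source == "DAZ") {
    if (is.null(dura)) {
      stop("run_pipeline: DAZ mode needs a dural template", call. = FALSE)
    }
    # dilate the dural domain once for the whole cohort
    dom <- dilate_binary(dural_domain(dura), config$daz_dilation)
    masks <- lapply(masks, function(m) {
      m$data <- array(as.integer(m$data == 1L & dom), dim = dim(m$data))
      m$label <- paste0(m$label, "_daz")
      attr(m, "unattached") <- sum(m$data) == 0L
      m
    })
    unattached <- vapply(masks, function(m) isTRUE(attr(m, "unattached")),
                         logical(1))
    n_unattached <- sum(unattached)
    if (n_unattached > 0L) {
      message("run_pipeline: excluding ", n_unattached,
              " unattached tumors from the DAZ analysis")
      masks <- masks[!unattached]
      outcome <- outcome[!unattached]
      table <- table[!unattached, , drop = FALSE]
    }
  }

  freq <- frequency_map(masks)
  Lm <- assemble_lesion_matrix(masks, min_overlap = config$min_overlap,
                               patient_ids = table$patient_id)
  sm <- voxelwise_glm(Lm, outcome, direction = config$direction)

  corrections <- list()
  for (method in config$corrections) {
    corrections[[method]] <- switch(method,
      bonferroni = bonferroni(sm, alpha = config$alpha),
      fdr = bh_fdr(sm, alpha = config$alpha),
      maxz = permutation_correct(Lm, outcome,
                                 n_permutations = config$n_permutations,
                                 seed = config$seed, statistic = "maxz",
                                 alpha = config$alpha,
                                 direction = config$direction),
      tfce = permutation_correct(Lm, outcome,
                                 n_permutations = config$n_permutations,
                                 seed = config$seed, statistic = "maxtfce",
                                 tfce = config$tfce, alpha = config$alpha,
                                 direction = config$direction)
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dazvlsm")),
    seed = config$seed,
    endpoint = config$endpoint,
    mask_source = config$mask_source,
    min_overlap = config$min_overlap,
    alpha = config$alpha,
    corrections = config$corrections,
    n_masks_read = n_read,
    n_analyzed = length(masks),
    n_unattached_excluded = n_unattached,
    n_voxels_included = nrow(sm$stats),
    n_degenerate = sum(sm$stats$degenerate),
    n_significant = vapply(corrections,
                           function(cr) sum(cr$voxels$significant),
                           integer(1))
  )

  run <- structure(list(stat_map = sm, corrections = corrections,
                        freq = freq, lesion_matrix = Lm, table = table,
                        config = config, manifest = manifest),
                   class = "vlsm_run")
  if (!is.null(config$output_dir)) {
    run$manifest$outputs <- write_run(run, config$output_dir)
  }
  run
}

#' @export
print.vlsm_run <- function(x, ...) {
  cat("<vlsm_run> ", x$manifest$mask_source, " / ", x$manifest$endpoint,
      ": ", x$manifest$n_voxels_included, " voxels",
      if (length(x$manifest$n_significant)) {
        paste0("; significant: ",
               paste(names(x$manifest$n_significant),
                     x$manifest$n_significant,
                     sep = "=", collapse = ", "))
      } else "",
      "\n", sep = "")
  invisible(x)
}

# Write every map of a run plus the JSON manifest; returns a named list of
# paths with md5 checksums in the manifest.
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wv <- function(vol, name) {
    p <- file.path(dir, name)
    write_volume(vol, p)
    paths[[name]] <<- p
    p
  }
  sm <- run$stat_map
  wv(stat_map_volume(sm, "z"), "zmap.nii.gz")
  wv(stat_map_volume(sm, "p", fill = 1), "pmap.nii.gz")
  wv(list(grid = sm$grid,
          data = array(as.integer(sm$included), dim = sm$grid$shape)),
     "included.nii.gz")
  wv(list(grid = run$freq$grid, data = run$freq$counts), "freqmap.nii.gz")
  for (method in names(run$corrections)) {
    cr <- run$corrections[[method]]
    wv(list(grid = cr$grid,
            data = array(as.integer(cr$significant), dim = cr$grid$shape)),
       paste0("sig_", method, ".nii.gz"))
    if (!is.null(cr$null_max)) {
      p <- file.path(dir, paste0("null_max_", method, ".tsv"))
      utils::write.table(data.frame(null_max = cr$null_max), p,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      paths[[basename(p)]] <- p
    }
  }
  vr <- file.path(dir, "voxel_report.tsv")
  utils::write.table(as.data.frame(sm$stats), vr, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths[["voxel_report.tsv"]] <- vr
  manifest <- run$manifest
  manifest$outputs <- lapply(paths, function(p) {
    list(path = basename(p), md5 = unname(tools::md5sum(p)))
  })
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  paths[["manifest.json"]] <- mp
  paths
}

#' Run TTV-based and DAZ-based VLSM side by side
#'
#' Runs the pipeline twice on identical inputs — once on the whole-tumor
#' (TTV) masks and once on the dural attachment zones (DAZ) — and reports,
#' per correction method: significant-voxel counts, the overlap of the two
#' significance masks, and the "spillover" fraction of significant voxels
#' lying outside the dilated dural domain.  Spillover quantifies the
#' volume-driven spread of whole-tumor mapping beyond plausible dural
#' origin regions; for DAZ runs it is 0 by construction.
#'
#' @param config an [analysis_config()]; its `mask_source` is ignored.
#' @param masks,table,dura as in [run_pipeline()] (`dura` required).
#' @return A list of class `ttv_daz_comparison`: `ttv`, `daz`
#'   (`vlsm_run`s), and `report` (one row per correction method).
#' @export
compare_ttv_daz <- function(config, masks = NULL, table = NULL,
                            dura = NULL) {
  cfg_ttv <- config; cfg_ttv$mask_source <- "TTV"
  cfg_daz <- config; cfg_daz$mask_source <- "DAZ"
  if (!is.null(config$output_dir)) {
    cfg_ttv$output_dir <- file.path(config$output_dir, "ttv")
    cfg_daz$output_dir <- file.path(config$output_dir, "daz")
  }
  run_ttv <- run_pipeline(cfg_ttv, masks = masks, table = table, dura = dura)
  run_daz <- run_pipeline(cfg_daz, masks = masks, table = table, dura = dura)
  if (is.null(dura) && !is.null(config$dural_template)) {
    dura <- read_dural_template(config$dural_template)
  }
  dural_dil <- dilate_binary(dural_domain(dura), config$daz_dilation)
  report <- dplyr::bind_rows(lapply(config$corrections, function(method) {
    st <- run_ttv$corrections[[method]]$significant
    sd_ <- run_daz$corrections[[method]]$significant
    n_ttv <- sum(st)
    n_daz <- sum(sd_)
    tibble::tibble(
      method = method,
      n_significant_ttv = n_ttv,
      n_significant_daz = n_daz,
      n_overlap = sum(st & sd_),
      spillover_ttv = if (n_ttv > 0) sum(st & !dural_dil) / n_ttv else 0,
      spillover_daz = if (n_daz > 0) sum(sd_ & !dural_dil) / n_daz else 0
    )
  }))
  structure(list(ttv = run_ttv, daz = run_daz, report = report),
            class = "ttv_daz_comparison")
}

#' @export
print.ttv_daz_comparison <- function(x, ...) {
  cat("<ttv_daz_comparison>\n")
  print(x$report)
  invisible(x)
}
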