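# Study orchestration: simulate -> fit -> ROI stats -> resampling -> report,
# as idempotent commands over a single configuration with manifests.

#' Study configuration
#'
#' Single configuration object driving the whole pipeline.  Defaults mirror
#' a typical single-shell clinical acquisition (b = 1000 s/mm^2, 61
#' directions, tau = 70 ms, SH order 6, penalty 0.006) and a three-group
#' synthetic cohort.
#'
#' @param output_dir Root output directory.
#' @param seed Base seed for every random stage.
#' @param groups Named per-group sizes.
#' @param dims,n_regions,margin Toy atlas geometry.
#' @param b,n_dirs Shell b-value (s/mm^2) and direction count.
#' @param tau,L,lambda,K See [qspace_config()].
#' @param snr Baseline SNR of the Rician noise.
#' @param baseline Baseline [voxel_params()].
#' @param offsets Effect injection, as in [cohort_spec()].
#' @param subject_sd Subject-level population SDs, as in [cohort_spec()].
#' @param trim_low,trim_high ROI trim percentiles.
#' @param min_size,step,B,alpha Resampling plan settings.
#' @return A list of class `study_config`.
#' @export
study_config <- function(output_dir = "amura_study", seed = 1L,
                         groups = c(HC = 10L, EM = 10L, CM = 10L),
                         dims = c(24, 24, 12), n_regions = 12L, margin = 1L,
                         b = 1000, n_dirs = 61L,
                         tau = 0.070, L = 6L, lambda = 0.006, K = 64L,
                         snr = 30, baseline = voxel_params(),
                         offsets = list(), subject_sd = c(f = 0.075),
                         trim_low = 2, trim_high = 98,
                         min_size = 10L, step = 5L, B = 5001L,
                         alpha = 0.05) {
  cfg <- list(output_dir = output_dir, seed = as.integer(seed),
              groups = groups, dims = dims, n_regions = n_regions,
              margin = margin, b = b, n_dirs = n_dirs, tau = tau, L = L,
              lambda = lambda, K = K, snr = snr, baseline = baseline,
              offsets = offsets, subject_sd = subject_sd,
              trim_low = trim_low, trim_high = trim_high,
              min_size = min_size, step = step, B = B, alpha = alpha)
  class(cfg) <- "study_config"
  cfg
}

#' Read a study configuration from YAML
#'
#' Keys mirror the arguments of [study_config()]; unknown keys raise a
#' schema error naming the field.
#'
#' @param path YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown study config field(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$groups)) raw$groups <- unlist(raw$groups)
  if (!is.null(raw$subject_sd)) raw$subject_sd <- unlist(raw$subject_sd)
  if (!is.null(raw$baseline)) raw$baseline <- do.call(voxel_params,
                                                      raw$baseline)
  if (!is.null(raw$offsets))
    raw$offsets <- lapply(raw$offsets, function(g) lapply(g, unlist))
  do.call(study_config, raw)
}

config_cohort_spec <- function(cfg) {
  cohort_spec(groups = cfg$groups,
              atlas = toy_atlas(cfg$dims, cfg$n_regions, cfg$margin),
              baseline = cfg$baseline, offsets = cfg$offsets,
              subject_sd = cfg$subject_sd, snr = cfg$snr,
              scheme = synthetic_scheme(cfg$n_dirs, cfg$b),
              seed = cfg$seed)
}

config_qspace <- function(cfg) {
  qspace_config(tau = cfg$tau, L = cfg$L, lambda = cfg$lambda, K = cfg$K)
}

config_extraction <- function(cfg) {
  roi_extraction_spec(low = cfg$trim_low, high = cfg$trim_high)
}

# Stage manifest: configuration hash, seed, package version, elapsed time.
write_manifest <- function(cfg, dir, stage, elapsed) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg)[order(names(unclass(cfg)))], tmp)
  jsonlite::write_json(list(
    stage = stage,
    config_hash = unname(tools::md5sum(tmp)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("amura")),
    elapsed_s = round(elapsed, 3)),
    file.path(dir, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE)
}

stage_log <- function(stage, msg, t0) {
  message(sprintf("[%s] %6.1fs %s", stage, as.numeric(Sys.time()) - t0, msg))
}

#' Pipeline commands
#'
#' `cmd_simulate` writes the synthetic cohort; `cmd_fit` computes the 11
#' metric maps per subject; `cmd_roistats` reduces them to the ROI table and
#' group comparisons; `cmd_resample` runs the subsampling experiment;
#' `cmd_report` writes summary tables (significant-ROI counts and the
#' significance-vs-size curve) and simple figures.  Each command requires
#' its upstream outputs and fails with an actionable error naming the
#' command to run first.  All stages are deterministic given the
#' configuration.
#'
#' @param cfg A [study_config()].
#' @return The main artifact of the stage, invisibly where it is a file set.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_simulate <- function(cfg) {
  t0 <- as.numeric(Sys.time())
  dir <- file.path(cfg$output_dir, "cohort")
  spec <- config_cohort_spec(cfg)
  stage_log("simulate", paste("generating", nrow(spec$design), "subjects"), t0)
  res <- generate_cohort(spec, dir)
  write_manifest(cfg, dir, "simulate", as.numeric(Sys.time()) - t0)
  stage_log("simulate", paste("wrote cohort to", dir), t0)
  invisible(res)
}

require_upstream <- function(path, cmd) {
  if (!file.exists(path))
    stop("missing upstream output '", path, "'; run ", cmd, " first")
  path
}

#' @rdname pipeline
#' @export
cmd_fit <- function(cfg) {
  t0 <- as.numeric(Sys.time())
  cdir <- file.path(cfg$output_dir, "cohort")
  require_upstream(file.path(cdir, "design.tsv"), "cmd_simulate")
  design <- utils::read.table(file.path(cdir, "design.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  labels <- read_labels(file.path(cdir, "atlas.nii.gz"))
  mdir <- file.path(cfg$output_dir, "maps")
  dir.create(mdir, showWarnings = FALSE, recursive = TRUE)
  qc <- config_qspace(cfg)
  mask <- labels != 0L
  clip_total <- c(low = 0, high = 0, total = 0)
  n_invalid <- 0L
  for (s in seq_len(nrow(design))) {
    dwi <- read_dwi(file.path(cdir, paste0(design$subject_id[s],
                                           "_dwi.nii.gz")),
                    file.path(cdir, "cohort.bval"),
                    file.path(cdir, "cohort.bvec"))
    maps <- compute_metric_maps(dwi, mask = mask, config = qc)
    clip_total <- clip_total + attr(maps, "clip")
    n_invalid <- n_invalid + attr(maps, "n_invalid")
    for (m in colnames(maps))
      write_scalar_map(array(maps[, m], dim(labels)),
                       file.path(mdir, paste0(design$subject_id[s], "_", m,
                                              ".nii.gz")))
    if (s %% 25L == 0L) stage_log("fit", paste("fitted", s, "subjects"), t0)
  }
  jsonlite::write_json(c(as.list(clip_total), list(invalid = n_invalid)),
                       file.path(mdir, "fit_qc.json"), auto_unbox = TRUE)
  write_manifest(cfg, mdir, "fit", as.numeric(Sys.time()) - t0)
  stage_log("fit", paste("wrote", nrow(design) * 11, "metric maps"), t0)
  invisible(mdir)
}

#' @rdname pipeline
#' @export
cmd_roistats <- function(cfg) {
  t0 <- as.numeric(Sys.time())
  cdir <- file.path(cfg$output_dir, "cohort")
  mdir <- file.path(cfg$output_dir, "maps")
  require_upstream(file.path(mdir, "fit_qc.json"), "cmd_fit")
  design <- utils::read.table(file.path(cdir, "design.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  design$group <- factor(design$group, levels = names(cfg$groups))
  labels <- read_labels(file.path(cdir, "atlas.nii.gz"))
  skel <- read_scalar_map(file.path(cdir, "skeleton.nii.gz")) != 0
  atlas <- list(labels = labels, skeleton = skel)
  maps <- lapply(design$subject_id, function(sid) {
    m <- vapply(metric_names(), function(mn)
      as.numeric(read_scalar_map(file.path(mdir, paste0(sid, "_", mn,
                                                        ".nii.gz")))),
      numeric(length(labels)))
    colnames(m) <- metric_names()
    m
  })
  rt <- roi_table_from_maps(maps, atlas, design, config_extraction(cfg))
  sdir <- file.path(cfg$output_dir, "stats")
  dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
  write_roi_table(rt, file.path(sdir, "roi_table.tsv"))
  cmp <- roi_comparison_table(rt, alpha = cfg$alpha)
  utils::write.table(cmp, file.path(sdir, "comparisons.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(significant_counts(cmp),
                       file.path(sdir, "significant_counts.json"),
                       auto_unbox = TRUE)
  write_manifest(cfg, sdir, "roistats", as.numeric(Sys.time()) - t0)
  stage_log("roistats", paste("wrote", nrow(cmp), "comparison records"), t0)
  invisible(rt)
}

#' @rdname pipeline
#' @export
cmd_resample <- function(cfg) {
  t0 <- as.numeric(Sys.time())
  sdir <- file.path(cfg$output_dir, "stats")
  require_upstream(file.path(sdir, "roi_table.tsv"), "cmd_roistats")
  rt <- read_roi_table(file.path(sdir, "roi_table.tsv"))
  rt$group <- factor(rt$group, levels = names(cfg$groups))
  plan <- resampling_plan(n_full = min(table(rt$group)),
                          min_size = cfg$min_size, step = cfg$step,
                          B = cfg$B, alpha = cfg$alpha,
                          base_seed = cfg$seed)
  res <- subsample_experiment(rt, plan)
  rdir <- file.path(cfg$output_dir, "resampling")
  write_resampling_result(res, rdir)
  write_manifest(cfg, rdir, "resample", as.numeric(Sys.time()) - t0)
  stage_log("resample", paste("tracked", nrow(res$counts), "size x test cells"),
            t0)
  invisible(res)
}

#' @rdname pipeline
#' @param make_plots Also write PNG figures (default TRUE).
#' @export
cmd_report <- function(cfg, make_plots = TRUE) {
  t0 <- as.numeric(Sys.time())
  sdir <- file.path(cfg$output_dir, "stats")
  rdir <- file.path(cfg$output_dir, "resampling")
  require_upstream(file.path(sdir, "comparisons.tsv"), "cmd_roistats")
  cmp <- utils::read.table(file.path(sdir, "comparisons.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  odir <- file.path(cfg$output_dir, "report")
  dir.create(odir, showWarnings = FALSE, recursive = TRUE)
  counts <- significant_counts(cmp)
  utils::write.table(counts, file.path(odir, "significant_roi_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  curve <- NULL
  if (file.exists(file.path(rdir, "subsample_counts.tsv"))) {
    sub <- utils::read.table(file.path(rdir, "subsample_counts.tsv"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    res <- structure(list(counts = sub), class = "resampling_result")
    curve <- significance_vs_size_curve(res)
    utils::write.table(curve, file.path(odir, "significance_vs_size.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (make_plots && !is.null(curve) && nrow(curve)) {
    grDevices::png(file.path(odir, "significance_vs_size.png"),
                   width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    pairs <- unique(curve$pair)
    graphics::par(mfrow = c(1, length(pairs)))
    for (pr in pairs) {
      x <- curve[curve$pair == pr, ]
      mets <- unique(x$metric)
      graphics::matplot(
        sort(unique(x$size)),
        vapply(mets, function(m) {
          y <- x[x$metric == m, ]
          y$n_significant[order(y$size)]
        }, numeric(length(unique(x$size)))),
        type = "b", pch = 16, lty = 1,
        xlab = "subjects per group", ylab = "significant ROIs", main = pr)
      graphics::legend("topleft", legend = mets, col = seq_along(mets),
                       pch = 16, cex = 0.7)
    }
  }
  write_manifest(cfg, odir, "report", as.numeric(Sys.time()) - t0)
  stage_log("report", paste("report written to", odir), t0)
  invisible(odir)
}

#' Run the whole study end to end
#'
#' simulate -> fit -> roistats -> resample -> report.
#'
#' @param cfg A [study_config()].
#' @return Invisibly, the report directory.
#' @export
run_study <- function(cfg) {
  cmd_simulate(cfg)
  cmd_fit(cfg)
  cmd_roistats(cfg)
  cmd_resample(cfg)
  cmd_report(cfg)
}
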