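#' Replicate-level group summary (mean +/- s.e.m.)
#'
#' Summarizes a condition the way the source experiments are reported:
#' cells are averaged within each biological replicate (an independent
#' culture or dish) first, and mean and s.e.m. are computed over the
#' replicate means, so the replicate — not the cell — is the unit of
#' analysis.
#'
#' @param values Numeric vector of per-cell (or per-trace) values.
#' @param replicate Factor/vector assigning each value to a replicate;
#'   `NULL` treats each value as its own replicate.
#' @param condition Optional condition label.
#' @return A `group_summary` one-row data.frame: condition, n_replicates,
#'   n_cells_total, mean, sem (`NA` when only one replicate), sd.
#' @export
summarize_group <- function(values, replicate = NULL, condition = NA_character_) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (is.null(replicate)) replicate <- seq_along(values)
  stopifnot(length(replicate) == length(values))
  rep_means <- tapply(values, replicate, mean)
  n <- length(rep_means)
  out <- data.frame(condition = condition,
                    n_replicates = n,
                    n_cells_total = length(values),
                    mean = mean(rep_means),
                    sem = if (n >= 2L) stats::sd(rep_means) / sqrt(n)
                          else NA_real_,
                    sd = if (n >= 2L) stats::sd(rep_means) else NA_real_)
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Two-sample Student's t-test (two-tailed)
#'
#' Classical pooled-variance Student's t for unpaired comparisons
#' (df = n_a + n_b - 2), or the paired t on within-pair differences.
#' Two groups with zero variance and equal means return t = 0, p = 1 by
#' convention.
#'
#' @param group_a,group_b Numeric vectors; equal lengths when paired.
#' @param paired Paired test?
#' @return List: `t`, `df`, `p` (two-tailed), `mean_a`, `mean_b`.
#' @export
two_sample_t_test <- function(group_a, group_b, paired = FALSE) {
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (paired && length(group_a) != length(group_b))
    stop("paired test requires equal group lengths")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 observations")
  degenerate <- if (paired) stats::var(group_a - group_b) == 0
                else stats::var(group_a) == 0 && stats::var(group_b) == 0
  if (degenerate) {
    if (paired && all(group_a == group_b) ||
        !paired && mean(group_a) == mean(group_b)) {
      df <- if (paired) length(group_a) - 1L else
        length(group_a) + length(group_b) - 2L
      return(list(t = 0, df = df, p = 1,
                  mean_a = mean(group_a), mean_b = mean(group_b)))
    }
    stop("zero variance with unequal means: t is unbounded")
  }
  ht <- stats::t.test(group_a, group_b, paired = paired, var.equal = TRUE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Run a configured multi-stage analysis
#'
#' Executes the requested pipeline stages against a configuration list (or
#' YAML/JSON file) and writes every CSV/JSON output plus a `manifest.json`
#' recording the package version, the seed, and every numeric parameter
#' and convention flag each stage consumed. Reruns with an identical
#' config are bit-identical for the deterministic stages.
#'
#' Supported stages and their config blocks:
#' \describe{
#'   \item{simulate}{`scene` and/or `kinetic` parameter lists (passed to
#'     [scene_config()] / [kinetic_config()]); writes the scene TIFF +
#'     ground-truth JSON, and/or a biosensor trace CSV.}
#'   \item{enrich}{needs a simulated scene; writes per-cell enrichment CSV
#'     (cilium + endosome, both conventions).}
#'   \item{puncta}{puncta count / positivity CSV for the scene.}
#'   \item{traffick}{needs `scene` + `kinetic`; simulates a movie and
#'     writes the accumulation trace CSV.}
#'   \item{biosensor}{phase summaries (AUC/peak/plateau) of the simulated
#'     trace, CSV.}
#'   \item{coloc}{spot detection + distance classification CSV for the
#'     scene (protein spots vs marker mask).}
#'   \item{report}{group summary + t-test JSON over any numeric column of
#'     a stage output named in `report$file` / `report$column` /
#'     `report$group_by`.}
#' }
#'
#' @param config A named list, or path to a YAML/JSON file. Top-level
#'   keys: `stages` (character vector), `out_dir`, `seed`, plus the
#'   per-stage blocks above. Unknown top-level keys are an error.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  known <- c("stages", "out_dir", "seed", "scene", "kinetic", "enrich",
             "puncta", "traffick", "biosensor", "coloc", "report")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("invalid config keys: ", paste(bad, collapse = ", "))
  stages <- match.arg(config$stages,
                      c("simulate", "enrich", "puncta", "traffick",
                        "biosensor", "coloc", "report"),
                      several.ok = TRUE)
  out_dir <- config$out_dir %||% stop("config needs 'out_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  manifest <- list(package = "punctate",
                   version = as.character(utils::packageVersion("punctate")),
                   seed = seed, stages = stages, parameters = list())

  scene_cfg <- do.call(scene_config, c(config$scene %||% list(),
                                       list(seed = seed)))
  kin_cfg <- do.call(kinetic_config, c(config$kinetic %||% list(),
                                       list(seed = seed)))
  manifest$parameters$scene <- unclass(scene_cfg)
  manifest$parameters$kinetic <- unclass(kin_cfg)

  scene <- NULL
  need_scene <- any(stages %in% c("simulate", "enrich", "puncta", "coloc"))
  if (need_scene) scene <- simulate_static_scene(scene_cfg)

  if ("simulate" %in% stages) {
    write_stack(scene$stack, file.path(out_dir, "scene.tif"))
    truth <- scene$truth
    truth$masks <- NULL; truth$noiseless <- NULL  # keep the sidecar small
    jsonlite::write_json(truth, file.path(out_dir, "scene.truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  if ("enrich" %in% stages) {
    opts <- config$enrich %||% list()
    cell <- region_mask(scene$truth$masks$cell)
    rows <- rbind(
      cilia_enrichment(scene$stack, region_mask(scene$truth$masks$cilium),
                       cell, convention = opts$convention %||% "mean-ratio",
                       cell_id = "cell1"),
      endosome_enrichment(scene$stack, cell,
                          marker_threshold = opts$marker_threshold,
                          convention = opts$convention %||% "mean-ratio",
                          cell_id = "cell1"))
    write_table(rows, file.path(out_dir, "enrichment.csv"))
    manifest$parameters$enrich <- opts
  }
  if ("puncta" %in% stages) {
    opts <- config$puncta %||% list()
    cls <- count_internal_puncta(
      max_project_z(scene$stack, 2L), region_mask(scene$truth$masks$cell),
      threshold = opts$threshold,
      min_area_px = opts$min_area_px %||% 3L,
      threshold_puncta = opts$threshold_puncta %||% 10L,
      cell_id = "cell1")
    write_table(cls, file.path(out_dir, "puncta.csv"))
    manifest$parameters$puncta <- opts
  }
  if ("traffick" %in% stages) {
    mov <- simulate_trafficking_movie(scene_cfg, kin_cfg)
    tr <- puncti_accumulation_trace(mov$stack, puncti_config())
    write_table(as.data.frame(tr), file.path(out_dir, "traffick_trace.csv"))
  }
  if ("biosensor" %in% stages) {
    sim <- simulate_biosensor_trace(kin_cfg)
    tr <- fskibmx_normalize(sim$trace)
    write_table(as.data.frame(tr), file.path(out_dir, "biosensor_trace.csv"))
    write_table(summarize_phases(tr, cell_id = "cell1"),
                file.path(out_dir, "biosensor_summary.csv"))
  }
  if ("coloc" %in% stages) {
    opts <- config$coloc %||% list()
    ac <- max_project_z(scene$stack, 2L)
    marker <- max_project_z(scene$stack, 1L)
    cell <- region_mask(scene$truth$masks$cell)
    spots <- detect_spots(ac, cell)
    ref <- endosome_mask_from_marker(marker, cell)
    res <- classify_colocalized(spots, ref, scene_cfg$pixel_size,
                                opts$max_distance_um %||% 1.0)
    write_table(res$per_spot, file.path(out_dir, "coloc_spots.csv"))
    write_table(data.frame(n_spots_total = res$n_spots_total,
                           n_colocalized = res$n_colocalized,
                           max_distance_um = res$max_distance_um),
                file.path(out_dir, "coloc_summary.csv"))
    manifest$parameters$coloc <- opts
  }
  if ("report" %in% stages) {
    opts <- config$report
    if (is.null(opts$file) || is.null(opts$column))
      stop("invalid config keys: report$file, report$column are required")
    tab <- read_table(file.path(out_dir, opts$file))
    grp <- if (!is.null(opts$group_by)) tab[[opts$group_by]] else NULL
    summ <- summarize_group(tab[[opts$column]], replicate = grp)
    write_table(summ, file.path(out_dir, "report_summary.csv"))
    manifest$parameters$report <- opts
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(out_dir)
}
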