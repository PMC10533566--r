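# End-to-end pipeline commands: simulate, extract, analyze.
# These back the command-line interface (inst/cli/salisense) and are the
# programmatic entry points for full runs.

#' Assemble and validate a full run configuration
#'
#' Nested configuration for an end-to-end run.  Unknown keys are rejected
#' so typos in YAML configs fail before any stage executes.
#'
#' @param generator List of [generator_config()] arguments (or a ready
#'   `generator_config`).
#' @param layout A [sensor_layout()] or list of its arguments.
#' @param chemometrics List: `ttest_variant` ("pooled"/"welch"),
#'   `threshold` (NULL = grand mean of the analysed data).
#' @param discrimination List: `variance_target`, `cv_scheme`
#'   ("loo"/"kfold"/"resubstitution"), `kfold_k`.
#' @param render_images Render PNG pairs during simulation?
#' @param pixel_noise_sd Per-pixel Gaussian noise SD for rendered images.
#' @return Object of class `run_config`.
#' @export
run_config <- function(generator = list(), layout = sensor_layout(),
                       chemometrics = list(), discrimination = list(),
                       render_images = TRUE, pixel_noise_sd = 0) {
  if (!inherits(generator, "generator_config")) {
    check_keys(generator, names(formals(generator_config)), "generator")
    generator <- do.call(generator_config, generator)
  }
  if (!inherits(layout, "sensor_layout")) {
    check_keys(layout, names(formals(sensor_layout)), "layout")
    layout <- do.call(sensor_layout, layout)
  }
  chem_defaults <- list(ttest_variant = "pooled", threshold = NULL)
  check_keys(chemometrics, names(chem_defaults), "chemometrics")
  chem <- utils::modifyList(chem_defaults, chemometrics)
  disc_defaults <- list(variance_target = 0.95, cv_scheme = "loo",
                        kfold_k = 5L)
  check_keys(discrimination, names(disc_defaults), "discrimination")
  disc <- utils::modifyList(disc_defaults, discrimination)
  if (!disc$cv_scheme %in% c("loo", "kfold", "resubstitution")) {
    stop("invalid config: unknown cv_scheme '", disc$cv_scheme, "'")
  }
  if (!chem$ttest_variant %in% c("pooled", "welch")) {
    stop("invalid config: unknown ttest_variant '", chem$ttest_variant, "'")
  }
  structure(list(generator = generator, layout = layout,
                 chemometrics = chem, discrimination = disc,
                 render_images = isTRUE(render_images),
                 pixel_noise_sd = pixel_noise_sd),
            class = "run_config")
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("invalid config: unknown ", where, " key(s): ",
         paste(extra, collapse = ", "))
  }
  invisible(x)
}

#' Load a run configuration from YAML
#' @param path YAML file; top-level keys are the [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  check_keys(y, names(formals(run_config)), "run")
  if (!is.null(y$layout) && !is.null(y$layout$spots)) {
    y$layout$spots <- do.call(rbind, lapply(y$layout$spots, as.data.frame))
  }
  do.call(run_config, y)
}

#' Simulate a full study: cohort, responses, images, manifest
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list of the written paths plus the cohort and
#'   response matrix.
#' @export
cmd_simulate <- function(config = run_config(), outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("unwritable output directory: ", outdir)
  gen <- config$generator
  cohort <- generate_cohort(gen)
  paths <- list(cohort = file.path(outdir, "cohort.csv"),
                responses = file.path(outdir, "responses.csv"),
                layout = file.path(outdir, "layout.yaml"),
                manifest = file.path(outdir, "manifest.json"))
  write_cohort_csv(cohort, paths$cohort)
  responses <- NULL
  if (nrow(cohort) > 0L) {
    responses <- generate_responses(cohort, receptor_panel(), gen)
    write_response_csv(responses, paths$responses)
    if (config$render_images) {
      imgdir <- file.path(outdir, "images")
      dir.create(imgdir, showWarnings = FALSE)
      for (i in seq_len(nrow(responses))) {
        pair <- render_sensor_image(responses[i, ], receptor_panel(),
                                    config$layout, gen,
                                    pixel_noise_sd = config$pixel_noise_sd)
        id <- rownames(responses)[i]
        write_sensor_png(pair$before, file.path(imgdir, paste0(id, "_before.png")))
        write_sensor_png(pair$after, file.path(imgdir, paste0(id, "_after.png")))
      }
      paths$images <- imgdir
    }
  } else {
    # empty cohort: still write an empty (header-only) response table
    utils::write.csv(
      stats::setNames(data.frame(matrix(nrow = 0, ncol = 37)),
                      c("id", response_colnames())),
      paths$responses, row.names = FALSE)
  }
  write_layout(config$layout, paths$layout)
  manifest <- list(
    tool = "salisense", version = as.character(utils::packageVersion("salisense")),
    seed = gen$seed,
    n_diabetic = gen$n_diabetic, n_nondiabetic = gen$n_nondiabetic,
    config_hash = unname(tools::md5sum(paths$cohort)),
    files = lapply(paths, basename)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(paths, list(cohort_data = cohort, response_data = responses)))
}

#' Extract response vectors from a directory of image pairs
#'
#' Pairs are discovered by the `<id>_before.png` / `<id>_after.png` naming
#' convention.  Orphan or unreadable images are skipped with a warning;
#' matching no pair at all is an error.
#'
#' @param imgdir Directory of PNG pairs.
#' @param layout A [sensor_layout()] or path to a layout YAML.
#' @param out_csv Optional path for the response CSV.
#' @return The n x 36 response matrix (invisibly written to `out_csv`).
#' @export
cmd_extract <- function(imgdir, layout, out_csv = NULL) {
  if (is.character(layout)) layout <- read_layout(layout)
  files <- list.files(imgdir, pattern = "_(before|after)\\.png$")
  ids_b <- sub("_before\\.png$", "", grep("_before", files, value = TRUE))
  ids_a <- sub("_after\\.png$", "", grep("_after", files, value = TRUE))
  orphans <- c(setdiff(ids_b, ids_a), setdiff(ids_a, ids_b))
  for (o in orphans) warning("skipping orphan image pair id: ", o)
  ids <- sort(intersect(ids_b, ids_a))
  if (length(ids) == 0L) stop("no before/after image pairs found in ", imgdir)
  rows <- list()
  for (id in ids) {
    row <- tryCatch({
      before <- read_sensor_png(file.path(imgdir, paste0(id, "_before.png")))
      after <- read_sensor_png(file.path(imgdir, paste0(id, "_after.png")))
      compute_response_vector(before, after, layout)
    }, error = function(e) {
      warning("skipping unreadable pair '", id, "': ", conditionMessage(e))
      NULL
    })
    if (!is.null(row)) rows[[id]] <- row
  }
  if (length(rows) == 0L) stop("no image pair could be processed in ", imgdir)
  m <- do.call(rbind, rows)
  class(m) <- c("salisense_responses", class(m))
  if (!is.null(out_csv)) write_response_csv(m, out_csv)
  invisible(m)
}

#' Analyze a response matrix against its cohort
#'
#' Produces the full statistics report: total-response summary with the
#' norm-threshold confusion, the cross-validated PCA-LDA classification,
#' receptor-FBG correlations (MR+TBOH on binned FBG, TMA-AgNPs direct)
#' and age-total response correlations per group.  When only one group is
#' present, discrimination is skipped with an explicit notice and the norm
#' summary is still reported.
#'
#' @param responses n x 36 response matrix or path to a response CSV.
#' @param cohort Cohort data frame or path to a cohort CSV.
#' @param config A [run_config()].
#' @param outdir Optional directory for report.json, scores.csv, norms.csv
#'   and the score plot.
#' @return The report as a nested list (class `salisense_report`).
#' @export
cmd_analyze <- function(responses, cohort, config = run_config(),
                        outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(responses)) responses <- read_response_csv(responses)
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  ids_r <- rownames(responses)
  missing_in_cohort <- setdiff(ids_r, cohort$id)
  missing_in_resp <- setdiff(cohort$id, ids_r)
  if (length(missing_in_cohort) || length(missing_in_resp)) {
    stop("join error: ids without a match - responses: [",
         paste(missing_in_cohort, collapse = ", "), "]; cohort: [",
         paste(missing_in_resp, collapse = ", "), "]")
  }
  cohort <- cohort[match(ids_r, cohort$id), ]
  groups <- as.character(cohort$group)
  gen <- config$generator

  trs <- total_response_summary(responses, groups,
                                variant = config$chemometrics$ttest_variant)
  threshold <- config$chemometrics$threshold
  if (is.null(threshold)) threshold <- trs$grand_mean
  pred_norm <- threshold_classify(trs$norms, threshold)

  report <- list(
    n = nrow(responses),
    groups = as.list(table(groups)),
    total_response = list(
      group_stats = trs$group_stats,
      grand_mean = trs$grand_mean,
      t = trs$t, df = trs$df, p = trs$p,
      threshold = threshold
    )
  )

  two_groups <- length(unique(groups)) == 2L
  if (two_groups) {
    cmn <- table(factor(groups, levels = sort(unique(groups))),
                 factor(pred_norm, levels = sort(unique(groups))))
    cmn <- matrix(as.integer(cmn), 2, 2,
                  dimnames = list(sort(unique(groups)), sort(unique(groups))))
    norm_rep <- confusion_metrics(cmn)
    report$total_response$confusion <- norm_rep$confusion
    report$total_response$accuracy <- norm_rep$accuracy
    cvrep <- crossvalidate(responses, groups,
                           scheme = config$discrimination$cv_scheme,
                           k = config$discrimination$kfold_k,
                           seed = gen$seed,
                           variance_target = config$discrimination$variance_target)
    report$discrimination <- list(
      scheme = cvrep$scheme,
      confusion = cvrep$confusion,
      accuracy = cvrep$accuracy,
      error_rate = cvrep$error_rate,
      sensitivity = as.list(cvrep$sensitivity),
      specificity = as.list(cvrep$specificity)
    )
  } else {
    report$discrimination <- list(
      skipped = TRUE,
      notice = "only one group present; discrimination requires two")
  }

  # receptor-FBG and age correlations
  correlations <- list()
  if (!is.null(cohort$fbg) && stats::sd(cohort$fbg) > 0) {
    s5 <- receptor_response(responses, 5)
    s10 <- receptor_response(responses, 10)
    binned <- fbg_binned(cohort$fbg, gen)
    if (stats::sd(binned) > 0 && stats::sd(s5) > 0) {
      pr <- pearson(binned, s5)
      correlations$mr_tboh_fbg_binned <- list(r = pr$r, p = pr$p, n = pr$n)
    }
    if (stats::sd(s10) > 0) {
      pr <- pearson(cohort$fbg, s10)
      correlations$tma_agnp_fbg <- list(r = pr$r, p = pr$p, n = pr$n)
    }
  }
  if (!is.null(cohort$age)) {
    for (g in unique(groups)) {
      idx <- groups == g
      if (sum(idx) >= 3 && stats::sd(cohort$age[idx]) > 0 &&
          stats::sd(trs$norms[idx]) > 0) {
        pr <- pearson(cohort$age[idx], trs$norms[idx])
        correlations[[paste0("age_total_response_", g)]] <-
          list(r = pr$r, p = pr$p, n = pr$n)
      }
    }
  }
  report$correlations <- correlations
  class(report) <- c("salisense_report", class(report))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    norm_df <- data.frame(id = ids_r, group = groups, norm = trs$norms,
                          predicted = pred_norm, row.names = NULL)
    utils::write.csv(norm_df, file.path(outdir, "norms.csv"),
                     row.names = FALSE)
    if (two_groups) {
      es <- export_scores(responses, groups, fbg = cohort$fbg,
                          file_csv = file.path(outdir, "scores.csv"),
                          file_plot = file.path(outdir, "score_plot.png"))
      report$pc1_fbg <- es$pc1_fbg
      report$explained_variance_pc12 <-
        sum(es$pca_model$all_variances[1:2]) / es$pca_model$total_variance * 100
    }
    write_report_json(unclass(report), file.path(outdir, "report.json"))
  }
  report
}
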