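# End-to-end orchestration over synthetic cohorts: simulate -> (optional
# render/segment) -> contextual features -> mixture clustering -> planted
# survival -> elastic-net risk -> evaluation, with a versioned manifest.

#' Pipeline run configuration
#'
#' Collects stage toggles, seeds and modelling parameters for
#' [run_pipeline()]. All randomness flows from the named per-stage seeds
#' recorded in the run manifest. In paper mode the number of clusters is
#' fixed at 8.
#'
#' @param n_patients cohort size.
#' @param tiles_per_patient tiles simulated per patient.
#' @param sim a [sim_config()] for the tissue simulator.
#' @param spec a [neighborhood_spec()].
#' @param K number of mixture components.
#' @param paper_mode enforce the published configuration (K = 8).
#' @param alpha elastic-net mixing weight.
#' @param censor_rate censoring fraction for the planted outcomes.
#' @param stages named logical toggles: \code{segment} (render tiles and
#'   re-segment instead of using simulated cell tables), \code{qmif},
#'   \code{genes}.
#' @param seeds named per-stage seeds (\code{simulate}, \code{survival},
#'   \code{cluster}, \code{risk}); missing entries are defaulted with a
#'   warning by [validate_config()].
#' @param out_dir output directory for artifacts (NULL = no files written).
#' @return object of class \code{run_config}.
#' @export
pipeline_config <- function(n_patients = 50L, tiles_per_patient = 3L,
                            sim = sim_config(), spec = neighborhood_spec(),
                            K = 8L, paper_mode = TRUE, alpha = 0.5,
                            censor_rate = 0.2,
                            stages = list(segment = FALSE, qmif = FALSE,
                                          genes = FALSE),
                            seeds = list(simulate = 1L, survival = 2L,
                                         cluster = 3L, risk = 4L),
                            out_dir = NULL) {
  structure(list(n_patients = as.integer(n_patients),
                 tiles_per_patient = as.integer(tiles_per_patient),
                 sim = sim, spec = spec, K = as.integer(K),
                 paper_mode = isTRUE(paper_mode), alpha = alpha,
                 censor_rate = censor_rate, stages = stages, seeds = seeds,
                 out_dir = out_dir), class = "run_config")
}

#' Validate and normalize a pipeline configuration
#'
#' Fills missing stage toggles and seeds (with a warning for defaulted
#' seeds) and rejects invalid settings: non-positive radii or cohort
#' sizes, and a K other than 8 in paper mode.
#'
#' @param config a \code{run_config} (or bare list).
#' @return the normalized \code{run_config}; invalid configurations abort
#'   with the full error list.
#' @export
validate_config <- function(config) {
  errors <- character(0)
  if (config$n_patients <= 0L) errors <- c(errors, "n_patients must be positive")
  if (config$tiles_per_patient <= 0L) {
    errors <- c(errors, "tiles_per_patient must be positive")
  }
  if (any(config$spec$radii <= 0)) {
    errors <- c(errors, "neighborhood radii must be positive")
  }
  if (config$paper_mode && config$K != 8L) {
    errors <- c(errors,
                "paper mode fixes K = 8 clusters; set paper_mode = FALSE to explore other K")
  }
  if (length(errors) > 0L) {
    rlang::abort(paste0("invalid configuration:\n- ",
                        paste(errors, collapse = "\n- ")))
  }
  for (st in c("segment", "qmif", "genes")) {
    config$stages[[st]] <- isTRUE(config$stages[[st]])
  }
  defaults <- list(simulate = 1L, survival = 2L, cluster = 3L, risk = 4L)
  for (nm in names(defaults)) {
    if (is.null(config$seeds[[nm]])) {
      rlang::warn(sprintf("seed '%s' missing; defaulted to %d", nm,
                          defaults[[nm]]))
      config$seeds[[nm]] <- defaults[[nm]]
    }
  }
  config
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates a cohort of cell maps, extracts the contextual TIL features,
#' fits the phenotype mixture, builds the patient cluster matrix, draws
#' planted survival outcomes from the simulated phenotype counts, fits the
#' elastic-net Cox risk model, and evaluates the stratification. Optional
#' stages add IF subtype pairing and gene association on the same cohort.
#' When \code{out_dir} is set, every stage writes CSV/JSON artifacts and a
#' manifest with their md5 hashes, seeds and library versions; re-running
#' an identical configuration reproduces identical artifact hashes.
#'
#' @param config a [pipeline_config()].
#' @return list with the fitted objects, tables and \code{manifest}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  config <- validate_config(config)
  seeds <- config$seeds

  # --- simulate cohort ------------------------------------------------
  sims <- list()
  for (p in seq_len(config$n_patients)) {
    for (tl in seq_len(config$tiles_per_patient)) {
      key <- sprintf("P%03d_T%d", p, tl)
      sims[[key]] <- gen_cell_map(
        config$sim,
        seed = derive_seed(seeds$simulate,
                           p * config$tiles_per_patient + tl))
    }
  }
  patient_of <- sub("_T\\d+$", "", names(sims))

  # optionally replace simulated cell tables by render + segment + classify
  if (config$stages$segment) {
    sims <- lapply(sims, function(s) {
      rendered <- render_tile(s$cell_map,
                              noise_sd = config$sim$render_noise_sd)
      cm <- extract_descriptors(rendered$image, rendered$mask,
                                microns_per_pixel = config$sim$microns_per_pixel)
      cm <- classify_tils(cm)
      list(cell_map = cm, truth = s$truth)
    })
  }

  # --- contextual features -------------------------------------------
  feats <- purrr::imap(sims, function(s, key) {
    f <- extract_all(s$cell_map, config$spec)
    if (nrow(f) > 0L) {
      f$patient_id <- sub("_T\\d+$", "", key)
      f$tile_id <- key
    }
    f
  })
  features <- dplyr::bind_rows(feats)

  # --- mixture clustering --------------------------------------------
  model <- fit_phenotype_model(features, K = config$K,
                               seed = seeds$cluster)
  labels <- assign_clusters(model, features)
  patients <- sprintf("P%03d", seq_len(config$n_patients))
  N <- suppressWarnings(
    patient_cluster_matrix(labels, features$patient_id, K = config$K,
                           patients = patients))

  # --- planted survival from the simulated phenotype counts ----------
  truth_counts <- matrix(0L, config$n_patients,
                         length(config$sim$beta_star),
                         dimnames = list(patients, NULL))
  for (key in names(sims)) {
    ph <- sims[[key]]$truth$true_phenotype
    ph <- ph[!is.na(ph)]
    if (length(ph) > 0L) {
      tab <- tabulate(ph, nbins = ncol(truth_counts))
      pid <- sub("_T\\d+$", "", key)
      truth_counts[pid, ] <- truth_counts[pid, ] + tab
    }
  }
  survival <- gen_survival(truth_counts, config$sim$beta_star,
                           censor_rate = config$censor_rate,
                           seed = seeds$survival)

  # --- risk model and evaluation -------------------------------------
  risk <- fit_risk_model(N, survival, alpha = config$alpha,
                         seed = seeds$risk)
  scores <- compute_osrs(N, risk)
  groups <- stratify(scores, risk)
  report <- evaluate_survival(survival, groups, scores)

  result <- list(config = config, features = features, model = model,
                 labels = labels, cluster_matrix = N, survival = survival,
                 risk_model = risk, scores = scores, groups = groups,
                 eval = report, truth_counts = truth_counts)

  if (config$stages$qmif) {
    s1 <- sims[[1L]]
    ifs <- gen_if_stack(s1$cell_map, s1$truth,
                        seed = derive_seed(seeds$simulate, 0L))
    rendered <- render_tile(s1$cell_map, noise_sd = 0,
                            seed = derive_seed(seeds$simulate, 1L))
    calls <- quantify_subtype(ifs$stack, rendered$mask, s1$cell_map)
    first_tile_labels <- tibble::tibble(
      til_id = feats[[1L]]$til_id,
      cluster = labels[seq_len(nrow(feats[[1L]]))])
    result$qmif <- list(
      calls = calls,
      composition = cluster_subtype_composition(first_tile_labels, calls,
                                                K = config$K))
  }

  if (config$stages$genes) {
    ge <- gen_expression(N, seed = derive_seed(seeds$simulate, 2L))
    corr <- correlate_expression(ge$expr,
                                 cbind(N, OSRS = scores))
    result$genes <- list(expr_truth = ge$planted_genes, correlation = corr,
                         activation = select_activation_genes(corr))
  }

  if (!is.null(config$out_dir)) {
    result$manifest <- write_run_artifacts(result, config$out_dir)
  }
  result
}

write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    features = file.path(out_dir, "features.csv"),
    labels = file.path(out_dir, "labels.csv"),
    cluster_matrix = file.path(out_dir, "cluster_matrix.csv"),
    survival = file.path(out_dir, "survival.csv"),
    scores = file.path(out_dir, "scores.csv"),
    phenotype_model = file.path(out_dir, "phenotype_model.json"),
    risk_model = file.path(out_dir, "risk_model.json"),
    km = file.path(out_dir, "km_curves.csv"))
  utils::write.csv(result$features, paths$features, row.names = FALSE)
  utils::write.csv(tibble::tibble(til_id = result$features$til_id,
                                  patient_id = result$features$patient_id,
                                  cluster = result$labels),
                   paths$labels, row.names = FALSE)
  utils::write.csv(as.data.frame(result$cluster_matrix),
                   paths$cluster_matrix, row.names = TRUE)
  utils::write.csv(result$survival, paths$survival, row.names = FALSE)
  utils::write.csv(tibble::tibble(patient_id = rownames(result$cluster_matrix),
                                  osrs = result$scores,
                                  group = as.character(result$groups)),
                   paths$scores, row.names = FALSE)
  write_phenotype_model(result$model, paths$phenotype_model)
  write_risk_model(result$risk_model, paths$risk_model)
  utils::write.csv(result$eval$km, paths$km, row.names = FALSE)
  hashes <- vapply(paths, function(p) unname(tools::md5sum(p)),
                   character(1))
  manifest <- list(
    seeds = result$config$seeds,
    n_patients = result$config$n_patients,
    tiles_per_patient = result$config$tiles_per_patient,
    K = result$config$K,
    artifacts = as.list(hashes),
    versions = list(R = paste(R.version$major, R.version$minor, sep = "."),
                    phenotil = as.character(utils::packageVersion("phenotil"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
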