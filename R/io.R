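#' Load a study from map and data files
#'
#' The map file is a region CSV (`region_id` + `x`/`y` or `lon`/`lat`) or a
#' GeoJSON polygon file; the data CSV needs a `y` column, a `region_id`
#' column, and one column per covariate (all remaining columns).
#'
#' @param map_path,data_path,adjacency_path File paths (adjacency optional).
#' @return A list with `map` ([area_map()]) and `table`
#'   ([observation_table()]).
#' @export
load_study <- function(map_path, data_path, adjacency_path = NULL) {
  map <- read_area_map(map_path, adjacency_path)
  df <- utils::read.csv(data_path, stringsAsFactors = FALSE)
  need <- c("region_id", "y")
  if (!all(need %in% names(df))) {
    stop("data CSV must contain columns: ", paste(need, collapse = ", "))
  }
  covs <- setdiff(names(df), need)
  if (!length(covs)) stop("data CSV has no covariate columns")
  X <- as.matrix(df[, covs, drop = FALSE])
  table <- observation_table(df$y, X, df$region_id, map)
  list(map = map, table = table)
}

#' Write posterior draws to a columnar on-disk layout
#'
#' Each parameter block becomes a wide CSV (rows = kept iterations) under
#' `dir`, alongside a JSON `manifest.json` recording the model
#' specification, priors, MCMC settings, seed and draw counts.
#'
#' @param draws A `bgwr_draws` or `bgwr_select_draws` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_draws <- function(draws, dir) {
  stopifnot(inherits(draws, "bgwr_draws"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dims <- dim(draws$beta)
  flatten <- function(a) {
    m <- matrix(a, nrow = dim(a)[1])
    colnames(m) <- as.vector(outer(dimnames(a)[[2]], dimnames(a)[[3]],
                                   paste, sep = "."))
    m
  }
  fwrite17 <- function(m, path) {
    # 17 significant digits: doubles round-trip bit-exactly through text
    df <- as.data.frame(lapply(as.data.frame(m), function(v) {
      if (is.double(v)) sprintf("%.17g", v) else v
    }), check.names = FALSE)
    data.table::fwrite(df, path, quote = FALSE)
  }
  fwrite17(flatten(draws$beta), file.path(dir, "beta.csv"))
  fwrite17(draws$sigma2, file.path(dir, "sigma2.csv"))
  fwrite17(data.frame(sigma_beta2 = draws$sigma_beta2,
                      bandwidth = draws$bandwidth),
           file.path(dir, "global.csv"))
  if (!is.null(draws$gamma)) {
    data.table::fwrite(as.data.frame(flatten(draws$gamma)),
                       file.path(dir, "gamma.csv"))
    fwrite17(draws$psi, file.path(dir, "psi.csv"))
  }
  manifest <- list(
    class = class(draws)[1],
    n_draws = dims[1], n_regions = dims[2], n_covariates = dims[3],
    region_ids = dimnames(draws$beta)[[2]],
    covariate_names = dimnames(draws$beta)[[3]],
    kernel = unclass(draws$kernel), priors = unclass(draws$priors),
    settings = unclass(draws$settings),
    accept_rate = draws$accept_rate)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read posterior draws written by [write_draws()]
#'
#' @param dir Directory containing the CSV blocks and `manifest.json`.
#' @return A `bgwr_draws` or `bgwr_select_draws` object (without the
#'   original map/table, which are not serialized).
#' @export
read_draws <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  unflatten <- function(path) {
    m <- as.matrix(data.table::fread(path))
    storage.mode(m) <- "double"
    array(m, dim = c(nrow(m), manifest$n_regions, manifest$n_covariates),
          dimnames = list(NULL, manifest$region_ids,
                          manifest$covariate_names))
  }
  beta <- unflatten(file.path(dir, "beta.csv"))
  sigma2 <- as.matrix(data.table::fread(file.path(dir, "sigma2.csv")))
  glb <- data.table::fread(file.path(dir, "global.csv"))
  out <- list(beta = beta, sigma2 = sigma2,
              sigma_beta2 = glb$sigma_beta2, bandwidth = glb$bandwidth,
              accept_rate = manifest$accept_rate,
              kernel = structure(manifest$kernel, class = "kernel_spec"),
              priors = structure(manifest$priors, class = "prior_spec"),
              settings = structure(manifest$settings, class = "mcmc_settings"))
  if (file.exists(file.path(dir, "gamma.csv"))) {
    out$gamma <- unflatten(file.path(dir, "gamma.csv"))
    out$psi <- as.matrix(data.table::fread(file.path(dir, "psi.csv")))
    class(out) <- c("bgwr_select_draws", "bgwr_draws")
  } else {
    class(out) <- "bgwr_draws"
  }
  out
}

#' Write a synthetic study to CSV files
#'
#' Produces `map.csv`, `data.csv`, `truth.csv` and a seed-stamped
#' `manifest.json` under `dir`.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) as.data.frame(lapply(df, function(v) {
    if (is.double(v)) sprintf("%.17g", v) else v
  }), check.names = FALSE)
  cent <- study$map$centroids
  data.table::fwrite(fmt(data.frame(region_id = study$map$region_ids,
                                    x = cent[, 1], y = cent[, 2])),
                     file.path(dir, "map.csv"), quote = FALSE)
  data.table::fwrite(fmt(data.frame(region_id = study$table$obs_region,
                                    y = study$table$y, study$table$X,
                                    check.names = FALSE)),
                     file.path(dir, "data.csv"), quote = FALSE)
  truth <- data.frame(region_id = rownames(study$true_beta),
                      study$true_beta, check.names = FALSE)
  if (!is.null(study$true_clusters)) truth$cluster <- study$true_clusters
  data.table::fwrite(truth, file.path(dir, "truth.csv"))
  jsonlite::write_json(list(setting = study$setting, seed = study$seed,
                            generator = study$generator),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a cluster configuration and its probabilities to CSV
#'
#' @param config A `cluster_config`.
#' @param path Output CSV path for the per-region assignment; when the
#'   configuration carries per-label probabilities they are written next to
#'   it as `<path-sans-ext>_probabilities.csv`.
#' @param region_ids Optional region identifiers.
#' @return `path`, invisibly.
#' @export
write_configuration <- function(config, path, region_ids = NULL) {
  stopifnot(inherits(config, "cluster_config"))
  if (is.null(region_ids)) {
    region_ids <- seq_along(config$assignment)
  }
  data.table::fwrite(data.frame(region_id = region_ids,
                                cluster = config$assignment,
                                method = config$method),
                     path)
  if (!is.null(config$probabilities)) {
    data.table::fwrite(data.frame(region_id = region_ids,
                                  config$probabilities, check.names = FALSE),
                       sub("\\.csv$", "_probabilities.csv", path))
  }
  invisible(path)
}

#' Run the full simulate / fit / select / cluster / assess pipeline
#'
#' A scripted end-to-end run: generate (or load) a study, fit the BGWR
#' model, optionally run variable selection, cluster the posterior
#' coefficient surfaces, assess the fit, and write every artifact with a
#' manifest into `output_dir`.
#'
#' @param config A list with elements `seed`, `output_dir`, and optional
#'   `study` (a `synthetic_study`; default a seeded [louisiana_like()]
#'   study), `kernel` ([kernel_spec()]), `priors`, `settings`, `select`
#'   (logical), `cluster` (list of [two_stage_configuration()] arguments),
#'   `assess` (logical).
#' @return Invisibly, a list of the produced objects and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$output_dir))
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  study <- if (!is.null(config$study)) config$study else louisiana_like(seed)
  write_study(study, file.path(out_dir, "study"))

  kernel <- if (!is.null(config$kernel)) config$kernel
            else kernel_spec("exponential", D = 100)
  priors <- if (!is.null(config$priors)) config$priors else prior_spec()
  settings <- if (!is.null(config$settings)) config$settings
              else mcmc_settings(iterations = 2000, burn_in = 500, seed = seed)

  fit_fun <- if (isTRUE(config$select)) run_bgwr_select else run_bgwr
  draws <- fit_fun(study$table, study$map, kernel, priors, settings)
  write_draws(draws, file.path(out_dir, "draws"))
  message(sprintf("bandwidth acceptance rate: %.2f", draws$accept_rate))
  if (!is.na(draws$accept_rate) &&
      (draws$accept_rate < 0.1 || draws$accept_rate > 0.6)) {
    warning("bandwidth acceptance rate outside [0.1, 0.6]; ",
            "consider tuning bandwidth_step")
  }

  result <- list(study = study, draws = draws)
  summary_df <- posterior_summary(draws)
  data.table::fwrite(summary_df, file.path(out_dir, "summary.csv"))

  if (!is.null(config$cluster)) {
    cl_args <- config$cluster
    cl_args$draws <- draws
    if (is.null(cl_args$seed)) cl_args$seed <- seed
    cfg <- do.call(two_stage_configuration, cl_args)
    write_configuration(cfg, file.path(out_dir, "clusters.csv"),
                        region_ids = study$map$region_ids)
    result$configuration <- cfg
  }
  if (!identical(config$assess, FALSE)) {
    fa <- assess_fit(draws)
    jsonlite::write_json(list(waic = fa$waic, dic = fa$dic, p_d = fa$p_d,
                              p_waic = fa$p_waic, n_draws = fa$n_draws),
                         file.path(out_dir, "assessment.json"),
                         auto_unbox = TRUE, digits = NA)
    result$assessment <- fa
  }
  jsonlite::write_json(list(seed = seed, select = isTRUE(config$select),
                            kernel = unclass(kernel),
                            priors = unclass(priors),
                            settings = unclass(settings)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(result)
}
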