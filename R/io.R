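#' Canonical per-vertex fit table
#'
#' Flattens a `fit_result` into the canonical interchange schema: one row
#' per vertex with columns `vertex_id`, `hemisphere`, `condition`, `model`,
#' `pass`, `mu`, `sigma`, `beta`, `r2`, `bic`, `flags` (`"ok"` or
#' `"invalid"`). Mixture fits report the eye component in `mu`/`sigma` and
#' carry the mouth component in extra columns.
#'
#' @param fit a `fit_result` data.frame.
#' @param hemisphere per-vertex hemisphere labels (recycled if length 1).
#' @param condition condition tag (`"spatial"`, `"face"`, ...).
#' @param pass pass tag (`"pass1"` or `"pass2"`).
#' @return data.frame in the canonical schema.
#' @export
fit_table <- function(fit, hemisphere = "H01", condition = "spatial",
                      pass = "pass2") {
  model <- attr(fit, "model") %||% "gaussian"
  if (model == "mog") {
    base <- data.frame(vertex_id = fit$vertex_id, hemisphere = hemisphere,
                       condition = condition, model = model, pass = pass,
                       mu = fit$mu_eye, sigma = fit$sigma_eye,
                       beta = fit$beta_eye, r2 = fit$r2, bic = fit$bic,
                       flags = ifelse(fit$valid, "ok", "invalid"),
                       mu_mouth = fit$mu_mouth, sigma_mouth = fit$sigma_mouth,
                       beta_mouth = fit$beta_mouth)
  } else {
    base <- data.frame(vertex_id = fit$vertex_id, hemisphere = hemisphere,
                       condition = condition, model = model, pass = pass,
                       mu = fit$mu, sigma = fit$sigma, beta = fit$beta,
                       r2 = fit$r2, bic = fit$bic,
                       flags = ifelse(fit$valid, "ok", "invalid"))
  }
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fit_table_required <- c("vertex_id", "hemisphere", "condition", "model",
                         "pass", "mu", "sigma", "beta", "r2", "bic", "flags")

#' Write / read a fit table as TSV
#'
#' Lossless roundtrip of the canonical schema; reading validates the header
#' and names any missing column in the error.
#'
#' @param table a fit table ([fit_table()]) or any data.frame with the
#'   canonical columns.
#' @param path TSV path.
#' @return `write_fit_table`: `path` invisibly; `read_fit_table`: the table.
#' @export
write_fit_table <- function(table, path) {
  miss <- setdiff(.fit_table_required, names(table))
  if (length(miss))
    stop("fit table schema error: missing column(s): ", paste(miss, collapse = ", "))
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fit_table
#' @export
read_fit_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  miss <- setdiff(.fit_table_required, names(tab))
  if (length(miss))
    stop("fit table schema error: missing column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Pipeline configuration
#'
#' Collects every tunable of the synthetic end-to-end pipeline in one
#' validated structure: cohort size, run designs, search grids, the fit and
#' HRF-inclusion thresholds, coverage selection criteria, permutation
#' counts, seeds and analysis flags.
#'
#' @param n_vertices vertices per hemisphere.
#' @param n_hemispheres hemisphere count.
#' @param designs named list with `spatial` and `face` `run_design`s.
#' @param mu_step,sigma_exp_step grid pitches (defaults 0.005 and 0.05, the
#'   canonical search grids; coarser values speed up demos).
#' @param r2_fit map threshold on R-squared (default 0.3).
#' @param r2_hrf_inclusion HRF-fit inclusion threshold (default 0.2).
#' @param noise_sd,n_runs cohort noise level and runs per condition.
#' @param n_null null-series count for the FDR bound (default 5000).
#' @param coverage list: `r2_min`, `sigma_max_dva`, `min_ecc_dva`,
#'   `n_shuffles` (default 100000).
#' @param split_permutations permutations for split-condition tests.
#' @param seed master seed.
#' @param flags list of logicals: `fine_fit`, `spearman`, `restricted`,
#'   `mog`.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_vertices = 125L, n_hemispheres = 4L,
                            designs = list(spatial = make_run_design("spatial"),
                                           face = make_run_design("face")),
                            mu_step = 0.005, sigma_exp_step = 0.05,
                            r2_fit = 0.3, r2_hrf_inclusion = 0.2,
                            noise_sd = 5, n_runs = 17L, n_null = 5000L,
                            coverage = list(r2_min = 0.5, sigma_max_dva = 3,
                                            min_ecc_dva = 1,
                                            n_shuffles = 100000L),
                            split_permutations = 10000L, seed = 1L,
                            flags = list(fine_fit = FALSE, spearman = FALSE,
                                         restricted = FALSE, mog = FALSE)) {
  cfg <- list(n_vertices = n_vertices, n_hemispheres = n_hemispheres,
              designs = designs, mu_step = mu_step,
              sigma_exp_step = sigma_exp_step, r2_fit = r2_fit,
              r2_hrf_inclusion = r2_hrf_inclusion, noise_sd = noise_sd,
              n_runs = n_runs, n_null = n_null, coverage = coverage,
              split_permutations = split_permutations, seed = seed,
              flags = flags)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  required <- c("n_vertices", "n_hemispheres", "designs", "mu_step",
                "sigma_exp_step", "r2_fit", "r2_hrf_inclusion", "noise_sd",
                "n_runs", "n_null", "coverage", "split_permutations",
                "seed", "flags")
  miss <- setdiff(required, names(cfg))
  if (length(miss)) stop("missing required key: ", paste(miss, collapse = ", "))
  for (k in c("r2_fit", "r2_hrf_inclusion"))
    if (cfg[[k]] < 0 || cfg[[k]] > 1) stop("threshold out of [0, 1]: ", k)
  if (cfg$coverage$n_shuffles < 1L || cfg$split_permutations < 1L)
    stop("permutation counts must be >= 1")
  if (!all(c("spatial", "face") %in% names(cfg$designs)))
    stop("missing required key: designs (spatial and face)")
  invisible(cfg)
}

# small polynomial rolling hash of the canonical JSON form of the config
# (JSON canonicalization makes the hash stable across a write/read roundtrip)
config_hash <- function(cfg) {
  s <- utf8ToInt(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                               digits = NA, force = TRUE)))
  h <- 0
  for (b in s) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> preprocess -> two-pass fit -> null/FDR -> map
#' statistics -> coverage permutation, and writes every declared artifact
#' into `out_dir`: fit tables (TSV), the fitted HRF (JSON), the null
#' R-squared distribution (TSV), the coverage curves (TSV + JSON), a
#' `report.json` with all statistics, and `log.txt` with the package
#' version, seed and config hash. With `resume = TRUE`, stages whose
#' artifact already exists under the same config hash are skipped.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if absent).
#' @param resume reuse existing artifacts from a partial earlier run.
#' @return (invisibly) list with `report`, `pairs`, `fits`, `coverage`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  logf <- file.path(out_dir, "log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat(sprintf("ptcmap %s | seed %d | config %s | %s\n",
              as.character(utils::packageVersion("ptcmap")), config$seed,
              hash, format(Sys.time())), file = logf)

  state <- file.path(out_dir, "state.json")
  fresh <- !(resume && file.exists(state) &&
               identical(jsonlite::read_json(state)$hash, hash))
  jsonlite::write_json(list(hash = hash, seed = config$seed), state,
                       auto_unbox = TRUE)

  mu_grid <- seq(-0.2, 1.2, by = config$mu_step)
  sigma_grid <- 2^seq(-5.6, 1, by = config$sigma_exp_step)

  logline("stage: simulate")
  truth <- make_ground_truth(config$n_vertices, config$n_hemispheres,
                             noise_sd = config$noise_sd,
                             n_runs = config$n_runs, seed = config$seed)
  sim <- simulate_dataset(truth, designs = config$designs)

  logline("stage: fit")
  tp <- two_pass_fit(list(spatial = sim$spatial, face = sim$face),
                     sim$apertures, mu_grid = mu_grid,
                     sigma_grid = sigma_grid,
                     inclusion_r2 = config$r2_hrf_inclusion,
                     fine = isTRUE(config$flags$fine_fit))
  write_hrf(tp$hrf, file.path(out_dir, "hrf.json"))
  for (cn in c("spatial", "face"))
    for (ps in c("pass1", "pass2"))
      write_fit_table(fit_table(tp$fits[[cn]][[ps]], truth$hemisphere, cn, ps),
                      file.path(out_dir, sprintf("fits_%s_%s.tsv", cn, ps)))

  logline("stage: null/FDR")
  null_path <- file.path(out_dir, "null_r2.tsv")
  if (fresh || !file.exists(null_path)) {
    nulls <- simulate_null(config$n_null, config$designs$spatial,
                           n_runs = config$n_runs, seed = config$seed + 1000L)
    pg_null <- prediction_grid(sim$apertures$spatial, mu_grid, sigma_grid,
                               tp$hrf)
    null_r2 <- coarse_fit(nulls, pg_null)$r2
    write_null_r2(null_r2, null_path)
  } else null_r2 <- read_null_r2(null_path)
  roi_r2 <- c(tp$fits$spatial$pass2$r2, tp$fits$face$pass2$r2)
  fdr <- tryCatch(fdr_upper_bound(null_r2, roi_r2, config$r2_fit),
                  error = function(e) list(p_fdr = NA, error = conditionMessage(e)))

  logline("stage: map statistics")
  pairs <- tuning_pairs(tp$fits$spatial$pass2, tp$fits$face$pass2,
                        truth$axis_position, truth$hemisphere)
  method <- if (isTRUE(config$flags$spearman)) "spearman" else "pearson"
  restricted <- isTRUE(config$flags$restricted)
  g <- function(what, domain = "spatial")
    tryCatch(unclass(group_ttest(suppressWarnings(
      map_correlations(pairs, what, domain, method, config$r2_fit, restricted)),
      method)),
      error = function(e) list(error = conditionMessage(e)))
  map_stats <- list(
    sigma_vs_axis_spatial = g("sigma_vs_axis", "spatial"),
    sigma_vs_axis_face = g("sigma_vs_axis", "face"),
    mu_cross = g("mu_cross"), sigma_cross = g("sigma_cross"),
    sigma_vs_ecc_spatial = g("sigma_vs_ecc", "spatial"),
    sigma_vs_ecc_face = g("sigma_vs_ecc", "face"))

  mog_stats <- NULL
  if (isTRUE(config$flags$mog)) {
    logline("stage: MoG/BIC")
    mf <- fit_mog(sim$face, sim$apertures$face, tp$hrf)
    write_fit_table(fit_table(mf, truth$hemisphere, "face", "pass2"),
                    file.path(out_dir, "fits_face_mog.tsv"))
    bc <- bic_compare(tp$fits$face$pass2, mf, nrow(sim$face$values))
    mog_stats <- bc[c("median_delta", "t_value", "df", "p_two_sided")]
  }

  logline("stage: coverage")
  sel <- select_coverage_vertices(pairs, config$coverage$r2_min,
                                  config$coverage$sigma_max_dva,
                                  config$coverage$min_ecc_dva)
  cov <- NULL
  if (nrow(sel$uvf) > 0L && nrow(sel$lvf) > 0L) {
    cov <- coverage_permutation(sel$uvf, sel$lvf,
                                n_shuffles = config$coverage$n_shuffles,
                                seed = config$seed + 2000L)
    write_coverage(cov, file.path(out_dir, "coverage.tsv"))
  } else logline("coverage skipped: empty group")

  utils::write.table(pairs, file.path(out_dir, "pairs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  report <- list(config_hash = hash, seed = config$seed,
                 n_vertices = nrow(pairs),
                 median_r2 = list(spatial = stats::median(pairs$sp_r2),
                                  face = stats::median(pairs$face_r2)),
                 prop_above_threshold = list(
                   spatial = mean(pairs$sp_r2 > config$r2_fit),
                   face = mean(pairs$face_r2 > config$r2_fit)),
                 fdr = fdr, map_stats = map_stats, mog = mog_stats,
                 coverage = if (is.null(cov)) NULL else
                   list(n_uvf = cov$n_uvf, n_lvf = cov$n_lvf,
                        n_significant = sum(cov$sig_mask),
                        min_p = min(cov$p_point), p_floor = cov$p_floor),
                 hrf = unclass(tp$hrf))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  logline("done")
  invisible(list(report = report, pairs = pairs, fits = tp, coverage = cov,
                 out_dir = out_dir))
}

#' Serialize / load a pipeline configuration as JSON
#'
#' Designs are stored by kind plus overridden fields and rebuilt through
#' [make_run_design()] on load.
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @return `write_config`: path invisibly; `read_config`: a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$designs <- lapply(cfg$designs, function(d)
    d[setdiff(names(d), "space_edges")])
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$designs <- lapply(cfg$designs, function(d)
    make_run_design(d$kind, overrides = d[setdiff(names(d), "kind")]))
  cfg$flags <- as.list(cfg$flags)
  cfg$coverage <- as.list(cfg$coverage)
  do.call(pipeline_config, cfg[setdiff(names(cfg), character(0))])
}
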