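#' Run the full network-inference analysis on a screen
#'
#' End-to-end orchestration of the method: build the lag-pair matrices at
#' (`t_in`, `t_out`), z-score them, fit one PLS model per output protein
#' (self term included among the predictors), accept or reject each model by
#' K-fold cross-validation with the variance gate, build a permutation null
#' per output, threshold the coefficient-to-null-sd ratios, refit minimal
#' least-squares models on the significant predictors and assemble the
#' signed directed network.
#'
#' @param screen Screen tibble ([as_screen()] dialect).
#' @param t_in,t_out Lag-pair times in minutes (default 1 and 3).
#' @param k Cross-validation fold count (default 10).
#' @param n_random Output-shuffled models per cross-validation (default
#'   100).
#' @param n_shuffles Permutation-null size per output (default 1000).
#' @param level Confidence level for edge significance (default 0.99).
#' @param variance_threshold Minimum training R^2 for model acceptance
#'   (default 0.5).
#' @param max_components Upper bound on PLS components (default: number of
#'   proteins).
#' @param seed Master seed; all stage seeds derive from it.
#' @return Object of class `phos_analysis`: `pairs` (normalized lag pairs),
#'   `correlation`, per-output `fits`, `validations`, `nulls`,
#'   `minimal_models`, the `edge_test`, `accepted` outputs, the assembled
#'   `network`, and the call parameters.
#' @export
analyze_screen <- function(screen, t_in = 1, t_out = 3, k = 10,
                           n_random = 100, n_shuffles = 1000, level = 0.99,
                           variance_threshold = 0.5, max_components = NULL,
                           seed = 1) {
  screen <- as_screen(screen)
  pairs <- zscore_normalize(build_lag_pairs(screen, t_in, t_out))
  X <- pairs$X
  proteins <- colnames(X)
  max_components <- max_components %||% ncol(X)

  fits <- list(); validations <- list(); nulls <- list()
  for (j in seq_along(proteins)) {
    o <- proteins[j]
    y <- pairs$Y[, o]
    fits[[o]] <- fit_pls1(X, y, max_components = max_components, output = o)
    validations[[o]] <- kfold_validate(
      X, y, k = k, n_random = n_random,
      seed = derive_seed(seed, j), max_components = max_components,
      output = o, variance_threshold = variance_threshold
    )
    nulls[[o]] <- permutation_null(
      X, y, n_shuffles = n_shuffles, seed = derive_seed(seed, 10000 + j),
      ncomp = fits[[o]]$n_components, output = o
    )
  }

  B <- t(vapply(proteins, function(o) fits[[o]]$b, numeric(ncol(X))))
  dimnames(B) <- list(proteins, proteins)
  edge_test <- significant_edges(B, nulls, level = level)
  accepted <- proteins[vapply(proteins, function(o) validations[[o]]$accepted,
                              logical(1))]
  network <- assemble_network(edge_test, accepted = accepted)

  minimal_models <- list()
  for (o in accepted) {
    sel <- proteins[edge_test$significant[o, ]]
    minimal_models[[o]] <- fit_minimal(X, pairs$Y[, o], sel, output = o)
  }

  structure(
    list(
      pairs = pairs,
      correlation = dynamic_correlation(pairs),
      fits = fits, validations = validations, nulls = nulls,
      edge_test = edge_test, accepted = accepted,
      minimal_models = minimal_models, network = network,
      t_in = t_in, t_out = t_out, k = k, n_random = n_random,
      n_shuffles = n_shuffles, level = level,
      variance_threshold = variance_threshold, seed = seed
    ),
    class = "phos_analysis"
  )
}

#' @export
print.phos_analysis <- function(x, ...) {
  cat(sprintf(
    "<phos_analysis> %d proteins, %d rows (t %g -> %g min): %d/%d models accepted, %d edges\n",
    ncol(x$pairs$X), nrow(x$pairs$X), x$t_in, x$t_out,
    length(x$accepted), length(x$fits), sum(x$network$A != 0)
  ))
  invisible(x)
}

#' Declarative pipeline configuration
#'
#' Validates and freezes every tunable of [run_pipeline()]. Invalid values
#' raise an error naming the offending field.
#'
#' @param screen_path Path to an existing screen CSV, or `NULL` to simulate.
#' @param sim List of [generate_ground_truth()] / [simulate_screen()]
#'   arguments used when `screen_path` is `NULL` (e.g. `n_proteins`,
#'   `cross_density`, `n_conditions`, `timepoints`).
#' @param t_in,t_out Lag-pair times (minutes).
#' @param k,n_random,n_shuffles,level,variance_threshold Modeling settings,
#'   as in [analyze_screen()].
#' @param extrapolate_to Horizon time in minutes, or `NULL` to skip
#'   extrapolation.
#' @param merge_groups Named list of variant-node groups to merge, or
#'   `NULL`.
#' @param out_dir Output directory for artifacts.
#' @param seed Master seed recorded in every artifact's metadata sidecar.
#' @return A validated `phos_config` list with a stable `hash`.
#' @export
pipeline_config <- function(screen_path = NULL, sim = list(), t_in = 1,
                            t_out = 3, k = 10, n_random = 100,
                            n_shuffles = 1000, level = 0.99,
                            variance_threshold = 0.5, extrapolate_to = 10,
                            merge_groups = NULL, out_dir = "phosnet-run",
                            seed = 1) {
  if (!is.null(screen_path) && !file.exists(screen_path)) {
    abort(sprintf("`screen_path` does not exist: %s", screen_path))
  }
  check_number(t_in, "t_in", lower = 0)
  check_number(t_out, "t_out", lower = 0)
  if (t_in >= t_out) abort("`t_in` must be less than `t_out`.")
  check_number(k, "k", lower = 2, integerish = TRUE)
  check_number(n_random, "n_random", lower = 1, integerish = TRUE)
  check_number(n_shuffles, "n_shuffles", lower = 1, integerish = TRUE)
  check_number(level, "level", lower = 0, upper = 1, open = TRUE)
  check_number(variance_threshold, "variance_threshold", lower = 0, upper = 1)
  if (!is.null(extrapolate_to)) {
    check_number(extrapolate_to, "extrapolate_to", lower = 0)
  }
  check_number(seed, "seed", lower = 0, upper = .Machine$integer.max,
               integerish = TRUE)
  cfg <- list(
    screen_path = screen_path, sim = sim, t_in = t_in, t_out = t_out,
    k = k, n_random = n_random, n_shuffles = n_shuffles, level = level,
    variance_threshold = variance_threshold,
    extrapolate_to = extrapolate_to, merge_groups = merge_groups,
    out_dir = out_dir, seed = seed
  )
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "phos_config")
}

write_with_meta <- function(write_fn, obj, path, cfg) {
  write_fn(obj, path)
  jsonlite::write_json(
    list(config_hash = cfg$hash, seed = cfg$seed,
         package = "phosnet",
         version = as.character(utils::packageVersion("phosnet"))),
    paste0(path, ".meta.json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Run the pipeline end to end and write artifacts
#'
#' Simulates or reads a screen, runs [analyze_screen()], optionally merges
#' variant nodes, classifies edge consistency for every in-degree-2 node,
#' extrapolates to the configured horizon, and writes all module exports
#' (screen CSV, correlation TSV, validation report, ratio and edge tables,
#' network TSV + DOT, minimal-model JSON, consistency CSVs, extrapolation
#' CSV) under `config$out_dir`. Every artifact gets a `.meta.json` sidecar
#' carrying the config hash and seed; runs with identical configuration are
#' byte-identical.
#'
#' @param config A [pipeline_config()] object.
#' @return The `phos_analysis` object, invisibly, with `artifacts` attached.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "phos_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  log_lines <- c(sprintf("phosnet run, config %s, seed %d",
                         config$hash, config$seed))
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  if (is.null(config$screen_path)) {
    sim <- config$sim
    truth <- generate_ground_truth(
      n_proteins = sim$n_proteins %||% 10,
      cross_density = sim$cross_density %||% 0.1,
      seed = derive_seed(config$seed, 1),
      ligands = sim$ligands %||% afcs_ligands,
      noise_sd = sim$noise_sd %||% 0.2
    )
    screen <- simulate_screen(
      truth,
      n_conditions = sim$n_conditions %||% 251,
      replicates = sim$replicates,
      timepoints = sim$timepoints %||% c(0, 1, 3, 10, 30),
      seed = derive_seed(config$seed, 2)
    )
    write_with_meta(write_truth_edges, truth, out("truth_edges.tsv"), config)
    say("simulated screen: %d records", nrow(screen))
  } else {
    truth <- NULL
    screen <- read_screen(config$screen_path)
    say("read screen: %s (%d records)", config$screen_path, nrow(screen))
  }
  write_with_meta(write_screen, screen, out("screen.csv"), config)

  ana <- analyze_screen(
    screen, t_in = config$t_in, t_out = config$t_out, k = config$k,
    n_random = config$n_random, n_shuffles = config$n_shuffles,
    level = config$level, variance_threshold = config$variance_threshold,
    seed = derive_seed(config$seed, 3)
  )
  say("models accepted: %d / %d", length(ana$accepted), length(ana$fits))

  write_with_meta(write_correlation, ana$correlation,
                  out("correlation.tsv"), config)
  write_with_meta(function(x, p) readr::write_tsv(tidy(x), p),
                  ana$edge_test, out("edge_tests.tsv"), config)
  validation_report <- purrr::map_dfr(ana$validations, tidy)
  write_with_meta(function(x, p) readr::write_tsv(x, p),
                  validation_report, out("validation.tsv"), config)

  net <- ana$network
  if (!is.null(config$merge_groups)) {
    net <- merge_variant_nodes(net, config$merge_groups)
    say("merged %d variant group(s)", length(config$merge_groups))
  }
  write_with_meta(function(x, p) export_network(x, p, "tsv"),
                  net, out("network.tsv"), config)
  write_with_meta(function(x, p) export_network(x, p, "dot"),
                  net, out("network.dot"), config)

  mm <- purrr::map(ana$minimal_models, function(m) {
    list(output = m$output, selected = m$selected,
         coefficients = as.list(m$coefficients),
         sigma_r = m$sigma_r, sigma_f = m$sigma_f,
         f_statistic = m$f_statistic, f_pass = m$f_pass,
         variance_captured = m$variance_captured,
         frac_1sig = m$frac_1sig, frac_2sig = m$frac_2sig)
  })
  write_with_meta(function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                                      digits = NA),
                  mm, out("minimal_models.json"), config)

  indeg2 <- net$nodes[colSums(net$A != 0) == 2]
  for (tgt in indeg2) {
    rep_ <- classify_experiments(net, tgt, screen,
                                 t_in = config$t_in, t_out = config$t_out)
    write_with_meta(function(x, p) readr::write_csv(x$cases, p),
                    rep_, out(sprintf("consistency_%s.csv", tgt)), config)
    write_with_meta(function(x, p) readr::write_csv(ligand_distribution(x), p),
                    rep_, out(sprintf("ligand_distribution_%s.csv", tgt)),
                    config)
  }
  say("consistency reports: %d in-degree-2 node(s)", length(indeg2))

  extra <- NULL
  if (!is.null(config$extrapolate_to) &&
      config$extrapolate_to %in% unique(screen$time_min) &&
      length(ana$minimal_models) > 0) {
    extra <- extrapolate(ana, screen, t_start = config$t_out,
                         t_end = config$extrapolate_to)
    write_with_meta(function(x, p) readr::write_csv(x$predictions, p),
                    extra, out("extrapolation.csv"), config)
    if (!is.null(extra$bands)) {
      write_with_meta(function(x, p) readr::write_tsv(x$bands, p),
                      extra, out("extrapolation_bands.tsv"), config)
    }
    say("extrapolated %g -> %g min", config$t_out, config$extrapolate_to)
  }

  writeLines(log_lines, out("run.log"))
  ana$truth <- truth
  ana$merged_network <- if (!is.null(config$merge_groups)) net else NULL
  ana$extrapolation <- extra
  ana$artifacts <- list.files(config$out_dir)
  ana$config <- config
  invisible(ana)
}
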