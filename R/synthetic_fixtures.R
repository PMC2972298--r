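#' Simulation configuration for synthetic fixtures
#'
#' Defines a complete synthetic study emulating the statistical structure of
#' a gene-index / expression-warehouse input set: skewed library sizes,
#' multinomial EST allocation to TCs, a planted condition-specific TC subset
#' enriched in designated libraries, reporter dropout, and expression
#' columns correlated with the planted enrichment.
#'
#' Defaults describe the reference study conditions used throughout the
#' package: 20 libraries of 2000-5000 ESTs, six of them condition
#' (mycorrhizal-root style) libraries, 1000 TCs of which 100 are planted
#' condition TCs upweighted 10-fold in the condition libraries, and two
#' platforms with two condition-contrast expression columns each where
#' condition TCs shift by 2 on the log2-ratio scale.
#'
#' @param n_libraries Number of cDNA libraries.
#' @param library_size_range Integer (min, max) for uniform library sizes.
#' @param n_tcs Number of TCs.
#' @param n_condition_tcs Number of planted condition-specific TCs.
#' @param n_condition_libraries Number of condition libraries (the first
#'   libraries of the catalog, ids prefixed `#AM`).
#' @param enrichment_factor Relative multinomial weight of condition TCs in
#'   condition libraries (> 1).
#' @param n_experiments Named integer vector: expression columns per
#'   platform, e.g. `c(genechip = 2, oligo = 2)`.
#' @param effect_size Mean log2-ratio shift of condition TCs in the
#'   condition-contrast expression columns.
#' @param noise_sd Gaussian noise standard deviation of expression values.
#' @param reporter_dropout Probability that a TC has no reporter on a
#'   platform.
#' @param multi_reporter_prob Probability of a second reporter per platform.
#' @param singleton_fraction Fraction of each library's ESTs withheld as
#'   singletons (never assembled into a TC), so per-library TC counts sum to
#'   at most the library size.
#' @param go_pool_size Number of distinct GO terms; the first tenth of the
#'   pool is reserved for condition TCs so clusters acquire distinct
#'   predominant terms.
#' @param seed Integer seed; the whole fixture is deterministic given it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_libraries = 20,
                              library_size_range = c(2000, 5000),
                              n_tcs = 1000,
                              n_condition_tcs = 100,
                              n_condition_libraries = 6,
                              enrichment_factor = 10,
                              n_experiments = c(genechip = 2, oligo = 2),
                              effect_size = 2,
                              noise_sd = 0.75,
                              reporter_dropout = 0.05,
                              multi_reporter_prob = 0.1,
                              singleton_fraction = 0.2,
                              go_pool_size = 50,
                              seed = 1L) {
  cfg <- list(n_libraries = n_libraries, library_size_range = library_size_range,
              n_tcs = n_tcs, n_condition_tcs = n_condition_tcs,
              n_condition_libraries = n_condition_libraries,
              enrichment_factor = enrichment_factor, n_experiments = n_experiments,
              effect_size = effect_size, noise_sd = noise_sd,
              reporter_dropout = reporter_dropout,
              multi_reporter_prob = multi_reporter_prob,
              singleton_fraction = singleton_fraction,
              go_pool_size = go_pool_size, seed = as.integer(seed))
  if (n_condition_tcs > n_tcs) stop_config("n_condition_tcs must be <= n_tcs")
  if (n_condition_libraries < 1 && n_condition_tcs > 0) {
    stop_config("need at least one condition library to plant condition TCs")
  }
  if (n_condition_libraries > n_libraries) {
    stop_config("n_condition_libraries must be <= n_libraries")
  }
  if (enrichment_factor <= 1) stop_config("enrichment_factor must be > 1")
  for (p in c(reporter_dropout, multi_reporter_prob, singleton_fraction)) {
    if (p < 0 || p > 1) stop_config("probabilities must be in [0, 1]")
  }
  structure(cfg, class = "simulation_config")
}

#' Generate a complete synthetic input set
#'
#' Draws library sizes uniformly in range; allocates each library's
#' non-singleton ESTs to TCs by weighted multinomial sampling (lognormal
#' base abundances; condition TCs upweighted by the enrichment factor in
#' condition libraries only); builds a reporter map with per-platform
#' dropout; simulates expression columns where condition TCs shift by the
#' effect size; and assigns GO terms with a condition-specific subpool. TCs
#' that receive no EST anywhere are removed (they would be invisible in a
#' real gene index); the manifest records the planted ground truth for the
#' TCs that exist.
#'
#' @param config A `simulation_config`.
#' @param outdir Optional directory; when given, all input files plus the
#'   manifest and a default run config are written there.
#' @return An `est_fixture` list: `catalog`, `compositions`, `selection`
#'   (condition libraries MUST, rest MAY), `reporter_map`, `matrices`,
#'   `go`, `manifest` (data frame `tc_id`, `condition`), `run_config`,
#'   `config`, and `files` (named paths when `outdir` was given).
#' @export
generate_fixture <- function(config, outdir = NULL) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  nl <- config$n_libraries
  ncl <- config$n_condition_libraries
  lib_ids <- c(sprintf("#AM%d", seq_len(ncl)),
               sprintf("L%02d", seq_len(nl - ncl)))
  lib_names <- c(sprintf("mycorrhizal roots library %d (synthetic)", seq_len(ncl)),
                 sprintf("background library %d (synthetic)", seq_len(nl - ncl)))
  sizes <- sample(config$library_size_range[1]:config$library_size_range[2], nl,
                  replace = TRUE)
  catalog <- library_catalog(lib_ids, lib_names, sizes)

  nt <- config$n_tcs
  tc_ids <- sprintf("TC%05d", seq_len(nt))
  condition <- rep(FALSE, nt)
  condition[sample.int(nt, config$n_condition_tcs)] <- TRUE
  base_w <- stats::rlnorm(nt, meanlog = 0, sdlog = 1)

  counts <- matrix(0L, nrow = nt, ncol = nl, dimnames = list(tc_ids, lib_ids))
  for (i in seq_len(nl)) {
    w <- base_w
    if (i <= ncl) w[condition] <- w[condition] * config$enrichment_factor
    n_alloc <- floor(sizes[i] * (1 - config$singleton_fraction))
    counts[, i] <- stats::rmultinom(1, n_alloc, w)[, 1]
  }
  present <- rowSums(counts) >= 1
  counts <- counts[present, , drop = FALSE]
  tc_ids <- tc_ids[present]
  condition <- condition[present]
  compositions <- lapply(seq_along(tc_ids), function(t) {
    tc_composition(tc_ids[t], counts[t, ])
  })

  selection <- library_selection(catalog, must = lib_ids[seq_len(ncl)])

  platforms <- names(config$n_experiments)
  map_rows <- list()
  for (p in platforms) {
    has <- stats::runif(length(tc_ids)) >= config$reporter_dropout
    second <- has & stats::runif(length(tc_ids)) < config$multi_reporter_prob
    for (t in which(has)) {
      nrep <- 1L + as.integer(second[t])
      map_rows[[length(map_rows) + 1]] <- data.frame(
        tc_id = tc_ids[t], platform = p,
        reporter_id = sprintf("%s_%s_r%d", toupper(p), tc_ids[t], seq_len(nrep)),
        score = round(stats::runif(nrep, 100, 1000), 1),
        stringsAsFactors = FALSE)
    }
  }
  reporter_map <- do.call(rbind, map_rows)
  rownames(reporter_map) <- NULL
  class(reporter_map) <- c("reporter_map", "data.frame")

  cond_mu <- stats::setNames(ifelse(condition, config$effect_size, 0), tc_ids)
  matrices <- lapply(platforms, function(p) {
    ent <- reporter_map[reporter_map$platform == p, , drop = FALSE]
    ne <- config$n_experiments[[p]]
    cols <- sprintf("%s_contrast_%d", p, seq_len(ne))
    vals <- matrix(stats::rnorm(nrow(ent) * ne,
                                mean = rep(cond_mu[ent$tc_id], ne),
                                sd = config$noise_sd),
                   nrow = nrow(ent), ncol = ne,
                   dimnames = list(ent$reporter_id, cols))
    structure(list(matrix_id = paste0(p, "_expr"), platform = p,
                   columns = cols, values = round(vals, 4)),
              class = "expression_matrix")
  })

  n_go <- config$go_pool_size
  n_cond_go <- max(1, n_go %/% 10)
  go_ids <- sprintf("GO:%07d", seq_len(n_go) * 977)  # arbitrary spaced ids
  go_names <- sprintf("synthetic term %03d", seq_len(n_go))
  go_ns <- rep(c("molecular_function", "biological_process", "cellular_component"),
               length.out = n_go)
  go_rows <- lapply(seq_along(tc_ids), function(t) {
    pool <- if (condition[t]) seq_len(n_cond_go) else (n_cond_go + 1):n_go
    picks <- sample(pool, min(length(pool), 1 + stats::rbinom(1, 2, 0.5)))
    data.frame(tc_id = tc_ids[t], go_id = go_ids[picks], namespace = go_ns[picks],
               name = go_names[picks], stringsAsFactors = FALSE)
  })
  go <- do.call(rbind, go_rows)
  rownames(go) <- NULL
  class(go) <- c("go_annotation", "data.frame")

  manifest <- data.frame(tc_id = tc_ids, condition = condition,
                         stringsAsFactors = FALSE)
  exps <- do.call(rbind, lapply(matrices, function(m) {
    data.frame(matrix_id = m$matrix_id, column = m$columns, stringsAsFactors = FALSE)
  }))
  rc <- run_config(experiments = exps, seed = config$seed)

  fixture <- structure(list(catalog = catalog, compositions = compositions,
                            selection = selection, reporter_map = reporter_map,
                            matrices = matrices, go = go, manifest = manifest,
                            run_config = rc, config = config),
                       class = "est_fixture")
  if (!is.null(outdir)) {
    fixture$files <- write_fixture(fixture, outdir)
  }
  fixture
}

#' Write a fixture to disk
#'
#' @param fixture An `est_fixture`.
#' @param outdir Output directory (created if absent).
#' @return Named character vector of the written file paths.
#' @export
write_fixture <- function(fixture, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(outdir, x)
  write_library_catalog(fixture$catalog, fp("catalog.tsv"))
  write_tc_compositions(fixture$compositions, fixture$catalog, fp("compositions.tsv"))
  write_library_selection(fixture$selection, fp("selection.tsv"))
  write_reporter_map(fixture$reporter_map, fp("reporter_map.tsv"))
  mats <- character()
  for (m in fixture$matrices) {
    f <- fp(paste0(m$matrix_id, ".tsv"))
    write_expression_matrix(m, f)
    mats[m$matrix_id] <- f
  }
  write_go_annotation(fixture$go, fp("go.tsv"))
  write_tsv_raw(data.frame(tc_id = fixture$manifest$tc_id,
                           condition = as.integer(fixture$manifest$condition)),
                fp("manifest.tsv"))
  write_run_config(fixture$run_config, fp("config.yaml"))
  c(catalog = fp("catalog.tsv"), compositions = fp("compositions.tsv"),
    selection = fp("selection.tsv"), reporter_map = fp("reporter_map.tsv"),
    mats, go = fp("go.tsv"), manifest = fp("manifest.tsv"),
    config = fp("config.yaml"))
}
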