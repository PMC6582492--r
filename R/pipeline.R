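#' Read and validate the experiment tables
#'
#' Reads `devices.csv`, `trees.csv`, `covers.csv` and `removal.csv`,
#' checks schemas and the domain invariants (unique device ids, positive tree
#' heights, cover fractions that are multiples of 1/20 — a warning for real
#' data —, litter/bare complementarity, complete day records), and reports
#' offending rows.
#'
#' @param paths named list or vector with elements `devices`, `trees`,
#'   `covers`, `removal`.
#' @return named list of validated data frames.
#' @export
read_tables <- function(paths) {
  need <- c("devices", "trees", "covers", "removal")
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop("missing input paths: ", paste(miss, collapse = ", "))
  for (nm in need)
    if (!file.exists(paths[[nm]]))
      stop("input file not found: ", paths[[nm]], " (", nm, ")")
  devices <- utils::read.csv(paths[["devices"]], stringsAsFactors = FALSE)
  trees <- utils::read.csv(paths[["trees"]], stringsAsFactors = FALSE)
  covers <- utils::read.csv(paths[["covers"]], stringsAsFactors = FALSE)
  removal <- utils::read.csv(paths[["removal"]], stringsAsFactors = FALSE)
  check_cols <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, ": missing columns ", paste(miss, collapse = ", "))
  }
  check_cols(devices, c("device_id", "grid_id", "row", "col", "x", "y"), "devices")
  check_cols(trees, c("tree_id", "x", "y", "height", "is_algarrobo"), "trees")
  check_cols(covers, c("device_id", cover_variables()), "covers")
  check_cols(removal, c("device_id", "season", "day", "removed"), "removal")
  dup <- devices$device_id[duplicated(devices$device_id)]
  if (length(dup)) stop("duplicated device_id: ", paste(unique(dup), collapse = ", "))
  if (nrow(trees) && any(trees$height <= 0)) {
    bad <- which(trees$height <= 0)
    stop("non-positive tree height at row(s) ", paste(bad, collapse = ", "))
  }
  cv <- as.matrix(covers[, cover_variables()])
  if (any(cv < 0 | cv > 1)) {
    bad <- which(rowSums(cv < 0 | cv > 1) > 0)
    stop("cover fraction outside [0, 1] at row(s) ", paste(bad, collapse = ", "))
  }
  offgrid <- abs(cv * 20 - round(cv * 20)) > 1e-9
  if (any(offgrid))
    warning("cover fractions not multiples of 1/20 at row(s) ",
            paste(unique(which(rowSums(offgrid) > 0)), collapse = ", "),
            " (kept as given)")
  lb <- abs(covers$dense_litter + covers$bare_ground - 1) > 1 / 40 + 1e-9
  if (any(lb))
    warning("dense_litter + bare_ground differs from 1 at row(s) ",
            paste(which(lb), collapse = ", "))
  removal$removed <- as.logical(removal$removed)
  trees$is_algarrobo <- as.logical(trees$is_algarrobo)
  key <- paste(removal$device_id, removal$season, removal$day)
  if (anyDuplicated(key))
    stop("duplicated removal record(s) at row(s) ",
         paste(which(duplicated(key)), collapse = ", "))
  list(devices = devices, trees = trees, covers = covers, removal = removal)
}

#' Analysis configuration
#'
#' @param paths input CSV paths (see [read_tables()]); NULL to simulate.
#' @param sim a [generative_spec()] used when `paths` is NULL.
#' @param tree_intensity_per_ha per-grid tree intensities for simulation.
#' @param class_bounds distance class bounds.
#' @param n_sim_mean,n_sim_var,n_sim_joins Monte-Carlo sample sizes for the
#'   mean selection tests, variance selection tests and join-count/Moran
#'   envelopes.
#' @param retention,transform_map PCA options.
#' @param seed master seed for all analysis resampling.
#' @param outdir output directory for the CSV tables and manifest.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(paths = NULL, sim = NULL,
                            tree_intensity_per_ha = c(J = 150, F = 110, V = 60),
                            class_bounds = list(c(0, 8.5), c(8.5, 12.5),
                                                c(12.5, 17), c(17, 22)),
                            n_sim_mean = 4999L, n_sim_var = 1999L,
                            n_sim_joins = 1999L,
                            retention = "kaiser", transform_map = NULL,
                            seed = 1L, outdir = NULL) {
  if (is.null(paths) && is.null(sim)) sim <- generative_spec("CSR")
  structure(list(paths = paths, sim = sim,
                 tree_intensity_per_ha = tree_intensity_per_ha,
                 class_bounds = class_bounds,
                 n_sim_mean = n_sim_mean, n_sim_var = n_sim_var,
                 n_sim_joins = n_sim_joins,
                 retention = retention, transform_map = transform_map,
                 seed = as.integer(seed), outdir = outdir),
            class = "analysis_config")
}

#' Load an analysis configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [analysis_config()]; the `sim` block is passed to [generative_spec()].
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$p_use)) y$sim$p_use <- do.call(rbind, y$sim$p_use)
    y$sim <- do.call(generative_spec, y$sim)
  }
  if (!is.null(y$class_bounds))
    y$class_bounds <- lapply(y$class_bounds, unlist)
  do.call(analysis_config, y)
}

simulate_inputs <- function(config) {
  sim <- config$sim
  devices <- make_grids()
  trees <- do.call(rbind, lapply(unique(devices$grid_id), function(g) {
    d <- devices[devices$grid_id == g, ]
    ext <- c(min(d$x) - 10, max(d$x) + 10, min(d$y) - 10, max(d$y) + 10)
    intens <- config$tree_intensity_per_ha[[g]]
    tr <- place_trees(ext, intens, seed = derive_seed(sim$seed, paste0("trees/", g)))
    if (nrow(tr)) tr$tree_id <- paste0(g, tr$tree_id)
    tr
  }))
  covers <- gen_microhabitat(devices, trees, seed = derive_seed(sim$seed, "covers"))
  z <- transform_covers(covers, config$transform_map)
  model <- pca_varimax(z, retention = config$retention)
  scores <- weighted_scores(model, z, devices$device_id, weighted = FALSE)
  removal <- simulate_removal(devices, trees, scores, sim)
  list(devices = devices, trees = trees, covers = covers, removal = removal)
}

#' Run the full selectivity analysis
#'
#' Executes the complete pipeline on real (CSV) or synthetic inputs:
#' geometry (distances, distance-class weights, tree distances, DTT weights),
#' microhabitat PCA with varimax rotation and eigenvalue-weighted scores,
#' occupancy analyses (usage, day dependence, GLM deviance table, season
#' independence), the multidimensional nearest-neighbour segregation test per
#' season, randomization selection tests per component/season/null model, and
#' join-count plus Moran correlograms per grid with CSR and DTT envelopes.
#' All outputs are written as CSV plus a JSON manifest when `outdir` is set;
#' the run is deterministic given the configuration.
#'
#' @param config an `analysis_config`.
#' @return list with all result tables (invisibly also written to
#'   `config$outdir`).
#' @export
run_all <- function(config) {
  inputs <- if (!is.null(config$paths)) read_tables(config$paths)
            else simulate_inputs(config)
  devices <- inputs$devices; trees <- inputs$trees
  covers <- inputs$covers; removal <- inputs$removal
  seasons <- unique(removal$season)

  # geometry
  tree_dist <- nearest_tree_distances(devices, trees)
  dttw <- dtt_weights(tree_dist)

  # microhabitat ordination
  z <- transform_covers(covers[match(devices$device_id, covers$device_id), ],
                        config$transform_map)
  model <- pca_varimax(z, retention = config$retention)
  scores_u <- weighted_scores(model, z, devices$device_id, weighted = FALSE)
  scores_w <- weighted_scores(model, z, devices$device_id, weighted = TRUE)
  comp <- colnames(model$loadings)

  # occupancy
  usage <- make_usage(removal)
  if (!"grid_id" %in% names(usage))
    usage <- merge(usage, devices[, c("device_id", "grid_id")],
                   by = "device_id", sort = FALSE)
  day_dep <- lapply(stats::setNames(seasons, seasons), function(s)
    day_dependence_test(removal[removal$season == s, ]))
  cells <- stats::aggregate(used ~ season + grid_id, data = usage, FUN = sum)
  cells$total <- stats::aggregate(used ~ season + grid_id, data = usage,
                                  FUN = length)$used
  devtab <- removal_deviance_analysis(cells)
  indep <- lapply(stats::setNames(unique(usage$grid_id), unique(usage$grid_id)),
    function(g) {
      ug <- usage[usage$grid_id == g, ]
      counts <- tapply(ug$used, ug$device_id, sum)
      p_s <- tapply(ug$used, ug$season, mean)
      season_independence_test(as.integer(counts), as.numeric(p_s))
    })

  # multidimensional segregation per season (weighted scores)
  smat <- as.matrix(scores_w[, comp])
  graph <- nn_graph(smat)
  seg <- do.call(rbind, lapply(seasons, function(s) {
    us <- usage$used[usage$season == s][match(devices$device_id,
                                              usage$device_id[usage$season == s])]
    pc <- pair_counts(us, graph)
    dt <- dixon_test(pc, graph = graph)
    data.frame(season = s, N11 = dt$N11, E11 = dt$E11, Z11 = dt$Z11, P11 = dt$P11,
               N00 = dt$N00, E00 = dt$E00, Z00 = dt$Z00, P00 = dt$P00,
               C = dt$C, P_C = dt$P_C)
  }))

  # unidimensional selection tests (unweighted rotated scores)
  sel <- list(); si <- 0L
  for (s in seasons) {
    us <- usage$used[usage$season == s][match(devices$device_id,
                                              usage$device_id[usage$season == s])]
    for (cc in comp) for (mdl in c("pooled", "stratified"))
      for (st in c("mean", "variance")) {
        ns <- if (st == "mean") config$n_sim_mean else config$n_sim_var
        tst <- selection_test(scores_u[[cc]], us, devices$grid_id, st, mdl, ns,
                              seed = derive_seed(config$seed,
                                                 paste("sel", s, cc, mdl, st)))
        si <- si + 1L
        sel[[si]] <- data.frame(component = cc, season = s, model = mdl,
                                statistic = st, observed = tst$observed,
                                expectation = tst$expectation,
                                lo = tst$lo, hi = tst$hi, pseudo_P = tst$pseudo_P)
      }
  }
  sel <- do.call(rbind, sel)

  # spatial correlograms per grid
  corr <- list(); mor <- list(); ci <- 0L; mi <- 0L
  for (g in unique(devices$grid_id)) {
    gi <- devices$grid_id == g
    W <- distance_class_weights(pairwise_distances(cbind(devices$x, devices$y)[gi, ]),
                                config$class_bounds)
    wg <- dttw[gi]
    for (s in seasons) {
      ug <- usage[usage$season == s & usage$grid_id == g, ]
      us <- ug$used[match(devices$device_id[gi], ug$device_id)]
      for (k in seq_along(W)) {
        env_c <- csr_envelope(us, W[[k]], n_sim = config$n_sim_joins,
                              seed = derive_seed(config$seed,
                                                 paste("csr", g, s, k)))
        env_d <- if (sum(wg > 0) >= sum(us))
          dtt_envelope(wg, us, W[[k]], n_sim = config$n_sim_joins,
                       seed = derive_seed(config$seed, paste("dtt", g, s, k)))
          else NULL
        for (env in Filter(Negate(is.null), list(env_c, env_d))) {
          ci <- ci + 1L
          corr[[ci]] <- data.frame(grid = g, season = s, class = k,
                                   observed_pct = env$observed,
                                   null_model = env$null_model,
                                   median = env$median, lo = env$lo,
                                   hi = env$hi, pseudo_P = env$pseudo_P)
        }
      }
    }
    contvars <- c(stats::setNames(as.list(scores_u[gi, comp]), comp),
                  list(d_tree3 = tree_dist$d_tree3[gi],
                       d_alg4 = tree_dist$d_alg4[gi]))
    contvars <- Filter(function(v) stats::sd(v) > 0 && all(is.finite(v)), contvars)
    for (v in names(contvars)) {
      me <- morans_envelope(contvars[[v]], W, n_sim = config$n_sim_joins,
                            seed = derive_seed(config$seed, paste("moran", g, v)))
      mi <- mi + 1L
      mor[[mi]] <- cbind(grid = g, variable = v, me)
    }
  }
  corr <- do.call(rbind, corr)
  mor <- do.call(rbind, mor)

  res <- list(inputs = inputs, tree_distances = tree_dist, dtt_weights = dttw,
              pca = model, scores = scores_u, weighted_scores = scores_w,
              usage = usage, day_dependence = day_dep,
              deviance = devtab, season_independence = indep,
              segregation = seg, selection_tests = sel,
              correlograms = corr, moran = mor, config = config)
  if (!is.null(config$outdir)) write_outputs(res, config$outdir)
  res
}

write_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  wr(res$inputs$devices, "devices.csv")
  wr(res$inputs$trees, "trees.csv")
  wr(res$inputs$covers, "covers.csv")
  wr(res$inputs$removal, "removal.csv")
  wr(res$tree_distances, "tree_distances.csv")
  ld <- as.data.frame(res$pca$loadings)
  ld <- cbind(variable = rownames(res$pca$loadings), ld)
  wr(ld, "pca_loadings.csv")
  wr(res$scores, "scores.csv")
  wr(res$segregation, "segregation.csv")
  wr(res$selection_tests, "selection_tests.csv")
  wr(res$correlograms, "correlograms.csv")
  wr(res$moran, "moran_correlograms.csv")
  wr(res$deviance$table, "deviance_table.csv")
  indep <- do.call(rbind, lapply(names(res$season_independence), function(g) {
    r <- res$season_independence[[g]]
    data.frame(grid = g, chisq = r$chisq, df = r$df, P = r$P,
               df_est = r$df_est, P_est = r$P_est)
  }))
  wr(indep, "independence_tests.csv")
  manifest <- list(
    package = "seedsel",
    version = as.character(utils::packageVersion("seedsel")),
    r_version = as.character(getRversion()),
    seed = res$config$seed,
    sim_seed = if (!is.null(res$config$sim)) res$config$sim$seed else NULL,
    model = if (!is.null(res$config$sim)) res$config$sim$model else "data",
    n_devices = nrow(res$inputs$devices),
    n_sim = list(mean = res$config$n_sim_mean, variance = res$config$n_sim_var,
                 joins = res$config$n_sim_joins),
    retention = res$config$retention,
    outputs = list.files(outdir, pattern = "\\.csv$"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
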