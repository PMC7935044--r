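#' Read a multivariate time series with spatial coordinates
#'
#' Two input forms are supported: a 4D NIfTI volume plus a binary mask
#' (voxels inside the mask become channels, with mm coordinates from the
#' affine), or a delimited T x N matrix with a JSON sidecar of N spatial
#' coordinates. A `TR` given in `config` overrides the file header (the
#' override is recorded in the returned object).
#'
#' @param path path to a `.nii`/`.nii.gz` 4D volume or a delimited matrix
#'   (TSV/CSV, no header).
#' @param mask_path binary mask NIfTI (required for NIfTI input); for
#'   delimited input, the coordinate sidecar path (default
#'   `<path>.geometry.json`).
#' @param TR optional repetition time override (s).
#' @return List with `series` (a `timeseries_matrix`) and `geometry` (a
#'   [grid_geometry()]).
#' @export
read_timeseries <- function(path, mask_path = NULL, TR = NULL) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI requires the RNifti package")
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 4) stop(sprintf("%s is not a 4D volume", path))
    if (is.null(mask_path)) stop("a mask NIfTI is required for 4D input")
    msk <- RNifti::readNifti(mask_path)
    if (!identical(dim(msk), dim(img)[1:3]))
      stop(sprintf("mask %s does not match the volume grid", mask_path))
    keep <- which(msk != 0)
    if (!length(keep)) stop("mask selects no voxels")
    nt <- dim(img)[4]
    mat <- matrix(img, ncol = nt)[keep, , drop = FALSE]
    aff <- RNifti::xform(img)
    ijk <- arrayInd(keep, dim(msk)) - 1
    pos <- t(aff %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
    vv <- abs(det(aff[1:3, 1:3]))
    tr <- TR %||% RNifti::pixdim(img)[4]
    series <- structure(list(values = t(mat), sampling_interval = tr,
                             channel_ids = paste0("v", keep)),
                        class = "timeseries_matrix")
    list(series = series,
         geometry = grid_geometry(pos, voxel_volume = vv))
  } else {
    vals <- as.matrix(utils::read.table(path, header = FALSE))
    sidecar <- mask_path %||% paste0(path, ".geometry.json")
    if (!file.exists(sidecar))
      stop(sprintf("coordinate sidecar not found: %s", sidecar))
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pos <- matrix(unlist(side$positions), ncol = 3, byrow = FALSE)
    if (nrow(pos) != ncol(vals))
      stop(sprintf("%s: %d coordinates for %d channels", sidecar,
                   nrow(pos), ncol(vals)))
    tr <- TR %||% side$TR %||% 1
    series <- structure(list(values = vals, sampling_interval = tr,
                             channel_ids = paste0("s", seq_len(ncol(vals)))),
                        class = "timeseries_matrix")
    list(series = series,
         geometry = grid_geometry(pos,
                                  voxel_volume = side$voxel_volume %||% 1,
                                  hemisphere_axis = side$hemisphere_axis %||% 1))
  }
}

#' Write a time series as a delimited matrix with a JSON geometry sidecar
#'
#' @param series a `timeseries_matrix`.
#' @param geometry a [grid_geometry()].
#' @param path output path for the T x N matrix (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, geometry, path) {
  utils::write.table(series$values, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(positions = geometry$positions,
         voxel_volume = geometry$voxel_volume,
         hemisphere_axis = geometry$hemisphere_axis,
         TR = series$sampling_interval),
    paste0(path, ".geometry.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a partition to JSON
#'
#' One object per particle with sorted `internal`, `sensory`, `active`
#' index arrays (1-based); the edge convention (`A[i,j] = 1` means state j
#' influences state i) is recorded in the header.
#'
#' @param partition a `partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_json <- function(partition, path) {
  jsonlite::write_json(
    list(convention = "A[i,j]=1 iff state j influences state i (J[i,j] != 0)",
         n_states = partition$n_states,
         particles = lapply(partition$particles, function(p)
           list(internal = p$internal, sensory = p$sensory,
                active = p$active))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the posterior coupling estimates as an edge list
#'
#' Tab-separated table: source, target, coupling (Hz), posterior sd,
#' retained flag.
#'
#' @param posterior a `jacobian_posterior`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(posterior, path) {
  n <- nrow(posterior$mean)
  sdm <- coupling_sd(posterior)
  idx <- which(row(posterior$mean) != col(posterior$mean), arr.ind = TRUE)
  df <- data.frame(source = idx[, 2], target = idx[, 1],
                   coupling_hz = posterior$mean[idx],
                   posterior_sd = sdm[idx],
                   retained = posterior$support[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Human-readable analysis report
#'
#' Emits per-scale tables (particle counts, characteristic constants), the
#' evidence-versus-radius profile, the scaling fit, and a table of
#' extrapolated spatiotemporal scales, as both plain text and JSON with
#' identical numbers.
#'
#' @param model a `multiscale_model` (or `NULL`).
#' @param fit a `scaling_fit` (or `NULL`).
#' @param distance_search result of [distance_model_search()] (or `NULL`).
#' @param path output path without extension (writes `.txt` and `.json`).
#' @param extrapolate_to scale indices for the extrapolation table.
#' @return The report list, invisibly.
#' @export
write_report <- function(model = NULL, fit = NULL, distance_search = NULL,
                         path, extrapolate_to = seq(-8, 16, by = 4)) {
  rep <- list()
  if (!is.null(model) && length(model$scales)) {
    s <- summary(model)
    ss <- tryCatch(scale_summaries(model), error = function(e) NULL)
    if (!is.null(ss)) s <- merge(as.data.frame(s), ss[, c("scale", "sigma_tau",
                                                          "sigma_len")],
                                 by = "scale")
    rep$scales <- s
  } else rep$notice <- "no scales"
  if (!is.null(distance_search))
    rep$distance_evidence <- data.frame(radius_mm = distance_search$radii,
                                        evidence_nats = distance_search$profile)
  if (!is.null(fit)) {
    rep$scaling <- list(alpha = fit$alpha, gamma = fit$gamma,
                        f_tau = unname(fit$factors["f_tau"]),
                        f_len = unname(fit$factors["f_len"]))
    rep$extrapolation <- extrapolate_scales(fit, extrapolate_to)
  }
  jsonlite::write_json(rep, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  con <- file(paste0(path, ".txt"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Multiscale dynamics report")
  w("==========================")
  if (!is.null(rep$notice)) w("NOTICE: %s", rep$notice)
  if (!is.null(rep$scales)) {
    w("\nPer-scale summary:")
    utils::capture.output(print(rep$scales, row.names = FALSE)) |>
      writeLines(con = con)
  }
  if (!is.null(rep$distance_evidence)) {
    w("\nEvidence vs coupling radius (nats, relative to worst):")
    utils::capture.output(print(rep$distance_evidence, row.names = FALSE)) |>
      writeLines(con = con)
  }
  if (!is.null(rep$scaling)) {
    w("\nScaling: sigma_tau = %.4g * sigma_len^%.3f (factors: time x%.3g, space x%.3g)",
      rep$scaling$gamma, rep$scaling$alpha, rep$scaling$f_tau, rep$scaling$f_len)
    w("\nExtrapolated scales (anchor = first characterized scale):")
    ex <- rep$extrapolation
    for (r in seq_len(nrow(ex)))
      w("  scale %+3d: sigma_len = %10.4g mm, sigma_tau = %10.4g s",
        ex$scale[r], ex$sigma_len[r], ex$sigma_tau[r])
  }
  invisible(rep)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/read, Jacobian estimation, recursive
#' coarse-graining, dynamical characterization, scaling fit and report,
#' writing plain-text artifacts and a manifest (configuration, seeds,
#' stage completion) to the output directory.
#'
#' @param config list with entries: either `input` (path readable by
#'   [read_timeseries()]) or `simulate` (a list with `n_per_hemisphere`,
#'   `spacing`, `duration`, `dt`, `TR`, ...); `out_dir`; `seed`;
#'   plus optional stage settings `estimate` (config for
#'   [estimate_jacobian()]), `rg` (arguments for [run_rg()]).
#' @param verbose print stage progress.
#' @return List with the main stage outputs (invisibly).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(seed = seed, started = format(Sys.time()), stages = list())

  if (!is.null(config$input)) {
    say("reading %s", config$input)
    inp <- read_timeseries(config$input, config$mask, TR = config$TR)
    series <- inp$series; geometry <- inp$geometry; truth <- NULL
  } else {
    sim <- config$simulate %||% list()
    say("simulating a synthetic system")
    geometry <- make_geometry(sim$n_per_hemisphere %||% 10,
                              sim$spacing %||% 3,
                              sim$layout %||% "grid",
                              seed = child_seed(seed, "geometry"))
    truth <- sample_jacobian(geometry, coupling = sim$coupling %||% list(),
                             seed = child_seed(seed, "jacobian"))
    lat <- simulate_latent(truth, duration = sim$duration %||% 1000,
                           dt = sim$dt %||% 0.1,
                           seed = child_seed(seed, "latent"))
    om <- observation_model(gamma_kernel_basis(sim$dt %||% 0.1),
                            observation_noise = sim$observation_noise %||% 0.1,
                            TR = sim$TR %||% 1)
    series <- observe(lat, om, seed = child_seed(seed, "observe"))
    write_timeseries(series, geometry, file.path(out_dir, "series.tsv"))
  }
  manifest$stages$data <- "ok"
  if (identical(config$stop_after, "data")) {
    if (is.null(config$input))
      write_timeseries(series, geometry, file.path(out_dir, "series.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    return(invisible(list(series = series, geometry = geometry, truth = truth)))
  }

  say("estimating the Jacobian (%d states)", ncol(series$values))
  post <- estimate_jacobian(series, geometry, inputs = config$inputs,
                            config = config$estimate %||% list())
  write_edge_list(post, file.path(out_dir, "edges.tsv"))
  manifest$stages$estimate <- "ok"

  say("renormalizing")
  rg <- config$rg %||% list()
  model <- run_rg(post$mean, geometry = geometry,
                  n_scales = rg$n_scales %||% 3,
                  n_internal = rg$n_internal %||% 1,
                  dissipation_threshold = rg$dissipation_threshold %||% 1,
                  max_modes = rg$max_modes %||% 8)
  if (!is.null(model$scales[[1]]$partition))
    write_partition_json(model$scales[[1]]$partition,
                         file.path(out_dir, "partition_scale1.json"))
  manifest$stages$renormalize <- "ok"

  say("characterizing dynamics")
  lam_top <- model$scales[[length(model$scales)]]$lambda
  hh <- tryCatch(helmholtz(lam_top[Re(lam_top) != 0]), error = function(e) NULL)
  dpl <- tryCatch(distance_power_law(post$mean, mirrored_distances(geometry)),
                  error = function(e) NULL)
  manifest$stages$characterize <- "ok"

  say("fitting scaling")
  fit <- tryCatch(fit_scaling(model), error = function(e) NULL)
  manifest$stages$scaling <- if (is.null(fit)) "skipped (<2 scales)" else "ok"

  write_report(model, fit, path = file.path(out_dir, "report"))
  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  say("done; artifacts in %s", out_dir)
  invisible(list(series = series, geometry = geometry, truth = truth,
                 posterior = post, model = model, helmholtz = hh,
                 distance_law = dpl, scaling = fit))
}
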