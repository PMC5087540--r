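#' Configure an end-to-end segmentation run
#'
#' Bundles every stage of the pipeline — phantom generation, optional noise
#' corruption, edge-map computation, force-field solution, snake evolution
#' and evaluation — into one reproducible configuration.
#'
#' @param phantom A [phantom_spec()].
#' @param noise A [noise_spec()] or `NULL` for a clean image.
#' @param edge List of [edge_map()] options: `sigma`, `squared`.
#' @param field A [field_config()].
#' @param snake A [snake_config()].
#' @param init A single initial-contour spec (list with `shape`, `center`,
#'   `size`, `n_points`) or a list of several; each produces one
#'   segmentation.
#' @param normalize_field Unit-normalize the force field before snake
#'   evolution (default `TRUE`).
#' @param seed Global seed; it drives the noise module (all other stages
#'   are deterministic).
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec("disk"),
                       noise = NULL,
                       edge = list(sigma = 0, squared = FALSE),
                       field = field_config("proposed", K = 0.1, tau = 1,
                                            n_iter = 400L),
                       snake = snake_config(n_iter = 200L),
                       init = list(shape = "ellipse",
                                   center = NULL, size = NULL,
                                   n_points = 100L),
                       normalize_field = TRUE, seed = 1L) {
  if (is.list(phantom) && !inherits(phantom, "phantom_spec"))
    phantom <- do.call(phantom_spec, phantom)
  if (!is.null(noise) && !inherits(noise, "noise_spec"))
    noise <- do.call(noise_spec, noise)
  if (is.list(field) && !inherits(field, "field_config"))
    field <- do.call(field_config, field)
  if (is.list(snake) && !inherits(snake, "snake_config"))
    snake <- do.call(snake_config, snake)
  if (!is.null(init$shape)) init <- list(init)  # single spec -> list of one
  edge <- utils::modifyList(list(sigma = 0, squared = FALSE), edge)
  assert_scalar(seed, "seed")
  structure(list(phantom = phantom, noise = noise, edge = edge,
                 field = field, snake = snake, init = init,
                 normalize_field = isTRUE(normalize_field),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @noRd
default_init <- function(init, spec) {
  if (is.null(init$center)) init$center <- spec$center
  if (is.null(init$size)) {
    extent <- if (spec$kind == "disk") 2 * spec$radius else spec$side
    s <- min(extent + 16, spec$width - 2, spec$height - 2)
    init$size <- c(s, s)
  }
  if (is.null(init$n_points)) init$n_points <- 100L
  if (is.null(init$shape)) init$shape <- "ellipse"
  init
}

#' Run the full segmentation pipeline
#'
#' Executes phantom generation, noise corruption, edge-map computation,
#' force-field solution, snake evolution and evaluation in order. Each
#' stage failure is re-signalled with the stage name. With `out_dir` set,
#' writes the final contour(s) as CSV, mask(s) as PNG, a metrics CSV, the
#' resolved configuration as YAML and a short log.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory, or `NULL` (default) to skip writing.
#' @return An object of class `pipeline_result`: list with `metrics`
#'   (tibble, one row per initial contour), `fits`, `masks`, `field`,
#'   `edge_map`, `image`, `truth` and the resolved `config`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(field = field_config("gvf", n_iter = 150)))
#' res$metrics
#' }
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  ph <- stage("phantom", make_phantom(cfg$phantom))
  img <- ph$image
  if (!is.null(cfg$noise)) {
    ns <- cfg$noise
    ns$seed <- cfg$seed  # the global seed drives the noise module
    img <- stage("noise", add_noise(img, ns))
  }
  f <- stage("edgemap", edge_map(img, sigma = cfg$edge$sigma,
                                 squared = isTRUE(cfg$edge$squared)))
  V <- stage("forcefield", solve_field(f, cfg$field))
  domain <- c(cfg$phantom$width, cfg$phantom$height)
  fits <- list(); masks <- list(); rows <- list()
  for (i in seq_along(cfg$init)) {
    init <- default_init(cfg$init[[i]], cfg$phantom)
    contour0 <- stage("init_contour", make_initial_contour(
      init$shape, center = init$center, size = init$size,
      n_points = init$n_points, domain = domain))
    fit <- stage("snake", evolve_snake(contour0, V, cfg$snake,
                                       normalize = cfg$normalize_field))
    mask <- stage("rasterize", contour_to_mask(fit$contour,
                                               dim(ph$mask)))
    rep_i <- stage("evaluate", evaluate_mask(mask, ph$mask))
    fits[[i]] <- fit; masks[[i]] <- mask
    rows[[i]] <- tibble::tibble(init = i, rep_i)
  }
  metrics <- dplyr::bind_rows(rows)
  res <- structure(list(metrics = metrics, fits = fits, masks = masks,
                        field = V, edge_map = f, image = img,
                        truth = ph$mask, config = cfg),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @noRd
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(res$fits)) {
    utils::write.csv(res$fits[[i]]$contour,
                     file.path(out_dir, sprintf("contour_%d.csv", i)),
                     row.names = FALSE)
    write_gray_png(res$masks[[i]],
                   file.path(out_dir, sprintf("mask_%d.png", i)))
  }
  utils::write.csv(res$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  write_run_config(res$config, file.path(out_dir, "config.yaml"))
  writeLines(c(
    sprintf("gvfsnakes %s", as.character(utils::packageVersion("gvfsnakes"))),
    sprintf("seed: %d", res$config$seed),
    sprintf("method: %s", res$config$field$method),
    sprintf("field residual (final): %.6g",
            utils::tail(res$field$residuals, 1)),
    sprintf("mean F1: %.4f", mean(res$metrics$f1))),
    file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Sweep the edge-intensity threshold tau
#'
#' Re-runs the pipeline across a grid of `tau` values at fixed `K` and
#' reports the mean F1 per value (averaged over the configured initial
#' contours). Used to map the method's insensitivity plateau.
#'
#' @param cfg A [run_config()] with `field$method = "proposed"`.
#' @param tau_values Numeric vector of thresholds in (0, 1\].
#' @return A tibble with columns `tau`, `mean_f1`, in the input order.
#' @export
sweep_tau <- function(cfg, tau_values) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$field$method != "proposed")
    stop("`sweep_tau` applies to the convex-coefficient ('proposed') field",
         call. = FALSE)
  rows <- purrr::map(tau_values, function(tv) {
    cfg$field$tau <- tv
    res <- run_pipeline(cfg)
    tibble::tibble(tau = tv, mean_f1 = mean(res$metrics$f1))
  })
  dplyr::bind_rows(rows)
}

#' Write a run configuration as YAML
#'
#' @param cfg A [run_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  plain <- rapply(unclass(cfg), unclass, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path A YAML file written by [write_run_config()] (or hand-written
#'   with the same keys).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$phantom$center <- unlist(raw$phantom$center)
  if (is.na(raw$phantom$indent_depth %||% NA)) raw$phantom$indent_depth <- NULL
  if (!is.null(raw$init))
    raw$init <- lapply(raw$init, function(i) {
      i$center <- unlist(i$center); i$size <- unlist(i$size); i
    })
  run_config(phantom = raw$phantom, noise = raw$noise,
             edge = raw$edge %||% list(),
             field = raw$field, snake = raw$snake, init = raw$init,
             normalize_field = raw$normalize_field %||% TRUE,
             seed = raw$seed %||% 1L)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s phantom, %s field; %d run(s)\n",
              x$config$phantom$kind, x$config$field$method,
              nrow(x$metrics)))
  print(x$metrics)
  invisible(x)
}
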