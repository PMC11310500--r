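#' Serialize per-organ baselines to a JSON model file
#'
#' Writes one top-level object per organ with the grid parameters, pointwise
#' mean and SD densities, reference count and bandwidth rule, plus a
#' schema_version and creation timestamp. Density values are stored as
#' 17-significant-digit decimal strings so the round trip reproduces the
#' doubles bit for bit (plain JSON numbers lose the last two digits).
#'
#' @param baselines named list of [BaselineKDE] objects.
#' @param path destination JSON path.
#' @return the path, invisibly.
#' @export
writeBaselines <- function(baselines, path) {
  obj <- list(schema_version = 1L,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              organs = lapply(baselines, function(b) {
                g <- b@grid
                list(organ = b@organ,
                     grid = list(min = sprintf("%.17g", g@points[1]),
                                 step = sprintf("%.17g", g@step),
                                 n_points = length(g@points)),
                     mean_density = sprintf("%.17g", b@meanDensity),
                     sd_density = sprintf("%.17g", b@sdDensity),
                     n_reference = b@nReference,
                     bandwidth_rule = b@bandwidthRule)
              }))
  names(obj$organs) <- vapply(baselines, function(b) b@organ, character(1))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBaselines
#' @return \code{readBaselines}: named list of [BaselineKDE] objects.
#' @export
readBaselines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop("unsupported baseline schema version", call. = FALSE)
  out <- lapply(obj$organs, function(b) {
    n <- as.integer(b$grid$n_points)
    gmin <- as.numeric(b$grid$min)
    gstep <- as.numeric(b$grid$step)
    pts <- gmin + (seq_len(n) - 1) * gstep
    grid <- new("KDEGrid", points = pts, step = gstep)
    mu <- as.numeric(b$mean_density)
    sdv <- as.numeric(b$sd_density)
    new("BaselineKDE", organ = b$organ, grid = grid, meanDensity = mu,
        sdDensity = sdv, lower = pmax(mu - 2 * sdv, 0),
        upper = mu + 2 * sdv, nReference = as.integer(b$n_reference),
        bandwidthRule = b$bandwidth_rule)
  })
  names(out) <- names(obj$organs)
  out
}
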