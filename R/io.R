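# Dataset container and checkpoint I/O.
#
# Numeric payloads are serialized as "%.17g" text, which round-trips IEEE
# doubles bit-exactly; metadata travels as a JSON header line.  One file per
# dataset / model, self-describing.

fmt_num <- function(x) sprintf("%.17g", x)

write_payload_line <- function(con, name, v) {
  writeLines(paste(name, paste(fmt_num(v), collapse = " ")), con)
}

#' Save / load a labeled dataset as a single text archive
#'
#' The archive holds the stacked value arrays, the shared mask, the 0-based
#' integer labels, ids, class names, and (if present) the generation config.
#' `load_dataset(save_dataset(ds, f))` reproduces values bit-exactly.
#'
#' @param ds A [labeled_dataset].
#' @param path File path (conventional extension `.cagd`).
#' @return `save_dataset` returns `path` invisibly; `load_dataset` returns
#'   the [labeled_dataset].
#' @export
save_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "labeled_dataset"))
  n <- length(ds$maps)
  d <- if (n) dim(ds$maps[[1]]$values) else c(0L, 0L)
  meta <- list(format = "cagd", version = 1L, H = d[1], W = d[2], n = n,
               class_names = ds$class_names,
               labels = if (n) ds_labels(ds) else integer(0),
               ids = if (n) vapply(ds$maps, function(m) m$id, character(1))
                     else character(0),
               config = if (!is.null(ds$config)) unclass(ds$config) else NULL)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null", digits = NA), con)
  if (n) write_payload_line(con, "mask", as.numeric(ds$maps[[1]]$mask))
  for (i in seq_len(n)) write_payload_line(con, "map", as.numeric(ds$maps[[i]]$values))
  invisible(path)
}

parse_payload_line <- function(line, expect) {
  sp <- regexpr(" ", line)
  nm <- substr(line, 1L, sp - 1L)
  if (!identical(nm, expect)) stop("corrupt dataset file: expected '", expect, "' record")
  as.numeric(strsplit(substr(line, sp + 1L, nchar(line)), " ", fixed = TRUE)[[1]])
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(lines[1])
  if (!identical(meta$format, "cagd")) stop("not a cagd dataset file: ", path)
  n <- meta$n
  cfg <- if (!is.null(meta$config)) structure(meta$config, class = "synth_config")
  if (n == 0) return(labeled_dataset(list(), meta$class_names, cfg))
  if (length(lines) != 2L + n) stop("corrupt dataset file: record count mismatch")
  H <- meta$H; W <- meta$W
  mask <- matrix(parse_payload_line(lines[2], "mask") > 0, H, W)
  maps <- vector("list", n)
  for (i in seq_len(n)) {
    v <- parse_payload_line(lines[2L + i], "map")
    if (length(v) != H * W) stop("corrupt dataset file: map size mismatch")
    maps[[i]] <- activation_map(matrix(v, H, W), mask,
                                label = meta$labels[i], id = meta$ids[i])
  }
  labeled_dataset(maps, meta$class_names, cfg)
}

#' Export an activation map as an 8-bit grayscale PNG
#'
#' Values (expected in \[0, 1\]) are quantized as `round(value * 255)` into
#' 8-bit gray levels.
#'
#' @param map An [activation_map].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
export_png <- function(map, path) {
  stopifnot(inherits(map, "activation_map"))
  v <- pmin(pmax(map$values, 0), 1)
  png::writePNG(round(v * 255) / 255, target = path)
  invisible(path)
}

#' Export a signed map (e.g. a counterfactual explanation) as a diverging PNG
#'
#' Symmetric red/blue diverging scale around 0: positive values fade to red,
#' negative to blue, with the color range set by `max(abs(x))`.
#'
#' @param values Numeric matrix (may be negative).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
export_png_diverging <- function(values, path) {
  a <- max(abs(values), 1e-12)
  x <- values / a
  r <- ifelse(x > 0, 1, 1 + x)
  b <- ifelse(x < 0, 1, 1 - x)
  g <- 1 - abs(x)
  img <- array(c(r, g, b), c(nrow(values), ncol(values), 3))
  png::writePNG(round(img * 255) / 255, target = path)
  invisible(path)
}

# --- generic parameter-list checkpoints ------------------------------------

save_params_file <- function(meta, par, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta$param_names <- names(par)
  meta$param_dims <- lapply(par, function(p) if (is.null(dim(p))) length(p) else dim(p))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null", digits = NA), con)
  for (nm in names(par)) write_payload_line(con, nm, as.numeric(par[[nm]]))
  invisible(path)
}

load_params_file <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(lines[1])
  par <- list()
  for (i in seq_along(meta$param_names)) {
    nm <- meta$param_names[i]
    v <- parse_payload_line(lines[1L + i], nm)
    d <- meta$param_dims[[i]]
    if (length(d) > 1) dim(v) <- d
    par[[nm]] <- v
  }
  list(meta = meta, par = par)
}
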