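# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize a RNG state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_param <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param("parameter error: `", name, "` must be a finite number")
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    stop_param("parameter error: `", name, "` out of range")
  }
  invisible(x)
}

#' Read a flat key/value configuration file
#'
#' Parses a plain-text configuration in `key: value` form (one pair per line;
#' `#` starts a comment). Values that parse as numbers become numeric;
#' comma-separated values become vectors; `name=value` pairs inside a
#' comma-separated list become named vectors.
#'
#' @param path Path to the configuration file.
#' @return A named list of scalars and vectors.
#' @export
#' @examples
#' p <- tempfile(fileext = ".cfg")
#' writeLines(c("mode: additive", "L0: 100", "probs: 0.46, 0.42, 0.12"), p)
#' read_config(p)
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regexpr(":", ln, fixed = TRUE)
    if (m < 0) stop_param("config parse error: missing ':' in line '", ln, "'")
    key <- trimws(substr(ln, 1L, m - 1L))
    val <- trimws(substr(ln, m + 1L, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    nm <- rep(NA_character_, length(parts))
    has_eq <- grepl("=", parts, fixed = TRUE)
    if (any(has_eq)) {
      kv <- strsplit(parts, "=", fixed = TRUE)
      nm <- vapply(kv, function(z) trimws(z[[1L]]), "")
      parts <- vapply(kv, function(z) trimws(z[[2L]]), "")
    }
    num <- suppressWarnings(as.numeric(parts))
    parsed <- if (!anyNA(num)) num else parts
    if (any(has_eq)) names(parsed) <- nm
    out[[key]] <- parsed
  }
  out
}

#' Write a flat key/value configuration file
#'
#' Inverse of [read_config()]: scalars and vectors are written one key per
#' line; named vectors are written as `name=value` lists.
#'
#' @param config Named list of scalars/vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  fmt1 <- function(v) {
    s <- if (is.numeric(v)) format(v, digits = 15, trim = TRUE) else as.character(v)
    if (!is.null(names(v)) && any(nzchar(names(v)))) {
      s <- paste0(names(v), "=", s)
    }
    paste(s, collapse = ", ")
  }
  lines <- vapply(names(config), function(k) {
    paste0(k, ": ", fmt1(config[[k]]))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
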