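# Internal helpers shared across modules.

# Canonical unordered gene-pair key. Gene symbols never contain "\r".
pair_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

edge_key <- function(experiment, a, b) {
  paste(experiment, pair_key(a, b), sep = "\r\r")
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so package internals never perturb user simulations.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 closed_min = TRUE, closed_max = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  lo_ok <- if (closed_min) x >= min else x > min
  hi_ok <- if (closed_max) x <= max else x < max
  if (!lo_ok || !hi_ok)
    stopf("'%s' = %s is outside the allowed range %s%s, %s%s", name,
          format(x), if (closed_min) "[" else "(", format(min),
          format(max), if (closed_max) "]" else ")")
  invisible(x)
}

assert_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stopf("'%s' must be a single non-empty string", name)
  invisible(x)
}

# Serialise an open property set as "key=value;key=value" for flat TSV
# persistence. Values must not contain "=", ";" or tab characters.
format_properties <- function(props) {
  if (is.null(props) || length(props) == 0L) return("")
  vals <- vapply(props, function(v) {
    if (is.numeric(v)) format(v, digits = 15L, scientific = FALSE)
    else as.character(v)
  }, character(1L))
  if (any(grepl("[=;\t]", vals)) || any(grepl("[=;\t]", names(props))))
    stopf("property names/values must not contain '=', ';' or tabs")
  paste(names(props), vals, sep = "=", collapse = ";")
}

parse_properties <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- lapply(kv, function(p) {
    num <- suppressWarnings(as.numeric(p[[2L]]))
    if (!is.na(num)) num else p[[2L]]
  })
  names(out) <- vapply(kv, `[[`, character(1L), 1L)
  out
}
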