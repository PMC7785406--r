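## Internal helpers: seed streams, input checks, hashing.

# Derive `n` reproducible sub-seeds from a root seed without disturbing the
# caller's RNG state. Used to give every resampling iteration its own
# substream so results do not depend on execution order.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

# Uniform draw of one element; avoids sample()'s scalar-expansion surprise.
draw_one <- function(x) {
  if (length(x) == 1L) x else x[sample.int(length(x), 1L)]
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# MD5 of an object's canonical JSON form; used for provenance stamping.
config_hash <- function(x) {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  writeLines(
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                     force = TRUE),
    path
  )
  unname(tools::md5sum(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
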