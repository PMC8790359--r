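`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without clobbering the caller's
# random stream: .Random.seed is restored on exit.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != floor(x) || x < min) {
    stop("`", name, "` must be a single integer >= ", min, call. = FALSE)
  }
  as.integer(x)
}

check_positive_real <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a single positive number", call. = FALSE)
  }
  as.numeric(x)
}

check_unit_interval <- function(x, name, open_left = FALSE, open_right = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < 0 || x > 1 || (open_left && x == 0) || (open_right && x == 1)) {
    stop("`", name, "` must lie in ", if (open_left) "(" else "[", "0, 1",
         if (open_right) ")" else "]", call. = FALSE)
  }
  as.numeric(x)
}

# Coerce a table / named numeric to a named integer count vector.
as_named_counts <- function(x, name = "counts") {
  if (inherits(x, "table")) {
    out <- as.integer(x)
    names(out) <- names(x)
  } else if (is.numeric(x) && !is.null(names(x))) {
    out <- x
  } else {
    stop("`", name, "` must be a named numeric vector or table of counts",
         call. = FALSE)
  }
  if (anyNA(out) || any(out < 0)) {
    stop("`", name, "` must contain non-negative counts", call. = FALSE)
  }
  if (anyDuplicated(names(out))) {
    stop("`", name, "` has duplicated condition names", call. = FALSE)
  }
  out
}
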