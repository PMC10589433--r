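# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# `seed = NULL` leaves the global RNG untouched (draws still consume it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("cvrsvd_invalid_argument", "error")))
}

assert_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    stop_invalid("`", name, "` must be a single ",
                 if (strict) "positive" else "non-negative", " number")
  }
  invisible(x)
}

as_binary_array <- function(mask, name = "mask") {
  if (is.logical(mask)) {
    m <- mask
  } else if (is.numeric(mask)) {
    v <- as.vector(mask)
    if (!all(v %in% c(0, 1) | is.na(v))) {
      stop_invalid("`", name, "` must be binary (0/1 or logical)")
    }
    m <- array(mask > 0.5, dim = dim(mask))
  } else {
    stop_invalid("`", name, "` must be a logical or 0/1 numeric array")
  }
  if (is.null(dim(m)) || length(dim(m)) != 3L) {
    stop_invalid("`", name, "` must be a 3D array")
  }
  if (anyNA(m)) stop_invalid("`", name, "` contains missing values")
  m
}
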