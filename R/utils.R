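# internal helpers

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

# run code under a seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# index of the half-open bracket [lo, hi) containing each age; NA if outside
assign_bracket <- function(age, lo, hi) {
  idx <- findInterval(age, lo)
  idx[idx == 0L] <- NA_integer_
  out_of_range <- !is.na(idx) & !is.na(age) & age >= hi[pmax(idx, 1L)]
  idx[out_of_range] <- NA_integer_
  idx
}

stopifnot_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", what))
  }
}

md5_of <- function(x) {
  path <- tempfile()
  on.exit(unlink(path))
  writeLines(x, path)
  unname(tools::md5sum(path))
}
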