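# Internal helpers.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never disturbs user-level randomness.
withSeed <- function(seed, expr) {
  if (is.null(seed))
    return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had)
      assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic text rendering of one table cell: 6 significant digits for
# doubles, exact rendering for integers/logicals/strings, "NA" for missing.
formatCell <- function(x) {
  if (is.double(x))
    out <- ifelse(is.na(x), "NA", formatC(x, digits = 6L, format = "g"))
  else if (is.logical(x))
    out <- ifelse(is.na(x), "NA", as.character(as.integer(x)))
  else
    out <- ifelse(is.na(x), "NA", as.character(x))
  as.character(out)
}

asGeneIds <- function(x, what = "gene identifiers") {
  x <- as.character(x)
  if (any(is.na(x)) || any(!nzchar(x)) || any(grepl("[[:space:]]", x)))
    stop(what, " must be non-empty tokens without whitespace")
  x
}
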