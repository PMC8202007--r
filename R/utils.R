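## small internal helpers

## set the RNG seed, returning the previous state so callers can restore
## it; keeps seeded operations from perturbing the caller's RNG stream
.pushSeed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

.popSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

## percent to one decimal, the reporting convention of the localization
## tables
.pct1 <- function(num, den) round(100 * num / den, 1)

## stop unless all named columns are present
.needCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}
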