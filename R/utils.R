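#' @keywords internal
"_PACKAGE"

## Seed handling: every stochastic operation takes an explicit seed and
## restores the caller's RNG state on exit, so package code never perturbs
## the global random stream.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Deterministic substream seed for a labelled unit of work (e.g. one group
## pair): a small polynomial string hash folded into the master seed, kept
## inside 32-bit integer range. Invariant to the order work is scheduled in.
seed_for_label <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

## Significance stars, figure-caption convention.
p_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p <= 0.001, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", "ns"))))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
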