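# run code with a local RNG state; the caller's stream is untouched
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# fixed-precision float for human-readable report columns (half-even)
.round4 <- function(x) round(x, 4)

# full-precision float rendering for machine-readable files
.fmt_full <- function(x) sprintf("%.17g", x)
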