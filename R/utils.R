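# Internal helpers.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; every seeded operation in the package funnels through this.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}

# Overlap queries between objects seen on different chromosomes are a normal
# situation here (a no-overlap result), not a user error: muffle the seqinfo
# merge warning only.
.quiet_seqlevels <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("no sequence levels in common", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# Derive a child seed from a base seed and a stage tag, kept below 2^31.
# Arithmetic in doubles: integer multiplication would overflow for large
# base seeds.
.child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1009 + h %% 100000) %% 2147483647)
}
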