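# internal helpers shared across modules

# Run code under a temporary RNG state so that seeded package functions do
# not disturb (or depend on) the caller's stream.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation: one user-facing seed fans out into
# independent per-subject / per-stream / per-day seeds. Constants keep every
# intermediate product below 2^53 so the arithmetic is exact in doubles,
# and the result below 2^31 so it is a valid R integer seed.
subSeed <- function(...) {
  parts <- as.numeric(c(...))
  h <- 0
  for (p in parts) h <- (h * 69069 + (abs(p) %% 2147483647) + 1) %% 2147483647
  as.integer(h)
}

# round half up to integer (1.5 -> 2), matching printed table percentages
roundHalfUp <- function(x) floor(x + 0.5)

stopifnot2 <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)

isCount <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x) && x > 0
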