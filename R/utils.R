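#' @keywords internal
"_PACKAGE"

# Labeled error helper: all user-facing errors carry class "phasictune_error"
# plus a specific subclass so tests can assert on the failure mode.
pt_stop <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "phasictune_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

pt_warn <- function(subclass, msg, ...) {
  warning(structure(
    class = c(subclass, "phasictune_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Deterministic seed chaining (Lehmer step modulo the Mersenne prime 2^31-1).
# Keeps every derived seed a valid 32-bit integer and makes each trial's
# random stream a pure function of (base seed, subject, angle index, trial).
mix_seed <- function(seed, key) {
  x <- (as.double(seed) %% 2147483647) * 48271 + as.double(key) * 8191 + 1
  as.integer(x %% 2147483647)
}

# Run code under a local RNG state; restores .Random.seed afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Spearman rank correlation (midranks), used for curve concordance checks.
spearman_rho <- function(x, y) {
  stats::cor(rank(x), rank(y))
}
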