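#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a run-level seed and a stage tag.
# Keeps every stage's RNG stream independent while the whole run is a pure
# function of one integer. Result stays strictly below 2^31 - 1.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(seed) * 69069 + h * 1013 + 1) %% 2147483647)
}

# Evaluate `expr` under a local, seeded RNG without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_msg <- function(...) stop(paste0(...), call. = FALSE)
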