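#' @keywords internal
"_PACKAGE"

# Deterministic derivation of child seeds from a parent seed and an index
# path (iteration, fold, feature, ...). Keeps every random stream
# reproducible from one global seed while remaining below 2^31 - 1.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 69069 + as.double(k) + 12345) %% 2147483647
  }
  as.integer(s)
}

# Run an expression under a locally fixed seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

stopifnot_binary <- function(x, name) {
  if (!all(x %in% c(0, 1))) {
    stop(sprintf("'%s' must be coded 0/1", name), call. = FALSE)
  }
  invisible(TRUE)
}

# Sex x class cell labels used throughout (female = 1, CAD+ = 1).
cell_of <- function(label, sex) {
  factor(
    ifelse(label == 1,
      ifelse(sex == 1, "F+", "M+"),
      ifelse(sex == 1, "F-", "M-")
    ),
    levels = c("F-", "M-", "F+", "M+")
  )
}
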