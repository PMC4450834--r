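# Internal helpers shared across modules.

# C-locale lexicographic sort: vector element order must not depend on the
# session locale, since it defines feature-vector index i.
sort_c <- function(x) sort(x, method = "radix")

abort_ontosim <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("ontosim_error_", class), "ontosim_error"), ...)
}

`%||%` <- rlang::`%||%`

# Normalize an unordered pair table so id_a <= id_b (C locale); keeps joins
# between score tables and label tables order-insensitive.
normalize_pairs <- function(df) {
  a <- pmin(df$id_a, df$id_b)
  b <- pmax(df$id_a, df$id_b)
  df$id_a <- a
  df$id_b <- b
  df
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
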