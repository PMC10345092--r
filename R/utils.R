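#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor median pchisq pnorm pt phyper rnorm rnbinom rlnorm
#'   runif sd setNames
#' @importFrom utils head
NULL

# abort with a sprintf-style message, no call in the condition
ps_stop <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

ps_warn <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

# collapse up to `max` items for an error message
ps_list_some <- function(x, max = 10L) {
  x <- as.character(x)
  if (length(x) > max) {
    paste0(paste(head(x, max), collapse = ", "), ", ... (", length(x), " total)")
  } else {
    paste(x, collapse = ", ")
  }
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ps_stop("'%s' must be a single finite number", name)
  }
  invisible(x)
}

# deterministic substream seed derived from a master seed and a string key.
# Keeps all draws reproducible per component so that, e.g., adding cells to a
# config does not perturb the gene-level draws. Arithmetic stays below 2^53 so
# the double modulus is exact; result lies in [1, 2^31 - 2].
substream_seed <- function(seed, key) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- (as.numeric(seed) %% m) + 1
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 131 + code) %% m
  }
  as.integer((h %% (m - 1)) + 1)
}

# evaluate `expr` under a local RNG seed, restoring the caller's RNG state
with_substream <- function(seed, key, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
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
  set.seed(substream_seed(seed, key))
  expr
}
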