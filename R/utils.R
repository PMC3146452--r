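#' @importFrom stats median quantile rbeta rbinom rnorm runif setNames
#'   aov TukeyHSD p.adjust wilcox.test binom.test cor.test oneway.test plogis
#' @importFrom utils read.delim write.table head
NULL

BASES <- c("A", "C", "G", "T")

# run `expr` under a temporary RNG state seeded with `seed`; NULL leaves the
# global stream untouched so callers can manage reproducibility themselves
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# sample() without the length-1 surprise
sample_int <- function(n, size, replace = FALSE) {
  sample.int(n, size = size, replace = replace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
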