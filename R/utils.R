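#' @keywords internal
"_PACKAGE"

#' @importFrom stats binom.test fisher.test wilcox.test smooth.spline predict
#'   rbinom runif rpois rlnorm rexp rnorm setNames
#' @importFrom utils head read.table write.table packageVersion
NULL

# Progress/audit logging. Every unstated-in-the-method decision the pipeline
# takes at run time (GC-tolerance relaxations, tie-breaks, multi-gene
# resolutions) is reported through here so runs are auditable.
g4_log <- function(fmt, ...) {
  if (isTRUE(getOption("g4screen.verbose", TRUE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}

# Deterministic child seed for stream i of a master seed; keeps results
# independent of the order in which streams are consumed. Stays below 2^31.
child_seed <- function(seed, i) {
  as.integer(((as.double(seed) %% 2147483647) * 69621 + i * 30011) %% 2147483647)
}

with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_g4 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
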