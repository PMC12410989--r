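#' @importFrom stats cor cor.test median rbinom rbeta rnbinom rnorm rlnorm
#'   rmultinom runif binom.test fisher.test p.adjust pt t.test wilcox.test
#'   quantile setNames var sd complete.cases
#' @importFrom utils read.delim write.table head modifyList
#' @importFrom methods as is
NULL

#' Derive a seed substream
#'
#' Hierarchical seed scheme: every stochastic component derives its own seed
#' from (root seed, stream index), so components are reproducible in
#' isolation and independent of evaluation order. Mixing constants come
#' from the MINSTD generator; results stay inside R's signed 32-bit
#' integer range.
#'
#' @param root_seed Root seed (integer-valued).
#' @param index Stream index.
#' @return An integer seed.
#' @export
substream_seed <- function(root_seed, index) {
  root <- as.double(root_seed) %% 2147483647
  idx <- as.double(index) %% 2147483647
  as.integer((root * 48271 + idx * 16807 + 12345) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Multivariate hypergeometric downsampling of a count vector
#'
#' Draws `target` reads without replacement from a vector of per-gene read
#' counts, i.e. a multivariate hypergeometric sample. This is the read-level
#' equivalent of downsampling a sequencing library to a fixed depth.
#'
#' @param x Non-negative integer vector of counts.
#' @param target Total count to retain; must not exceed `sum(x)`.
#' @return Integer vector of the same length as `x` summing to `target`.
#' @examples
#' set.seed(1)
#' downsample_count_vector(c(6L, 4L), 5L)
#' @export
downsample_count_vector <- function(x, target) {
  total <- sum(x)
  target <- as.integer(target)
  if (target > total) {
    stop("downsample target (", target, ") exceeds total counts (", total, ")")
  }
  if (target == total) return(as.integer(x))
  if (target == 0L) return(integer(length(x)))
  # drawing the complement (reads removed) is the same law and cheaper
  # when most reads are kept
  m <- min(target, total - target)
  pos <- sample.int(total, m)
  breaks <- cumsum(as.double(x))
  idx <- findInterval(pos - 1L, breaks) + 1L
  drawn <- tabulate(idx, nbins = length(x))
  if (m == target) drawn else as.integer(x) - drawn
}

cpm <- function(x) {
  tot <- sum(x)
  if (tot == 0) stop("cannot compute CPM of an all-zero profile")
  x * 1e6 / tot
}

# Spearman rho and two-sided P. Without ties, the permutation-complete
# exact distribution (n <= 9) or the AS89 approximation to it is used via
# cor.test; with ties the asymptotic t-approximation.
spearman_test <- function(x, y) {
  use_exact <- !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = use_exact)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(class, ...) {
  stop(structure(
    class = c(class, "celltempo_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
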