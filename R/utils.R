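#' Derive a reproducible child seed from a global seed and a key
#'
#' Computes a deterministic 31-bit seed from a global integer seed and an
#' arbitrary key (e.g. a gene identifier or round index) via a polynomial
#' rolling hash. Using per-unit derived seeds makes results independent of
#' iteration order over units.
#'
#' @param seed Integer global seed.
#' @param key Character or numeric key identifying the unit of work.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.double(abs(as.integer(seed))) %% m
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Canonical string id of a directed regulatory link.
link_id <- function(regulator, target) {
  paste(regulator, target, sep = "\r")
}

# Canonical id of an unordered gene pair (sorted endpoints).
pair_id <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

# log(sum(exp(x))) with max-shift; handles -Inf blocks.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Construct a gene regulatory network edge table
#'
#' Validates and canonicalizes a set of weighted regulatory links. At most
#' one link per (regulator, target) pair is allowed and self-links are
#' rejected; rows are ordered by (regulator, target) so that equal networks
#' have identical representations.
#'
#' @param regulator,target Character vectors of gene identifiers.
#' @param weight Numeric link confidence weights in `[0, 1]`.
#' @return A `data.frame` with columns `regulator`, `target`, `weight`.
#' @export
grn <- function(regulator = character(), target = character(),
                weight = numeric()) {
  regulator <- as.character(regulator)
  target <- as.character(target)
  weight <- as.numeric(weight)
  stopifnot(length(regulator) == length(target),
            length(regulator) == length(weight))
  if (any(regulator == target)) {
    stop("self-links (regulator == target) are not allowed")
  }
  if (length(weight) && (any(weight < 0) || any(weight > 1))) {
    stop("link weights must lie in [0, 1]")
  }
  if (anyDuplicated(link_id(regulator, target))) {
    stop("duplicate (regulator, target) pairs in network")
  }
  out <- data.frame(regulator = regulator, target = target, weight = weight,
                    stringsAsFactors = FALSE)
  out <- out[order(out$regulator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
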