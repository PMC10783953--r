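#' @importFrom stats plogis runif rnorm setNames
#' @importFrom utils head adist read.csv read.delim write.csv
NULL

# The 20 standard amino acids, alphabetical one-letter codes.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Keep probabilities strictly inside (0, 1) so log-loss is finite.
clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

bce_loss <- function(p, y) {
  p <- clamp_prob(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' All randomness in the package is funnelled through one user-supplied seed;
#' independent stages (initialisation, splits, negative sampling, dropout)
#' draw from sub-seeds derived deterministically from that seed plus a stage
#' label, so changing one stage never perturbs another.
#'
#' @param seed integer master seed.
#' @param tag character label of the consumer.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 131 + ch) %% 2147480009
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Evaluate expr under a temporary RNG state, restoring the caller's stream.
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
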