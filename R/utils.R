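#' @useDynLib spheroidquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif rpois hclust cutree dist quantile median pnorm sd
#' @importFrom utils write.csv read.csv packageVersion unzip combn head tail
NULL

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All stochastic steps in the package go through this so a
# run is a pure function of its seeds.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

# stop() with a classed condition so callers/tests can distinguish error kinds
sqStop <- function(class, ...) {
  stop(structure(class = c(class, "spheroidquantError", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

emptyNucleusTable <- function() {
  data.frame(id = integer(0), slice = integer(0), row = numeric(0), col = numeric(0),
             area_um2 = numeric(0), mean_intensity = numeric(0),
             zone = character(0), radial_um = numeric(0), state = character(0),
             stringsAsFactors = FALSE)
}

emptyFragmentTable <- function() {
  data.frame(id = integer(0), slice = integer(0), row = numeric(0), col = numeric(0),
             area_um2 = numeric(0), mean_intensity = numeric(0),
             stringsAsFactors = FALSE)
}

ZONE_LEVELS <- c("core", "rim", "invasion", "unassigned")
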