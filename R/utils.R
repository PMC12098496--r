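# Shared internal helpers: edge vectorization, Fisher z, seed fan-out.

# clip correlations away from +/-1 so atanh stays finite
.CLIP <- 1 - 1e-7

.fisherZ <- function(r) atanh(pmin(pmax(r, -.CLIP), .CLIP))

# Edge order convention: strict upper triangle, row-major, diagonal excluded,
# i.e. (1,2),(1,3),...,(1,P),(2,3),...  For a symmetric matrix this equals
# the column-major lower triangle, which is what R's lower.tri extracts.
.edgePairs <- function(P) {
  i <- rep.int(seq_len(P - 1L), (P - 1L):1L)
  j <- unlist(lapply(seq_len(P - 1L), function(a) (a + 1L):P), use.names = FALSE)
  cbind(i = i, j = j)
}

.edgeNames <- function(regionIDs) {
  pr <- .edgePairs(length(regionIDs))
  paste(regionIDs[pr[, "i"]], regionIDs[pr[, "j"]], sep = "--")
}

# vectorize the strict upper triangle (row-major) of a symmetric matrix
.vecUT <- function(m) m[lower.tri(m, diag = FALSE)]

# rebuild a symmetric P x P matrix (zero diagonal) from an edge vector
.unvecUT <- function(v, P, regionIDs = NULL) {
  m <- matrix(0, P, P)
  m[lower.tri(m, diag = FALSE)] <- v
  m <- m + t(m)
  if (!is.null(regionIDs)) dimnames(m) <- list(regionIDs, regionIDs)
  m
}

# deterministic per-stream seed fan-out from one master seed (keeps values
# well inside 32-bit integer range)
.deriveSeed <- function(master, stream) {
  master <- as.double(master); stream <- as.double(stream)
  as.integer((master * 48271 + stream * 16807) %% 2147483647)
}

# a block of n well-separated seeds: drawn from the master-seeded RNG so
# they carry no arithmetic structure (first draws after set.seed correlate
# across arithmetic seed progressions, which would confound groups)
.seedBlock <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  sample.int(2147483646L, n)
}

# seed the RNG for a simulation stream, discarding the first draws whose
# values are most sensitive to seed structure
.seedStream <- function(seed, burn = 32L) {
  set.seed(seed)
  invisible(stats::runif(burn))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
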