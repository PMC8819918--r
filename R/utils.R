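# internal numeric helpers

# geometric mean computed in log space; mean() accumulates in long double,
# which keeps the sum stable across the ~5 orders of magnitude seen in
# copies/ul data
geomMean <- function(x, na.rm = FALSE) {
  exp(mean(log(x), na.rm = na.rm))
}

# derive a child RNG seed from a root seed; kept below 2^31 - 1
childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 1000003 * stream) %% 2147483647L)
}

# run `expr` under a fixed seed without disturbing the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# breadth-first search connectivity of the taxon co-occurrence graph:
# `subsets` is a list of character vectors (taxa present per sample);
# returns a list of connected components over the union of taxa
taxonComponents <- function(subsets) {
  taxa <- unique(unlist(subsets))
  if (length(taxa) == 0L) return(list())
  comp <- integer(length(taxa))
  names(comp) <- taxa
  k <- 0L
  for (t in taxa) {
    if (comp[[t]] > 0L) next
    k <- k + 1L
    queue <- t
    comp[[t]] <- k
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      for (s in subsets) {
        if (cur %in% s) {
          new <- s[comp[s] == 0L]
          comp[new] <- k
          queue <- c(queue, new)
        }
      }
    }
  }
  split(names(comp), comp)
}
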