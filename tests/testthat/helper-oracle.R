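# Independent iterative-deepening oracle for the minimal-scenario search.
# Written against the same problem definition but with its own mechanics:
# plain recursive depth-first enumeration over all reversal intervals, no
# constructive last step, no canonical ordering tricks. It shares only the
# provable lower bound d >= ceil(b/2) as a prune (each reversal heals at
# most two breakpoints), without which deep searches are intractable.

oracleBreakpoints <- function(s, goal) {
  sm <- s[s != -1L]
  gm <- goal[goal != -1L]
  pos <- match(sm, gm)
  sum(abs(diff(c(0L, pos, length(pos) + 1L))) != 1L)
}

oracleMinScenarios <- function(perm, maxDepth) {
  start <- referenceSeq(perm)
  goal <- observedSeq(perm)
  m <- length(start)
  found <- list()
  dfs <- function(s, remaining, acc) {
    if (remaining == 0L) {
      if (identical(s, goal)) found[[length(found) + 1L]] <<- acc
      return(invisible())
    }
    if ((oracleBreakpoints(s, goal) + 1L) %/% 2L > remaining)
      return(invisible())
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        ns <- s
        ns[i:j] <- s[j:i]
        cls <- if (-1L %in% s[i:j]) "PeI" else "PaI"
        dfs(ns, remaining - 1L,
            rbind(acc, data.frame(start = i - 1L, end = j,
                                  classification = cls,
                                  stringsAsFactors = FALSE)))
      }
    }
  }
  empty <- data.frame(start = integer(), end = integer(),
                      classification = character(),
                      stringsAsFactors = FALSE)
  for (d in 0:maxDepth) {
    found <- list()
    dfs(start, d, empty)
    if (length(found)) return(list(dMin = d, scenarios = found))
  }
  list(dMin = Inf, scenarios = list())
}

scenarioKey <- function(sc) {
  paste(sprintf("%03d,%03d,%s", sc$start, sc$end, sc$classification),
        collapse = ";")
}

scenarioSetKeys <- function(scens) sort(vapply(scens, scenarioKey, ""))
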