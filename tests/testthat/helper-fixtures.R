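# Small in-code fixtures shared across test files.

tinyReference <- function(n = 7L, cen = 3L, group = 7L) {
  ReferenceOrder(group, sprintf("%dH%02d", group, seq_len(n)), cen)
}

tinyManifest <- function(ref) {
  manifestFromReference(stats::setNames(list(ref), as.character(ref@group)))
}

# A chromosome map laying out `probes` in the given order with the
# centromere after `sArm` of them.
mapFromOrder <- function(chromId, probes, sArm, centromere = 0.45,
                         copy = NULL) {
  n <- length(probes)
  pos <- c(if (sArm > 0) centromere * seq_len(sArm) / (sArm + 1L),
           if (n - sArm > 0) centromere + (1 - centromere) *
             seq_len(n - sArm) / (n - sArm + 1L))
  ChromosomeMap(chromId, centromere,
                data.frame(probe = probes, position = pos,
                           copy = if (is.null(copy)) 1L else copy))
}

# Random permutation with the observed centromere at a random rank.
randomPermutation <- function(n) {
  newPermutation(sample(0:(n - 1L)), sample(0:n, 1L),
                 refCentromereSlot = sample(0:n, 1L))
}
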