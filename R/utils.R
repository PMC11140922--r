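`%||%` <- function(a, b) if (is.null(a)) b else a

# minor allele frequency from a dosage vector (non-missing calls)
maf_of <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) return(0)
  p <- sum(g) / (2 * length(g))
  min(p, 1 - p)
}
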