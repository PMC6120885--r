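# Independent oracles used to validate the package's computations, kept
# deliberately naive (enumeration / explicit loops) so they share no code
# with the implementation.

# Upper-tail hypergeometric P(X >= k) by direct enumeration over choose()
enumHyperUpper <- function(k, K, N, n) {
  js <- k:min(n, K)
  js <- js[js >= max(0, n - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Same tail in log space (for corpus-scale populations)
logHyperUpper <- function(k, K, N, n) {
  js <- max(k, max(0, n - (N - K))):min(n, K)
  if (k > min(n, K)) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# Brute-force two-hop signed path enumeration over a Regulome, via explicit
# loops over edge rows
enumTargetSets <- function(reg, receptor, mode = "multiplicative") {
  a <- regulomeEdges(reg, "receptor_tf")
  b <- regulomeEdges(reg, "tf_target")
  acts <- character(); inhs <- character(); unks <- character()
  for (i in seq_len(nrow(a))) {
    if (a$source[i] != receptor) next
    for (j in seq_len(nrow(b))) {
      if (b$source[j] != a$target[i]) next
      s1 <- a$sign[i]; s2 <- b$sign[j]
      s <- if (s1 == "unk" || s2 == "unk") "unk"
      else if (mode == "as_printed" && s1 == "inh" && s2 == "act") "act"
      else if (s1 == s2) "act" else "inh"
      g <- b$target[j]
      if (s == "act") acts <- c(acts, g)
      else if (s == "inh") inhs <- c(inhs, g)
      else unks <- c(unks, g)
    }
  }
  list(activated = sort(unique(acts)), inhibited = sort(unique(inhs)),
       unknown = sort(setdiff(unique(unks), c(acts, inhs))))
}

# Random signed regulome for property tests
randomRegulome <- function(nR = 5, nT = 8, nG = 30, nEdges = 60, seed = 1) {
  set.seed(seed)
  rs <- paste0("R", seq_len(nR)); ts <- paste0("T", seq_len(nT))
  gs <- paste0("G", seq_len(nG))
  a <- unique(data.frame(source = sample(rs, nEdges, TRUE),
                         target = sample(ts, nEdges, TRUE),
                         sign = sample(c("act", "inh", "unk"), nEdges, TRUE),
                         stringsAsFactors = FALSE))
  b <- unique(data.frame(source = sample(ts, nEdges, TRUE),
                         target = sample(gs, nEdges, TRUE),
                         sign = sample(c("act", "inh", "unk"), nEdges, TRUE),
                         stringsAsFactors = FALSE))
  Regulome(a, b)
}

# Small genes-by-samples matrix with named dims
toyMatrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}
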