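# Shared fixture builders.

# marker matrix whose columns have known empirical percentile structure
percentile_matrix <- function(n = 100, markers = c("p53", "NaKATPase_beta1",
                                                   "TGFbR2_cyt"), seed = 1) {
  set.seed(seed)
  m <- sapply(markers, function(x) sample(seq_len(n)))
  rownames(m) <- sprintf("P%03d", seq_len(n))
  m
}

# overwrite row 1 with values at given percentile ranks of each column
place_patient <- function(m, pcts) {
  for (mk in names(pcts)) {
    m[1, mk] <- quantile(m[-1, mk], pcts[[mk]] / 100, names = FALSE)
  }
  m
}
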