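# Independent brute-force oracles used across tests. These deliberately share
# no code with the package implementation: plain loops over positions.

oracle_kmer_freq <- function(residues, k, alphabet = pepstack::AA_ALPHABET) {
  ch <- strsplit(residues, "")[[1]]
  L <- length(ch)
  keys <- alphabet
  if (k > 1) for (j in 2:k) keys <- as.vector(t(outer(keys, alphabet, paste0)))
  counts <- setNames(numeric(length(keys)), keys)
  for (i in seq_len(L - k + 1)) {
    kmer <- paste(ch[i:(i + k - 1)], collapse = "")
    counts[kmer] <- counts[kmer] + 1
  }
  counts / (L - k + 1)
}

oracle_gapped_pair_freq <- function(residues, g, alphabet = pepstack::AA_ALPHABET) {
  ch <- strsplit(residues, "")[[1]]
  L <- length(ch)
  keys <- as.vector(t(outer(alphabet, alphabet, paste0)))
  counts <- setNames(numeric(length(keys)), keys)
  n <- L - g - 1
  for (i in seq_len(n)) {
    counts[paste0(ch[i], ch[i + g + 1])] <- counts[paste0(ch[i], ch[i + g + 1])] + 1
  }
  counts / n
}

oracle_confusion <- function(truth, pred) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1L
    if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1L
    if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1L
    if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1L
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

oracle_auc <- function(truth, scores) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# every sequence of length 1..max_len over a sub-alphabet
all_sequences <- function(alphabet, max_len) {
  out <- character(0)
  cur <- alphabet
  for (len in seq_len(max_len)) {
    out <- c(out, cur)
    if (len < max_len) cur <- as.vector(t(outer(cur, alphabet, paste0)))
  }
  out
}

# small linearly separable feature matrix for learner contracts
separable_matrix <- function(n_per_class = 20, seed = 1) {
  set.seed(seed)
  m <- rbind(matrix(rnorm(n_per_class * 4, mean = 0), ncol = 4),
             matrix(rnorm(n_per_class * 4, mean = 4), ncol = 4))
  colnames(m) <- paste0("f", 1:4)
  rownames(m) <- paste0("r", seq_len(nrow(m)))
  list(m = m, y = rep(c(0L, 1L), each = n_per_class))
}

small_dataset <- function(n_pos = 20, n_neg = 40, delta = 1.5, seed = 7) {
  generate_peptides(synthetic_spec(n_pos = n_pos, n_neg = n_neg,
                                   delta = delta, seed = seed))
}
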