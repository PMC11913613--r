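# Small in-code fixtures shared across tests.

# Tiny two-feature cohort: f1 carries the signal, f2 is noise.
toy_cohort <- function(n = 200, seed = 42) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  data.frame(
    f1 = y * 2 + rnorm(n, sd = 0.5),
    f2 = rnorm(n),
    nodule = y)
}

# Perfectly separable cohort: feature equals the label.
separable_cohort <- function(n = 60) {
  y <- rep(0:1, length.out = n)
  data.frame(copy = y, junk = seq_len(n) %% 7, nodule = y)
}

# Brute-force ROC-AUC: concordant-pair counting with 0.5 tie credit.
pairwise_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Brute-force step-wise PR-AUC: walk thresholds at each unique score.
stepwise_pr_auc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  prev_recall <- 0; area <- 0
  for (th in ths) {
    sel <- scores >= th
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / npos
    area <- area + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  area
}

tiny_control <- function(seed = 1, pop = 8, iters = 5)
  stoa_control(population_size = pop, max_iterations = iters, seed = seed)
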