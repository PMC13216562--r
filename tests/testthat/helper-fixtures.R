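# Small fixtures built in code.

# Item bank with a hand-set presentation order: each veracity x slant cell
# contributes the same number of items to the odd and the even half.
balanced_bank <- function(items_per_cell = 2) {
  stopifnot(items_per_cell %% 2 == 0)
  bank <- generate_item_bank(items_per_cell, seed = 1)
  # give each cell a contiguous block of positions; even block length means
  # every cell lands equally often on odd and even positions
  ord <- order(bank$veracity, bank$slant)
  bank$order_index[ord] <- seq_len(nrow(bank))
  bank
}

# Judgments vector for a deterministic responder: judge each item by rule(item).
rule_judgments <- function(bank, rule) {
  stats::setNames(vapply(seq_len(nrow(bank)), function(i) rule(bank[i, ]),
                         logical(1)), bank$item_id)
}

# long-format judgments for a set of participants from a response matrix
long_judgments <- function(resp_matrix, participant_ids, item_ids) {
  data.frame(
    participant_id = rep(participant_ids, times = length(item_ids)),
    item_id = rep(item_ids, each = length(participant_ids)),
    response = ifelse(as.vector(resp_matrix), "true", "false"),
    stringsAsFactors = FALSE
  )
}

# variance-decomposition oracle for Cronbach's alpha: with C the item
# covariance matrix, var(total) = sum(C) and alpha = k/(k-1)*(1 - tr(C)/sum(C))
alpha_oracle <- function(m) {
  C <- stats::cov(m)
  k <- ncol(m)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}
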