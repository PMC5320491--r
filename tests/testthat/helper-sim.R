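# Shared simulation helpers for the test suite.

# A reduced study design for fast unit tests: same structure as the default
# configuration, fewer subjects and features.
tiny_config <- function(seed = 1, n_features = 60L,
                        classes = c(null = 40L, both_sex = 10L,
                                    female_specific = 10L, male_specific = 0L),
                        ...) {
  cc <- default_cell_counts()
  cc$n <- pmax(4L, cc$n %/% 8L)
  study_config(cell_counts = cc, n_features = n_features, classes = classes,
               seed = seed, ...)
}

# Build a feature_association data.frame directly from a p-value vector.
make_assoc <- function(p, ids = sprintf("f%03d", seq_along(p))) {
  data.frame(feature_id = ids, coef = rep(0, length(p)),
             se = rep(1, length(p)), p_value = p,
             q_bh = stats::p.adjust(p, "BH"),
             p_bonferroni = stats::p.adjust(p, "bonferroni"),
             n = rep(10L, length(p)), stringsAsFactors = FALSE)
}

# Independent brute-force Benjamini-Hochberg step-up adjustment:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j), mapped back to input order.
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, m * p[ord[j]] / j), numeric(1))
    q_sorted[i] <- min(vals)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
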