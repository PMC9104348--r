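# Shared fixture builders; everything is generated in code.

# minimal metadata for a flat two-group design (one sample per "mouse")
flat_records <- function(labels, age = 20, lifespan = 40) {
  n <- length(labels)
  sample_records(data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    mouse_id = sprintf("M%03d", seq_len(n)),
    group = labels,
    age_weeks = ifelse(labels %in% c("TKO", "CTRL"), age, NA),
    lifespan_weeks = ifelse(labels %in% c("TKO", "CTRL"), lifespan, NA),
    injection_order = seq_len(n)
  ))
}

# features x samples table from a matrix, auto-named
named_table <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("F%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%03d", seq_len(ncol(m)))
  feature_table(m)
}

# small cohort config used by fast module tests
small_config <- function(...) {
  sim_config(
    n_tko = 6, n_ctrl = 6,
    n_features_per_class = c(Cer = 5, SM = 5, polar = 5, OHP = 1),
    n_noise_features = 8,
    ...
  )
}

# independent textbook Welch oracle (scalar, straight from the formulas)
welch_oracle <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  tt <- (mean(x) - mean(y)) / sqrt(v1 / n1 + v2 / n2)
  df <- (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

# independent BH step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  pmin(q, 1)
}
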