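# Independent brute-force oracles. These deliberately re-derive every quantity
# from first principles (explicit loops, textbook formulas) and share no code
# with the implementation they check.

# Chord-distance scan: for sorted-decreasing values, distance of each point
# (x_i, y_i) -- both axes rescaled to [0, 1] -- to the line through the first
# and last points, via the |ax + by + c| / sqrt(a^2 + b^2) line form.
oracle_inflection_index <- function(values) {
  s <- sort(values, decreasing = TRUE)
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  # line through (x1, y1) and (xn, yn): a*x + b*y + c = 0
  a <- y[n] - y[1]
  b <- x[1] - x[n]
  cc <- x[n] * y[1] - x[1] * y[n]
  d <- abs(a * x + b * y + cc) / sqrt(a^2 + b^2)
  best <- 1
  for (i in seq_len(n)) if (d[i] > d[best]) best <- i  # first max wins
  list(index = best, threshold = s[best])
}

# Exhaustive co-resistance enumeration over a character call matrix.
oracle_coresistance <- function(calls_m, a, b) {
  ev <- character()
  co <- character()
  for (ln in rownames(calls_m)) {
    ca <- calls_m[ln, a]
    cb <- calls_m[ln, b]
    if (!is.na(ca) && !is.na(cb)) {
      ev <- c(ev, ln)
      if (ca == "resistant" && cb == "resistant") co <- c(co, ln)
    }
  }
  list(count = length(co), evaluable = ev, co_resistant = co)
}

# Min-max scaling by the definition.
oracle_minmax <- function(counts) (counts - min(counts)) / (max(counts) - min(counts))

# Panel ranking by explicit scoring and a hand-rolled sort with the stated
# tie rule (higher score, then higher evaluable count, then drug id).
oracle_rank <- function(calls_m, panel_drug, focal) {
  panel <- rownames(calls_m)[!is.na(calls_m[, panel_drug]) &
                               calls_m[, panel_drug] == "resistant"]
  cand <- setdiff(colnames(calls_m), panel_drug)
  score <- ev <- numeric(0)
  for (d in cand) {
    col <- calls_m[panel, d]
    n_ev <- sum(!is.na(col))
    if (n_ev == 0) next
    score[d] <- sum(!is.na(col) & col == "resistant") / n_ev
    ev[d] <- n_ev
  }
  ids <- names(score)
  ord <- order(-score, -ev, ids)
  list(order = ids[ord], rank = which(ids[ord] == focal),
       scores = score[ids[ord]])
}

# Textbook Pearson r via the raw-sum formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Random call matrix with missingness, for property tests.
random_calls <- function(n_lines, n_drugs, seed, p_missing = 0.15) {
  set.seed(seed)
  states <- sample(c("sensitive", "resistant"), n_lines * n_drugs,
                   replace = TRUE)
  states[runif(n_lines * n_drugs) < p_missing] <- NA
  m <- matrix(states, n_lines, n_drugs,
              dimnames = list(sprintf("L%02d", seq_len(n_lines)),
                              sprintf("d%02d", seq_len(n_drugs))))
  sensitivity_calls(m)
}

# Small call matrix from a compact spec: rows are strings over R/S/. per drug.
toy_calls <- function(rows, drugs) {
  m <- t(vapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    ifelse(ch == ".", NA_character_,
           ifelse(ch == "R", "resistant", "sensitive"))
  }, character(nchar(rows[1]))))
  rownames(m) <- names(rows)
  colnames(m) <- drugs
  sensitivity_calls(m)
}
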