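# Independent oracles, deliberately naive: explicit UPGMA agglomeration for
# the dendrogram FD, normal-equations OLS, and sum-of-squares ANOVA.

# Summed branch length of a UPGMA tree built by direct agglomeration over
# average pairwise leaf distances; lexicographic tie-break on member labels.
upgma_fd_oracle <- function(coords) {
  n <- nrow(coords)
  if (n <= 1) return(0)
  labels <- rownames(coords)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  clusters <- lapply(seq_len(n), function(i) i)   # leaf index sets
  heights <- rep(0, n)                            # current cluster heights
  d <- as.matrix(stats::dist(coords))
  total <- 0
  while (length(clusters) > 1) {
    best <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        dd <- mean(d[clusters[[a]], clusters[[b]]])
        key <- paste(sort(c(min(labels[clusters[[a]]]), min(labels[clusters[[b]]]))),
                     collapse = "|")
        if (is.null(best) || dd < best$d - 1e-12 ||
            (abs(dd - best$d) <= 1e-12 && key < best$key)) {
          best <- list(a = a, b = b, d = dd, key = key)
        }
      }
    }
    total <- total + (best$d - heights[best$a]) + (best$d - heights[best$b])
    merged <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$a]] <- merged
    heights[best$a] <- best$d
    clusters <- clusters[-best$b]
    heights <- heights[-best$b]
  }
  total
}

ols_oracle <- function(X, y) {
  X1 <- cbind(1, X)
  as.numeric(solve(t(X1) %*% X1, t(X1) %*% y))
}

anova_oracle <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  k <- length(unique(groups))
  n <- length(values)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, df = c(k - 1, n - k), p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}
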