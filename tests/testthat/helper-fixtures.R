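# Shared fixtures: tiny frames and point-set constructors used across the
# module tests. All randomized helpers take an explicit seed so every test
# is reproducible in isolation.

unit_frame <- function(w = 100, h = 100, upp = 1) coord_frame(w, h, upp)

pset <- function(x, y, label = NULL, frame = unit_frame(), ...) {
  df <- data.frame(x = x, y = y)
  if (!is.null(label)) df$label <- label
  annotation_set(df, frame, ...)
}

random_set <- function(n, frame = unit_frame(), seed = NULL,
                       p_positive = 0.3, labeled = TRUE, ...) {
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(x = runif(n, 0, frame$width_px),
                   y = runif(n, 0, frame$height_px))
  if (labeled) {
    df$label <- ifelse(runif(n) < p_positive, "positive", "negative")
  }
  annotation_set(df, frame, labeled = labeled, ...)
}

# independent two-way ANOVA mean squares, written from the definitions
# (explicit loops; deliberately not sharing code with the package)
anova_ms_oracle <- function(a, b) {
  y <- unname(cbind(a, b))
  n <- nrow(y); k <- ncol(y)
  g <- mean(y)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(y[i, ]) - g)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(y[, j]) - g)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (y[i, j] - mean(y[i, ]) - mean(y[, j]) + g)^2
  }
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

icc_consistency_oracle <- function(a, b) {
  ms <- anova_ms_oracle(a, b)
  (ms$msr - ms$mse) / (ms$msr + ms$mse)
}
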