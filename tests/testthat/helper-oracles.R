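# Independent oracles and small fixtures used across the test files.

# One-way-per-subject ANOVA oracle for the ISO variance components on
# balanced data: pooled residual mean square for repeatability, mean
# between-operator mean square for the operator component. Deliberately
# implemented through lm()/anova(), independent of rr_components().
anova_rr_oracle <- function(values) {
  v <- values
  v$subject <- as.character(v$subject)
  v$operator <- factor(v$operator)
  ms_within_num <- 0
  ms_within_df <- 0
  ms_between <- c()
  n_rep <- NA
  for (su in unique(v$subject)) {
    d <- v[v$subject == su, ]
    fit <- stats::anova(stats::lm(value ~ operator, data = d))
    ms_within_num <- ms_within_num +
      fit["Residuals", "Sum Sq"]
    ms_within_df <- ms_within_df + fit["Residuals", "Df"]
    ms_between <- c(ms_between, fit["operator", "Mean Sq"])
    n_rep <- nrow(d) / nlevels(droplevels(d$operator))
  }
  s_r2 <- ms_within_num / ms_within_df
  s_L2 <- max(0, (mean(ms_between) - s_r2) / n_rep)
  list(s_r = sqrt(s_r2), s_L = sqrt(s_L2), s_R = sqrt(s_r2 + s_L2))
}

# Balanced random R&R instance.
random_rr_instance <- function(p, q, n, sigma_r = 1, sigma_L = 0.5) {
  d <- expand.grid(session = seq_len(n), operator = seq_len(p),
                   subject = seq_len(q))
  d$value <- rnorm(q, sd = 3)[d$subject] +
    rnorm(p, sd = sigma_L)[d$operator] + rnorm(nrow(d), sd = sigma_r)
  d
}

cross_oracle <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Random rigid motion (rotation matrix + translation).
random_rigid <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  list(R = diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K),
       t = runif(3, -100, 100))
}

apply_rigid <- function(rigid, dataset) {
  obs <- dataset$observations
  P <- cbind(obs$x, obs$y, obs$z) %*% t(rigid$R)
  obs$x <- P[, 1] + rigid$t[1]
  obs$y <- P[, 2] + rigid$t[2]
  obs$z <- P[, 3] + rigid$t[3]
  annotation_dataset(obs, catalog = dataset$catalog)
}

# Tiny hand-built dataset: `reps` sessions x `ops` operators of every
# template landmark, exact template positions (no noise).
exact_dataset <- function(n_subjects = 2, ops = 3, reps = 2) {
  tpl <- default_template()
  rows <- list()
  for (su in sprintf("S%02d", seq_len(n_subjects))) {
    for (op in paste0("O", seq_len(ops))) {
      for (se in paste0("R", seq_len(reps))) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = su, operator_id = op, session_id = se,
          landmark = rownames(tpl), x = tpl[, 1], y = tpl[, 2],
          z = tpl[, 3], stringsAsFactors = FALSE)
      }
    }
  }
  annotation_dataset(do.call(rbind, rows))
}
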