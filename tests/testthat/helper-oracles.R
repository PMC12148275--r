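# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (per-pair loops, two-pass moments) so they
# share no code path with the package implementations they check.

# Naive per-tumor-cell nearest neighbor: vectorized only over CD8 cells,
# direct difference formula, sqrt before min.
brute_force_nnd <- function(tumor_xy, cd8_xy, cap = 1000) {
  n <- nrow(tumor_xy)
  if (n == 0) return(numeric(0))
  if (nrow(cd8_xy) == 0) return(rep(cap, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((tumor_xy[i, 1] - cd8_xy[, 1])^2 +
                (tumor_xy[i, 2] - cd8_xy[, 2])^2)
    out[i] <- min(min(d), cap)
  }
  out
}

# Two-pass mean and sample variance computed with explicit loops.
two_pass_moments <- function(x) {
  n <- length(x)
  s <- 0
  for (v in x) s <- s + v
  m <- s / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  list(mean = m, var = ss / (n - 1))
}

# Random cell table with known classes for classifier tests: intensities
# far from the thresholds so true class is unambiguous.
random_cell_fixture <- function(n, seed = 1) {
  set.seed(seed)
  cls <- sample(c("tumor", "cd8", "treg", "foxp3_only", "unclassified"),
                n, replace = TRUE)
  hi <- function(on) ifelse(on, runif(n, 8, 12), runif(n, 0, 1))
  data.frame(
    participant_id = "P1", core_id = "P1-C1",
    x_um = runif(n, -400, 400), y_um = runif(n, -400, 400),
    intensity_hoechst = runif(n, 8, 12),
    intensity_ck = hi(cls == "tumor"),
    intensity_cd8 = hi(cls %in% c("cd8", "treg")),
    intensity_foxp3 = hi(cls %in% c("treg", "foxp3_only")),
    true_class = cls,
    stringsAsFactors = FALSE
  )
}

# Binary proximity classes for survival simulations: values uniform, low =
# bottom quarter (the analysis cutpoint for proximity).
binary_proximity_frame <- function(n, rule = "q1") {
  vals <- runif(n)
  cls <- binarize(vals, rule = rule)
  list(
    frame = data.frame(participant_id = sprintf("P%04d", seq_len(n)),
                       proximity_class = as.character(cls),
                       stringsAsFactors = FALSE),
    values = vals,
    cutpoint = attr(cls, "cutpoint")
  )
}

# Exponential survival with a proportional-hazards step on a binary class.
simulate_step_survival <- function(classes, hr_low, baseline = 0.05,
                                   censor = 0.2) {
  n <- length(classes)
  rate <- baseline * ifelse(classes == "low", hr_low, 1)
  ev <- rexp(n, rate)
  cn <- rexp(n, censor)
  data.frame(time = pmin(ev, cn), event = as.integer(ev <= cn))
}
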